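## Coordinate models are thin wrappers around an atom table with columns
## type, elety, resid, resno, chain, x, y, z. Parsing and writing of the
## PDB format itself is delegated to bio3d.

new_coord_model <- function(atoms, source = "memory", model_id = NULL) {
  need <- c("type", "elety", "resid", "resno", "chain", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  structure(list(atoms = atoms, source = source,
                 model_id = if (is.null(model_id)) basename(source) else model_id),
            class = "coord_model")
}

#' @export
print.coord_model <- function(x, ...) {
  cat(sprintf("coord_model '%s': %d atoms, %d residues, chain(s) %s\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$resid, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

write_coord_model <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   type = a$type,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain)
  invisible(path)
}

#' Read a coordinate model from a PDB file
#'
#' Parses a (single- or multi-chain) PDB file via [bio3d::read.pdb()] and
#' restricts it to one chain. The default chain is the first one containing
#' protein (`ATOM`) records; `HETATM` records in that chain -- notably the
#' retinal, residue name `RET` -- are retained so the ligand stays
#' addressable.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier, or `NULL` for the first protein chain.
#' @param model_id optional identifier carried into reports.
#' @return an object of class `coord_model`.
#' @export
read_structure <- function(path, chain = NULL, model_id = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read structure: no file '%s'", path))
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  chains <- unique(at$chain)
  if (is.null(chain)) {
    prot <- unique(at$chain[at$type == "ATOM"])
    chain <- if (length(prot)) prot[1] else chains[1]
  }
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain, paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  atoms <- data.frame(type = at$type, elety = at$elety, resid = at$resid,
                      resno = at$resno, chain = at$chain,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  new_coord_model(atoms, source = path, model_id = model_id)
}

## Resolve a selector ("TYR268:CZ", "RET:C20") to a single atom row.
resolve_selector <- function(model, sel) {
  p <- parse_selector(sel)
  a <- model$atoms
  hit <- a$resid == p$resid & a$elety == p$elety
  if (!is.na(p$resno)) hit <- hit & a$resno == p$resno
  idx <- which(hit)
  if (length(idx) == 0) {
    stop(sprintf("selector '%s' does not resolve in model '%s'",
                 sel, model$model_id))
  }
  if (length(idx) > 1) {
    stop(sprintf("selector '%s' is ambiguous in model '%s' (%d matches)",
                 sel, model$model_id, length(idx)))
  }
  a[idx, , drop = FALSE]
}

#' Distance between two selected atoms
#'
#' Euclidean distance between the atom centres named by two selectors of
#' the form `"RESNAME<number>:ATOM"` (retinal atoms as `"RET:Cn"`). Full
#' precision is kept; round to 0.1 Angstrom only when comparing with
#' published values.
#'
#' @param model a `coord_model`.
#' @param sel_a,sel_b atom selectors.
#' @return distance in Angstrom.
#' @export
pair_distance <- function(model, sel_a, sel_b) {
  stopifnot(inherits(model, "coord_model"))
  a <- resolve_selector(model, sel_a)
  b <- resolve_selector(model, sel_b)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

#' Enumerate contacts between two atom classes
#'
#' All cross-class atom pairs at or below the cutoff, sorted by distance.
#' A class is given as `list(resid =, elety =)`, e.g. tyrosine zeta-carbons
#' are `list(resid = "TYR", elety = "CZ")`.
#'
#' @param model a `coord_model`.
#' @param class_a,class_b atom classes.
#' @param cutoff distance cutoff in Angstrom (default 6.0, the lower edge
#'   of the DARR observability band).
#' @return data frame with columns `selector_a`, `selector_b`, `label`,
#'   `distance`, sorted by distance.
#' @export
enumerate_contacts <- function(model, class_a, class_b, cutoff = 6.0) {
  stopifnot(inherits(model, "coord_model"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  pick <- function(cl) {
    a <- model$atoms
    keep <- rep(TRUE, nrow(a))
    if (!is.null(cl$resid)) keep <- keep & a$resid == toupper(cl$resid)
    if (!is.null(cl$elety)) keep <- keep & a$elety == toupper(cl$elety)
    a[keep, , drop = FALSE]
  }
  A <- pick(class_a)
  B <- pick(class_b)
  if (nrow(A) == 0 || nrow(B) == 0) {
    warning("empty selector class; returning no contacts")
    return(data.frame(selector_a = character(), selector_b = character(),
                      label = character(), distance = numeric()))
  }
  sel_of <- function(r) sprintf("%s%d:%s", r$resid, r$resno, r$elety)
  rows <- list()
  seen <- character()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      ai <- A[i, ]; bj <- B[j, ]
      if (ai$resid == bj$resid && ai$resno == bj$resno &&
          ai$elety == bj$elety) next
      d <- sqrt((ai$x - bj$x)^2 + (ai$y - bj$y)^2 + (ai$z - bj$z)^2)
      if (d > cutoff) next
      k <- paste(sort(c(sel_of(ai), sel_of(bj))), collapse = "|")
      if (k %in% seen) next
      seen <- c(seen, k)
      rows[[length(rows) + 1]] <- data.frame(
        selector_a = sel_of(ai), selector_b = sel_of(bj),
        label = sprintf("%s%d-%s%d", ai$resid, ai$resno, bj$resid, bj$resno),
        distance = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(selector_a = character(), selector_b = character(),
                      label = character(), distance = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------
## Restraints

#' Build a restraint set from distance estimates
#'
#' Converts a table of build-up distance estimates into structural
#' restraints: quantified estimates become POSITIVE restraints (`r` +/-
#' `sigma`); crosspeaks observed but not quantified become UPPER bounds at
#' 6.5 Angstrom (the outer edge of the observability band); crosspeaks
#' absent from the spectra become ABSENT restraints at 6.0 Angstrom (the
#' inner edge). Using the two edges this way is conservative: a model
#' distance in the ambiguous 6.0-6.5 zone satisfies both restraint types.
#'
#' @param estimates data frame as returned by [infer_distances()] (columns
#'   `pair`, `r_hat`, `sigma`, `status`), or a list of `distance_estimate`s.
#' @param mapping named list mapping each pair label to
#'   `c(selector_a, selector_b)`.
#' @param upper_limit,absent_limit the band edges in Angstrom.
#' @return object of class `restraint_set`: data frame with columns
#'   `label`, `type`, `selector_a`, `selector_b`, `r`, `sigma`, `limit`.
#' @export
restraints_from_estimates <- function(estimates, mapping,
                                      upper_limit = 6.5, absent_limit = 6.0) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "distance_estimate"))) {
    estimates <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(pair = e$pair, r_hat = e$r_hat, sigma = e$sigma,
                 status = e$status, stringsAsFactors = FALSE)
    }))
  }
  if (nrow(estimates) == 0) {
    out <- data.frame(label = character(), type = character(),
                      selector_a = character(), selector_b = character(),
                      r = numeric(), sigma = numeric(), limit = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("restraint_set", "data.frame")))
  }
  unmapped <- setdiff(estimates$pair, names(mapping))
  if (length(unmapped)) {
    stop(sprintf("no selector mapping for pair(s): %s",
                 paste(unmapped, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(estimates)), function(i) {
    e <- estimates[i, ]
    sel <- mapping[[e$pair]]
    base <- data.frame(label = e$pair, selector_a = sel[1],
                       selector_b = sel[2], stringsAsFactors = FALSE)
    if (e$status == "estimated") {
      cbind(base, type = "POSITIVE", r = e$r_hat,
            sigma = max(e$sigma, 1e-6), limit = NA_real_)
    } else if (e$status == "upper_bound_only") {
      cbind(base, type = "UPPER", r = NA_real_, sigma = NA_real_,
            limit = upper_limit)
    } else {
      cbind(base, type = "ABSENT", r = NA_real_, sigma = NA_real_,
            limit = absent_limit)
    }
  })
  out <- do.call(rbind, rows)[, c("label", "type", "selector_a",
                                  "selector_b", "r", "sigma", "limit")]
  rownames(out) <- NULL
  structure(out, class = c("restraint_set", "data.frame"))
}

#' Write / read restraint sets as TSV
#' @param restraints a `restraint_set`.
#' @param path file path.
#' @return `read_restraints` returns a `restraint_set`.
#' @export
write_restraints <- function(restraints, path) {
  utils::write.table(as.data.frame(restraints), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(out, class = c("restraint_set", "data.frame"))
}

#' Score a coordinate model against a restraint set
#'
#' A POSITIVE restraint is satisfied when the model distance lies within
#' `tolerance_multiplier * sigma` of the estimate; an UPPER restraint when
#' the distance is at most its limit; an ABSENT restraint when the
#' distance is at least its limit. The score is the fraction of evaluable
#' restraints satisfied. Restraints whose selectors do not resolve are
#' marked unevaluable, excluded from the denominator, and reported with a
#' warning.
#'
#' @param model a `coord_model`.
#' @param restraints a `restraint_set`.
#' @param tolerance_multiplier width of the satisfaction band for POSITIVE
#'   restraints, in units of sigma.
#' @return object of class `consistency_score`: list with `model_id`,
#'   `score`, `n_satisfied`, `n_evaluated`, `verdicts` (per-restraint data
#'   frame incl. model distances and normalized violation magnitudes) and
#'   `violations`.
#' @export
score_model <- function(model, restraints, tolerance_multiplier = 2) {
  stopifnot(inherits(model, "coord_model"))
  verdicts <- lapply(seq_len(nrow(restraints)), function(i) {
    rs <- restraints[i, ]
    d <- tryCatch(pair_distance(model, rs$selector_a, rs$selector_b),
                  error = function(e) NA_real_)
    if (is.na(d)) {
      return(data.frame(label = rs$label, type = rs$type, d_model = NA_real_,
                        satisfied = NA, violation = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (rs$type == "POSITIVE") {
      ok <- abs(d - rs$r) <= tolerance_multiplier * rs$sigma
      viol <- max(0, (abs(d - rs$r) - tolerance_multiplier * rs$sigma) / rs$sigma)
    } else if (rs$type == "UPPER") {
      ok <- d <= rs$limit
      viol <- max(0, (d - rs$limit) / rs$limit)
    } else if (rs$type == "ABSENT") {
      ok <- d >= rs$limit
      viol <- max(0, (rs$limit - d) / rs$limit)
    } else stop(sprintf("unknown restraint type '%s'", rs$type))
    data.frame(label = rs$label, type = rs$type, d_model = d,
               satisfied = ok, violation = viol, stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, verdicts)
  if (any(is.na(v$satisfied))) {
    warning(sprintf("restraint(s) unevaluable in model '%s': %s",
                    model$model_id,
                    paste(v$label[is.na(v$satisfied)], collapse = ", ")))
  }
  eval_v <- v[!is.na(v$satisfied), , drop = FALSE]
  n_eval <- nrow(eval_v)
  n_sat <- sum(eval_v$satisfied)
  structure(list(model_id = model$model_id,
                 score = if (n_eval > 0) n_sat / n_eval else NA_real_,
                 n_satisfied = n_sat, n_evaluated = n_eval,
                 verdicts = v,
                 violations = eval_v[!eval_v$satisfied, , drop = FALSE]),
            class = "consistency_score")
}

#' @export
print.consistency_score <- function(x, ...) {
  cat(sprintf("model '%s': score %.3f (%d/%d restraints satisfied)\n",
              x$model_id, x$score, x$n_satisfied, x$n_evaluated))
  if (nrow(x$violations)) {
    cat("violations:\n")
    print(x$violations[, c("label", "type", "d_model", "violation")])
  }
  invisible(x)
}

#' Rank candidate models by restraint consistency
#'
#' Scores every model with [score_model()] and sorts by score (descending);
#' ties are broken by the summed normalized violation magnitude (smaller
#' wins), and exact ties on both keys are reported as such.
#'
#' @param models a named list of `coord_model`s (>= 2).
#' @param restraints a `restraint_set`.
#' @param tolerance_multiplier passed to [score_model()].
#' @return list with `ranking` (data frame: `model_id`, `score`,
#'   `violation_sum`, `rank`, `tied`) and `scores` (the per-model
#'   `consistency_score` objects, in ranked order).
#' @export
discriminate_models <- function(models, restraints, tolerance_multiplier = 2) {
  if (length(models) < 2) stop("need >= 2 models to discriminate")
  scores <- lapply(models, score_model, restraints = restraints,
                   tolerance_multiplier = tolerance_multiplier)
  tab <- do.call(rbind, lapply(scores, function(s) {
    data.frame(model_id = s$model_id, score = s$score,
               violation_sum = sum(s$verdicts$violation, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$score, tab$violation_sum)
  tab <- tab[ord, , drop = FALSE]
  key <- paste(signif(tab$score, 12), signif(tab$violation_sum, 12))
  tab$rank <- match(key, unique(key))
  tab$tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  rownames(tab) <- NULL
  list(ranking = tab, scores = scores[ord])
}

## ---------------------------------------------------------------------
## Published pocket distances and synthetic stand-in models

#' Published retinal-pocket distance tables
#'
#' Inter-atomic distances reported for rhodopsin crystal structures
#' (PDB-IDs 1U19 and 1GZM) and for the two candidate Meta-II retinal
#' orientations: the NMR-derived orientation (C20 closer to Tyr268 than
#' C12) and the crystallographic one (the reverse). These printed values
#' serve as inputs for building synthetic stand-in coordinate models; see
#' [synthetic_pocket_model()].
#'
#' @param model one of `"rhodopsin-1u19"`, `"rhodopsin-1gzm"`,
#'   `"meta2-nmr"`, `"meta2-crystal"`.
#' @return data frame with columns `selector_a`, `selector_b`, `distance`.
#' @export
pocket_distance_table <- function(model = c("rhodopsin-1u19", "rhodopsin-1gzm",
                                            "meta2-nmr", "meta2-crystal")) {
  model <- match.arg(model)
  tab <- switch(model,
    "rhodopsin-1u19" = rbind(
      ## six extracellular Tyr(CZ)-Gly(CA) contacts
      c("TYR10:CZ",  "GLY3:CA",   3.9),
      c("TYR10:CZ",  "GLY280:CA", 4.4),
      c("TYR29:CZ",  "GLY101:CA", 4.0),
      c("TYR178:CZ", "GLY114:CA", 4.5),
      c("TYR191:CZ", "GLY188:CA", 5.2),
      c("TYR268:CZ", "GLY188:CA", 5.3),
      ## EL2 backbone control and Cys-Tyr probes
      c("CYS187:C",  "GLY188:CA", 2.4),
      c("TYR136:CZ", "CYS140:C",  5.1),
      ## retinal methyl contacts
      c("RET:C19",   "TYR268:CZ", 4.3),
      c("RET:C19",   "TYR191:CZ", 4.7),
      ## C18 to the Phe261 ring carbons, spanning the reported 4.9-5.4 A
      c("RET:C18",   "PHE261:CG",  4.9),
      c("RET:C18",   "PHE261:CD1", 5.0),
      c("RET:C18",   "PHE261:CD2", 5.1),
      c("RET:C18",   "PHE261:CE1", 5.2),
      c("RET:C18",   "PHE261:CE2", 5.3),
      c("RET:C18",   "PHE261:CZ",  5.4)),
    "rhodopsin-1gzm" = rbind(
      c("RET:C20", "TYR268:CZ", 4.1),
      c("RET:C12", "TYR268:CZ", 4.5),
      c("RET:C12", "RET:C20",   2.4)),
    ## in both Meta-II candidates the C19-tyrosine contact is lost
    ## (> 6-6.5 A); 7.0 A places it safely beyond the band
    "meta2-nmr" = rbind(
      c("RET:C20", "TYR268:CZ", 4.4),
      c("RET:C12", "TYR268:CZ", 5.6),
      c("RET:C12", "RET:C20",   2.4),
      c("RET:C19", "TYR268:CZ", 7.0)),
    "meta2-crystal" = rbind(
      c("RET:C12", "TYR268:CZ", 3.9),
      c("RET:C20", "TYR268:CZ", 5.9),
      c("RET:C12", "RET:C20",   2.4),
      c("RET:C19", "TYR268:CZ", 7.0)))
  data.frame(selector_a = tab[, 1], selector_b = tab[, 2],
             distance = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
}

#' Synthetic stand-in pocket models
#'
#' Builds a toy coordinate model (via [generate_toy_structure()]) that
#' realizes the published distances of [pocket_distance_table()] exactly.
#' These are geometric stand-ins for the deposited crystal structures --
#' use them when the real PDB entries are not on disk; they reproduce the
#' published pairwise distances but nothing else about the structures.
#'
#' @inheritParams pocket_distance_table
#' @param path optional PDB file path to write (filenames should carry a
#'   `synthetic-` prefix to keep their provenance obvious).
#' @return a `coord_model`.
#' @export
synthetic_pocket_model <- function(model = c("rhodopsin-1u19", "rhodopsin-1gzm",
                                             "meta2-nmr", "meta2-crystal"),
                                   path = NULL) {
  model <- match.arg(model)
  m <- generate_toy_structure(pocket_distance_table(model), path = path)
  m$model_id <- paste0("synthetic-", model)
  m
}
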