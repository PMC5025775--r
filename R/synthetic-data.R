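#' Known-distance calibration geometry
#'
#' The fixed intramolecular carbon pairs used to calibrate the build-up
#' model: retinal C5-C18 (1.4 A), the intra-retinal C8-C19 and C12-C20
#' methyl pairs (2.4 A), and the EL2 pairs Cys110 Cb-Cys187 Cb (3.6 A),
#' Cys187 Cb-Gly188 Ca (4.6 A) and Cys187 Cb-Gly188 C=O (5.3 A). The two
#' intra-retinal pairs marked as controls keep a fixed separation in every
#' photointermediate and are used for intensity normalization.
#'
#' @return data frame with columns `pair`, `distance` (Angstrom), `control`.
#' @export
calibration_geometry <- function() {
  data.frame(
    pair = c("C5-C18", "C8-C19", "C12-C20",
             "Cys110CB-Cys187CB", "Cys187CB-Gly188CA", "Cys187CB-Gly188C"),
    distance = c(1.4, 2.4, 2.4, 3.6, 4.6, 5.3),
    control = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

## Coerce a geometry spec (data frame or named vector) to the canonical
## data frame and validate it.
as_geometry <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- data.frame(pair = names(x), distance = as.numeric(x),
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || !all(c("pair", "distance") %in% names(x))) {
    stop("geometry must be a data frame with columns 'pair' and 'distance'")
  }
  if (nrow(x) == 0) stop("geometry is empty")
  if (anyDuplicated(x$pair)) stop("pair labels must be unique")
  if (any(!is.finite(x$distance)) || any(x$distance <= 0)) {
    stop("all distances must be positive")
  }
  if (is.null(x$control)) x$control <- FALSE
  x
}

as_crosspeak_table <- function(x) {
  need <- c("pair", "t_mix_ms", "intensity")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("crosspeak table needs columns pair, t_mix_ms, intensity")
  }
  if (is.null(x$replicate)) x$replicate <- 1L
  if (is.null(x$noise_rms)) x$noise_rms <- 0
  if (any(x$t_mix_ms < 0)) stop("mixing times must be non-negative")
  if (any(x$noise_rms < 0)) stop("noise_rms must be non-negative")
  x
}

#' Generate a synthetic crosspeak build-up dataset
#'
#' Evaluates the build-up model for every pair in `geometry` on the
#' mixing-time grid and adds i.i.d. Gaussian intensity noise of standard
#' deviation `noise_rms`. With `noise_rms = 0` the table reproduces
#' [simulate_buildup()] exactly; with a fixed `seed` generation is
#' bit-reproducible.
#'
#' @param geometry data frame (`pair`, `distance`) or named numeric vector
#'   of true distances in Angstrom; see [calibration_geometry()].
#' @param params a [buildup_params()] object.
#' @param grid mixing times in ms, strictly increasing.
#' @param noise_rms Gaussian intensity noise RMS (>= 0).
#' @param replicates number of independent noisy replicates per pair.
#' @param seed optional integer seed.
#' @return a crosspeak table: data frame with columns `pair`, `t_mix_ms`,
#'   `replicate`, `intensity`, `noise_rms`.
#' @export
generate_buildup_dataset <- function(geometry, params = buildup_params(),
                                     grid = default_mixing_grid(),
                                     noise_rms = 0.02, replicates = 1,
                                     seed = NULL) {
  geometry <- as_geometry(geometry)
  check_mixing_grid(grid)
  stopifnot(inherits(params, "buildup_params"))
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(geometry)), function(i) {
    clean <- simulate_buildup(geometry$distance[i], params, grid)
    do.call(rbind, lapply(seq_len(replicates), function(rep) {
      noise <- if (noise_rms > 0) {
        stats::rnorm(length(grid), 0, noise_rms)
      } else 0
      data.frame(pair = geometry$pair[i], t_mix_ms = grid,
                 replicate = rep, intensity = clean + noise,
                 noise_rms = noise_rms, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "normalized") <- FALSE
  out
}

#' Write / read crosspeak tables as TSV
#'
#' Plain tab-separated format with columns `pair`, `t_mix_ms`, `replicate`,
#' `intensity`, `noise_rms`.
#'
#' @param table a crosspeak table.
#' @param path file path.
#' @return `read_crosspeak_table` returns the table; `write_crosspeak_table`
#'   returns `path` invisibly.
#' @export
write_crosspeak_table <- function(table, path) {
  table <- as_crosspeak_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosspeak_table
#' @export
read_crosspeak_table <- function(path) {
  as_crosspeak_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------------
## Toy coordinate structures

## Parse "TYR268:CZ" / "RET:C20" into (resid, resno, elety).
parse_selector <- function(sel) {
  m <- regmatches(sel, regexec("^([A-Za-z]+)([0-9]*):([A-Za-z0-9']+)$", sel))[[1]]
  if (length(m) != 4) {
    stop(sprintf("cannot parse selector '%s' (expected RESNAME[number]:ATOM)", sel))
  }
  list(resid = toupper(m[2]),
       resno = if (nzchar(m[3])) as.integer(m[3]) else NA_integer_,
       elety = toupper(m[4]),
       key = toupper(sel))
}

## Fixed direction table used when an atom has a single distance constraint.
.toy_directions <- function() {
  d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1),
             c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
             c(1, -1, 0), c(-1, 0, 1), c(0, -1, 1),
             c(1, 1, 1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1))
  d / sqrt(rowSums(d^2))
}

#' Generate a toy coordinate structure realizing prescribed pair distances
#'
#' Places one pseudo-atom per selector so that every requested pair
#' distance is met exactly (to well below 1e-3 Angstrom), and optionally
#' writes the result as a minimal single-chain PDB file. Connected groups
#' of constraints are solved geometrically (fresh axis for a single
#' constraint, sphere-circle intersection for two, least-squares
#' trilateration for three or more); disconnected groups are offset 25
#' Angstrom apart so they cannot generate accidental contacts. The retinal
#' is written as HETATM records with residue name `RET`, matching deposited
#' rhodopsin conventions; everything else becomes ATOM records.
#'
#' The output is a geometric stand-in, not a chemically sensible model:
#' only the requested distances are controlled.
#'
#' @param spec data frame with columns `selector_a`, `selector_b`,
#'   `distance` (Angstrom); selectors like `"TYR268:CZ"` or `"RET:C20"`.
#' @param path optional path of the PDB file to write.
#' @param chain chain identifier for all atoms.
#' @return a `coord_model` (see [read_structure()]); if `path` is given the
#'   model is re-read from the written file so it round-trips the format.
#' @export
generate_toy_structure <- function(spec, path = NULL, chain = "A") {
  if (!is.data.frame(spec) ||
      !all(c("selector_a", "selector_b", "distance") %in% names(spec))) {
    stop("spec needs columns selector_a, selector_b, distance")
  }
  if (any(spec$distance <= 0)) stop("target distances must be positive")
  if (any(toupper(spec$selector_a) == toupper(spec$selector_b))) {
    stop("duplicate atom selectors within a pair are not allowed")
  }
  key <- function(s) toupper(s)
  pair_key <- paste(pmin(key(spec$selector_a), key(spec$selector_b)),
                    pmax(key(spec$selector_a), key(spec$selector_b)))
  if (anyDuplicated(pair_key)) stop("duplicate selector pairs in spec")

  sels <- unique(c(key(spec$selector_a), key(spec$selector_b)))
  parsed <- lapply(sels, parse_selector)
  names(parsed) <- sels

  ## constraint adjacency
  edges <- data.frame(a = key(spec$selector_a), b = key(spec$selector_b),
                      d = spec$distance, stringsAsFactors = FALSE)
  adj <- function(s) {
    rbind(
      data.frame(other = edges$b[edges$a == s], d = edges$d[edges$a == s]),
      data.frame(other = edges$a[edges$b == s], d = edges$d[edges$b == s])
    )
  }
  deg <- vapply(sels, function(s) nrow(adj(s)), integer(1))

  ## connected components
  comp <- stats::setNames(rep(NA_integer_, length(sels)), sels)
  cid <- 0
  for (s in sels) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      queue <- c(queue, adj(cur)$other)
    }
  }

  dirs <- .toy_directions()
  pos <- matrix(NA_real_, nrow = length(sels), ncol = 3,
                dimnames = list(sels, NULL))
  dir_i <- 0
  next_dir <- function() {
    dir_i <<- dir_i %% nrow(dirs) + 1
    dirs[dir_i, ]
  }

  for (ci in seq_len(cid)) {
    members <- sels[comp == ci]
    origin <- (ci - 1) * c(25, 25, 0)
    ## seed at the highest-degree atom for stable multi-constraint hubs
    seed_atom <- members[order(-deg[members])][1]
    pos[seed_atom, ] <- origin
    placed <- seed_atom
    remaining <- setdiff(members, seed_atom)
    while (length(remaining)) {
      ## next atom: most constraints to already-placed atoms
      ncon <- vapply(remaining, function(s) sum(adj(s)$other %in% placed),
                     integer(1))
      if (max(ncon) == 0) stop("internal error: disconnected component member")
      s <- remaining[order(-ncon)][1]
      con <- adj(s)
      con <- con[con$other %in% placed, , drop = FALSE]
      P <- pos[con$other, , drop = FALSE]
      d <- con$d
      pos[s, ] <- place_atom(P, d, next_dir, pos[placed, , drop = FALSE])
      placed <- c(placed, s)
      remaining <- setdiff(remaining, s)
    }
  }

  ## verify every requested distance
  for (i in seq_len(nrow(edges))) {
    got <- sqrt(sum((pos[edges$a[i], ] - pos[edges$b[i], ])^2))
    if (abs(got - edges$d[i]) > 1e-6) {
      stop(sprintf("constraint %s - %s (%.3f A) not realizable (got %.3f A)",
                   edges$a[i], edges$b[i], edges$d[i], got))
    }
  }

  ## residues named without a number get distinct fallback numbers
  nonum <- unique(vapply(parsed, function(p) {
    if (is.na(p$resno)) p$resid else NA_character_
  }, character(1)))
  nonum <- nonum[!is.na(nonum)]
  fallback_no <- stats::setNames(900L + seq_along(nonum), nonum)
  if ("RET" %in% nonum) fallback_no[["RET"]] <- 401L
  atoms <- do.call(rbind, lapply(sels, function(s) {
    p <- parsed[[s]]
    data.frame(
      type = if (p$resid == "RET") "HETATM" else "ATOM",
      elety = p$elety, resid = p$resid,
      resno = if (!is.na(p$resno)) p$resno else fallback_no[[p$resid]],
      chain = chain,
      x = pos[s, 1], y = pos[s, 2], z = pos[s, 3],
      stringsAsFactors = FALSE
    )
  }))
  atoms <- atoms[order(atoms$resno, atoms$elety), , drop = FALSE]
  rownames(atoms) <- NULL
  model <- new_coord_model(atoms, source = if (is.null(path)) "generated" else path)
  if (!is.null(path)) {
    write_coord_model(model, path)
    model <- read_structure(path, chain = chain)
  }
  model
}

## Solve for a point at distances d from rows of P (already-placed atoms).
place_atom <- function(P, d, next_dir, all_placed) {
  if (nrow(P) == 1) {
    for (i in 1:20) {
      cand <- P[1, ] + d[1] * next_dir()
      clash <- any(sqrt(rowSums((all_placed - matrix(cand, nrow(all_placed),
                                                    3, byrow = TRUE))^2)) < 0.5)
      if (!clash) return(cand)
    }
    stop("could not place atom without clashes")
  }
  if (nrow(P) == 2) {
    p1 <- P[1, ]; p2 <- P[2, ]
    v <- p2 - p1
    dist12 <- sqrt(sum(v^2))
    if (dist12 > d[1] + d[2] || dist12 < abs(d[1] - d[2])) {
      stop(sprintf("two-sphere constraint not realizable (centres %.3f A apart, radii %.3f/%.3f)",
                   dist12, d[1], d[2]))
    }
    u <- v / dist12
    a <- (d[1]^2 - d[2]^2 + dist12^2) / (2 * dist12)
    h2 <- d[1]^2 - a^2
    h <- sqrt(max(h2, 0))
    base <- p1 + a * u
    ## any perpendicular to u
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    perp <- ref - sum(ref * u) * u
    perp <- perp / sqrt(sum(perp^2))
    return(base + h * perp)
  }
  ## >= 3 constraints: least-squares trilateration
  init <- colMeans(P) + c(0.1, 0.2, 0.3)
  obj <- function(x) sum((sqrt(rowSums((P - matrix(x, nrow(P), 3,
                                                  byrow = TRUE))^2)) - d)^2)
  fit <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  if (fit$value > 1e-10) stop("multi-sphere constraint set not realizable")
  fit$par
}

## ---------------------------------------------------------------------
## Titration spectrum series

#' Default wavenumber grid of the decomposition window
#'
#' 1800 to 1600 1/cm, descending, at 4 1/cm spectral resolution.
#' @return numeric vector of wavenumbers.
#' @export
default_wavenumber_grid <- function() seq(1800, 1600, by = -4)

gaussian_bands <- function(grid, bands) {
  y <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    y <- y + bands$amp[i] *
      exp(-(grid - bands$centre[i])^2 / (2 * bands$width[i]^2))
  }
  y
}

#' Synthetic Meta-I / Meta-IIbH+ reference difference spectra
#'
#' A two-component basis of Gaussian bands on the 1800-1600 1/cm window.
#' The components differ in an amide-I band near 1644 vs 1661 1/cm and in
#' carboxylic C=O marker bands between 1700 and 1780 1/cm; band positions,
#' widths (8-15 1/cm) and signs are documented, invented constants -- they
#' emulate the qualitative appearance of photointermediate difference
#' spectra, not any measured dataset.
#'
#' @param grid wavenumber grid (1/cm); must lie within \[1600, 1800\].
#' @return object of class `basis_set`: list with `wavenumber` and a
#'   component matrix `components` (one named column per state).
#' @export
default_basis <- function(grid = default_wavenumber_grid()) {
  meta1 <- data.frame(centre = c(1661, 1727, 1768),
                      width = c(10, 9, 10),
                      amp = c(1.0, 0.45, -0.30))
  meta2 <- data.frame(centre = c(1644, 1712, 1748, 1768),
                      width = c(12, 9, 10, 10),
                      amp = c(-0.90, 0.60, 0.50, -0.30))
  basis_set(grid, cbind(meta_I = gaussian_bands(grid, meta1),
                        meta_IIbH = gaussian_bands(grid, meta2)))
}

#' Construct a basis set
#' @param wavenumber wavenumber grid (1/cm).
#' @param components matrix with one named column per reference spectrum.
#' @return object of class `basis_set`.
#' @export
basis_set <- function(wavenumber, components) {
  components <- as.matrix(components)
  if (nrow(components) != length(wavenumber)) {
    stop("component rows must match the wavenumber grid")
  }
  if (ncol(components) < 2) stop("basis needs >= 2 components")
  if (is.null(colnames(components))) {
    stop("basis components must be named")
  }
  if (any(wavenumber < 1600 - 1e-9) || any(wavenumber > 1800 + 1e-9)) {
    stop("wavenumber grid must lie within [1600, 1800] 1/cm")
  }
  structure(list(wavenumber = wavenumber, components = components),
            class = "basis_set")
}

#' Henderson-Hasselbalch Meta-II fraction
#'
#' `f(pH) = 1 / (1 + 10^(hill * (pH - pK)))`: the protonation-coupled
#' fraction of the receptor in the Meta-IIbH+ state, decreasing with pH and
#' equal to 1/2 at `pH = pK`.
#'
#' @param pH pH value(s).
#' @param pK apparent pK of the Meta-I to Meta-IIbH+ transition.
#' @param hill slope (Hill) coefficient; 1 for a pure one-proton law.
#' @return fraction(s) in \[0, 1\].
#' @export
hh_fraction <- function(pH, pK, hill = 1) {
  1 / (1 + 10^(hill * (pH - pK)))
}

#' Generate a synthetic titration spectrum series
#'
#' Mixes the two basis spectra by the Henderson-Hasselbalch law at each pH
#' and adds i.i.d. Gaussian noise. At `pH = pK` the mixture is exactly
#' 50/50; far below the pK it converges to the pure Meta-IIbH+ component.
#' `alkaline_floor` (default 0) lifts the high-pH limit of the Meta-II
#' fraction above zero, emulating the incomplete back-titration of
#' forward-shifted mutants.
#'
#' @param pK apparent pK of the generator (ground truth).
#' @param hill Hill slope of the generator (> 0).
#' @param pH pH grid, strictly increasing, within \[3, 10\].
#' @param basis a [basis_set()] with components `meta_I` and `meta_IIbH`.
#' @param noise_rms Gaussian noise RMS in spectrum units.
#' @param seed optional integer seed.
#' @param alkaline_floor Meta-II fraction retained at the alkaline limit.
#' @param label sample label (e.g. `"wild-type"` or a mutant name).
#' @return object of class `spectrum_series`: list with `wavenumber`,
#'   matrix `spectra` (wavenumber x pH), `pH`, `label`, and the ground-truth
#'   fractions as attribute `fractions_true`.
#' @export
generate_titration_series <- function(pK = 6.8, hill = 1,
                                      pH = seq(4.5, 9.0, by = 0.5),
                                      basis = default_basis(),
                                      noise_rms = 0, seed = NULL,
                                      alkaline_floor = 0,
                                      label = "wild-type") {
  stopifnot(inherits(basis, "basis_set"))
  if (hill <= 0) stop("hill must be > 0")
  if (is.unsorted(pH, strictly = TRUE)) stop("pH grid must be strictly increasing")
  if (any(pH < 3) || any(pH > 10)) stop("pH grid must lie within [3, 10]")
  if (alkaline_floor < 0 || alkaline_floor >= 1) {
    stop("alkaline_floor must be in [0, 1)")
  }
  if (!all(c("meta_I", "meta_IIbH") %in% colnames(basis$components))) {
    stop("basis must contain components 'meta_I' and 'meta_IIbH'")
  }
  f <- alkaline_floor + (1 - alkaline_floor) * hh_fraction(pH, pK, hill)
  A <- basis$components
  S <- A[, "meta_IIbH"] %o% f + A[, "meta_I"] %o% (1 - f)
  if (noise_rms > 0) {
    if (!is.null(seed)) set.seed(seed)
    S <- S + matrix(stats::rnorm(length(S), 0, noise_rms), nrow(S), ncol(S))
  }
  colnames(S) <- sprintf("pH=%g", pH)
  structure(list(wavenumber = basis$wavenumber, spectra = S, pH = pH,
                 label = label),
            class = "spectrum_series",
            fractions_true = f)
}

#' Write / read a spectrum series as CSV
#'
#' First column `wavenumber_cm-1`, one column per pH point labelled
#' `pH=<value>`.
#'
#' @param series a `spectrum_series`.
#' @param path file path.
#' @param label sample label attached on read.
#' @return `read_spectrum_series` returns a `spectrum_series`;
#'   `write_spectrum_series` returns `path` invisibly.
#' @export
write_spectrum_series <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  df <- data.frame(series$wavenumber, series$spectra, check.names = FALSE)
  names(df)[1] <- "wavenumber_cm-1"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_series
#' @export
read_spectrum_series <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  wn <- df[[1]]
  spc <- as.matrix(df[, -1, drop = FALSE])
  pH <- as.numeric(sub("^pH=", "", colnames(spc)))
  if (any(is.na(pH))) stop("spectrum columns must be labelled pH=<value>")
  structure(list(wavenumber = wn, spectra = spc, pH = pH, label = label),
            class = "spectrum_series")
}
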