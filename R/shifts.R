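## Carbon-13 chemical-shift bookkeeping. Shifts are stored in p.p.m. with
## the referencing compound recorded explicitly; the only supported scales
## are neat TMS (0 p.p.m.) and DSS in D2O, which sits 2.01 p.p.m. downfield
## of TMS for 13C.

.dss_minus_tms <- 2.01

#' Convert a 13C chemical shift between TMS and DSS referencing
#'
#' TMS -> DSS adds 2.01 p.p.m.; DSS -> TMS subtracts it; converting a
#' scale to itself is the identity. The conversion is an exact bijection.
#'
#' @param shift chemical shift(s) in p.p.m.
#' @param from,to referencing compound, `"TMS"` or `"DSS"`.
#' @return shift(s) on the target scale.
#' @export
convert_reference <- function(shift, from, to) {
  refs <- c(TMS = 0, DSS = .dss_minus_tms)
  if (!from %in% names(refs)) stop(sprintf("unknown reference '%s'", from))
  if (!to %in% names(refs)) stop(sprintf("unknown reference '%s'", to))
  shift - refs[[from]] + refs[[to]]
}

#' Construct a shift assignment
#'
#' @param site site label, e.g. `"RET:C18"` or `"SER186:CB"`.
#' @param state photointermediate state: `"rhodopsin"`, `"Meta-I"` or
#'   `"Meta-II"`.
#' @param shift chemical shift in p.p.m. (must lie in \[0, 250\]).
#' @param reference referencing compound, `"TMS"` (default) or `"DSS"`.
#' @return a `shift_assignment` list.
#' @export
shift_assignment <- function(site, state, shift, reference = "TMS") {
  state <- match.arg(state, c("rhodopsin", "Meta-I", "Meta-II"))
  reference <- match.arg(reference, c("TMS", "DSS"))
  if (shift < 0 || shift > 250) stop("13C shift outside [0, 250] p.p.m.")
  structure(list(site = site, state = state, shift = shift,
                 reference = reference), class = "shift_assignment")
}

#' Chemical-shift change between two states
#'
#' `delta = b$shift - a$shift` for the same site on the same referencing
#' scale. The direction is `"downfield"` (larger p.p.m.) for positive
#' deltas beyond the significance threshold, `"upfield"` for negative, and
#' `"unchanged"` within it. The default threshold of 0.2 p.p.m. is the
#' experimental reproducibility bound of repeated preparations.
#'
#' @param a,b `shift_assignment`s for the same site in different states.
#' @param threshold significance threshold in p.p.m.
#' @return a `shift_change` list with `site`, `delta`, `direction`,
#'   `threshold` and the two states.
#' @export
state_delta <- function(a, b, threshold = 0.2) {
  stopifnot(inherits(a, "shift_assignment"), inherits(b, "shift_assignment"))
  if (a$site != b$site) stop("assignments are for different sites")
  if (a$state == b$state) stop("assignments are for the same state")
  if (a$reference != b$reference) {
    stop("mixed referencing scales; convert_reference() first")
  }
  delta <- b$shift - a$shift
  direction <- if (abs(delta) <= threshold) "unchanged"
               else if (delta > 0) "downfield" else "upfield"
  structure(list(site = a$site, from = a$state, to = b$state,
                 delta = delta, direction = direction,
                 threshold = threshold), class = "shift_change")
}

#' @export
print.shift_change <- function(x, ...) {
  cat(sprintf("%s (%s -> %s): delta %+.2f p.p.m. (%s)\n",
              x$site, x$from, x$to, x$delta, x$direction))
  invisible(x)
}

#' Hydrogen-bonding interpretation of a serine Cbeta shift change
#'
#' The 13C-beta resonance of serine is sensitive to hydrogen bonding of the
#' Cbeta-OH group: a downfield change indicates increased hydrogen bonding,
#' an upfield change decreased. The rule is specific to serine Cbeta sites
#' (labelled `"SERnnn:CB"`); other sites are rejected rather than
#' over-interpreted.
#'
#' @param change a `shift_change` for a serine Cbeta site.
#' @return `"increased"`, `"decreased"` or `"unchanged"`.
#' @export
classify_hbond_change <- function(change) {
  stopifnot(inherits(change, "shift_change"))
  if (!grepl("^SER[0-9]*:CB$", toupper(change$site))) {
    stop(sprintf("hydrogen-bond rule applies to Ser Cbeta sites only, not '%s'",
                 change$site))
  }
  switch(change$direction,
         downfield = "increased",
         upfield = "decreased",
         unchanged = "unchanged")
}

#' Read a shift table from CSV
#'
#' Expects columns `site`, `state`, `shift_ppm`, `reference`. A small table
#' of published retinal and tyrosine shifts ships with the package:
#' `system.file("extdata", "retinal_shifts.csv", package = "rhodomet")`.
#'
#' @param path CSV path.
#' @return data frame of assignments.
#' @export
read_shift_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "state", "shift_ppm", "reference")
  if (!all(need %in% names(df))) {
    stop("shift table needs columns site, state, shift_ppm, reference")
  }
  df
}

#' State-to-state deltas for every site in a shift table
#'
#' @param table data frame as from [read_shift_table()].
#' @param from,to the two states to compare.
#' @param threshold significance threshold in p.p.m.
#' @return data frame with `site`, `delta`, `direction`.
#' @export
shift_deltas <- function(table, from = "rhodopsin", to = "Meta-II",
                         threshold = 0.2) {
  sites <- intersect(table$site[table$state == from],
                     table$site[table$state == to])
  rows <- lapply(sites, function(s) {
    a <- table[table$site == s & table$state == from, ][1, ]
    b <- table[table$site == s & table$state == to, ][1, ]
    ch <- state_delta(
      shift_assignment(s, from, a$shift_ppm, a$reference),
      shift_assignment(s, to, b$shift_ppm, b$reference),
      threshold = threshold)
    data.frame(site = s, delta = ch$delta, direction = ch$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
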