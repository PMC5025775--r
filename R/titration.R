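## FTIR difference-spectrum decomposition and Meta-I <-> Meta-IIbH+
## titration fitting over the 1800-1600 1/cm window.

#' Decompose a spectrum series onto reference spectra
#'
#' For each pH point, finds non-negative component fractions summing to
#' one that minimize the squared residual against the basis spectra over
#' the decomposition window. The sum-to-one constraint is imposed as an
#' augmented equality row on the non-negative least-squares problem; on
#' any noiseless in-span mixture the recovery is exact (residual zero).
#'
#' @param series a `spectrum_series` (see [generate_titration_series()] /
#'   [read_spectrum_series()]).
#' @param basis a [basis_set()] on the identical wavenumber grid.
#' @param max_condition reject the basis as degenerate when its condition
#'   number exceeds this.
#' @return data frame with one row per pH: `pH`, one fraction column per
#'   basis component, and `residual` (root-mean-square misfit per point);
#'   the basis condition number is attached as attribute `condition`.
#' @export
decompose_spectra <- function(series, basis, max_condition = 1e8) {
  stopifnot(inherits(series, "spectrum_series"), inherits(basis, "basis_set"))
  if (length(series$wavenumber) != length(basis$wavenumber) ||
      any(abs(series$wavenumber - basis$wavenumber) > 1e-9)) {
    stop("series and basis wavenumber grids do not match")
  }
  A <- basis$components
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    stop(sprintf("basis is degenerate (condition number %.3g)", cond))
  }
  lambda <- 1e4 * max(abs(A))
  A_aug <- rbind(A, lambda * rep(1, ncol(A)))
  out <- lapply(seq_along(series$pH), function(j) {
    y <- series$spectra[, j]
    sol <- pracma::lsqnonneg(A_aug, c(y, lambda))
    x <- sol$x
    if (sum(x) > 0) x <- x / sum(x)     # enforce the constraint exactly
    resid <- y - A %*% x
    row <- as.data.frame(as.list(stats::setNames(x, colnames(A))))
    row$pH <- series$pH[j]
    row$residual <- sqrt(mean(resid^2))
    row
  })
  out <- do.call(rbind, out)
  out <- out[, c("pH", colnames(A), "residual")]
  attr(out, "condition") <- cond
  attr(out, "label") <- series$label
  out
}

#' Fit a Henderson-Hasselbalch titration to Meta-II fractions
#'
#' Least-squares fit of `f(pH) = 1 / (1 + 10^(hill * (pH - pK)))` to the
#' Meta-IIbH+ fraction as a function of pH. The Hill slope is fixed at 1
#' unless freed (`hill_free = TRUE`). The fit is flagged two-state
#' (`two_state_ok`) when the largest per-point residual stays below
#' `tolerance`; biphasic titrations fail this flag. A pK further than one
#' unit outside the sampled pH range is flagged as extrapolated.
#'
#' @param fractions data frame from [decompose_spectra()], or any data
#'   frame with columns `pH` and a Meta-II fraction column.
#' @param component name of the Meta-II fraction column.
#' @param hill_free free the Hill slope instead of fixing it at 1.
#' @param tolerance two-state acceptance bound on the max per-point
#'   residual (fraction units).
#' @return object of class `titration_fit`: list with `pK`, `hill`,
#'   `fractions` (observed), `fitted`, `residual_norm`, `two_state_ok`,
#'   `extrapolated`, `alkaline_plateau` (observed Meta-II fraction at the
#'   highest pH) and `label`.
#' @export
fit_titration <- function(fractions, component = "meta_IIbH",
                          hill_free = FALSE, tolerance = 0.05) {
  if (!component %in% names(fractions)) {
    stop(sprintf("no fraction column '%s'", component))
  }
  pH <- fractions$pH
  f <- fractions[[component]]
  if (length(pH) < 4) stop("need >= 4 pH points")
  if (diff(range(pH)) < 2) stop("pH points must span >= 2 pH units")
  if (max(f) - min(f) < 1e-12) {
    stop("all fractions identical: no transition in the sampled window")
  }
  if (hill_free) {
    fit <- minpack.lm::nlsLM(
      f ~ 1 / (1 + 10^(hill * (pH - pK))),
      data = data.frame(pH = pH, f = f),
      start = list(pK = stats::median(pH), hill = 1),
      lower = c(pK = min(pH) - 3, hill = 0.05),
      upper = c(pK = max(pH) + 3, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    pK <- coef(fit)[["pK"]]
    hill <- coef(fit)[["hill"]]
  } else {
    hill <- 1
    obj <- function(pK) sum((f - hh_fraction(pH, pK, hill))^2)
    opt <- stats::optimize(obj, c(min(pH) - 3, max(pH) + 3), tol = 1e-10)
    pK <- opt$minimum
  }
  fitted <- hh_fraction(pH, pK, hill)
  resid <- f - fitted
  structure(list(pK = pK, hill = hill,
                 fractions = data.frame(pH = pH, f = f),
                 fitted = fitted,
                 residual_norm = sqrt(sum(resid^2)),
                 two_state_ok = max(abs(resid)) < tolerance,
                 extrapolated = pK < min(pH) - 1 || pK > max(pH) + 1,
                 alkaline_plateau = f[which.max(pH)],
                 label = attr(fractions, "label", exact = TRUE)),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("titration fit%s: apparent pK %.2f (hill %.2f)%s\n",
              if (is.null(x$label)) "" else sprintf(" [%s]", x$label),
              x$pK, x$hill,
              if (x$two_state_ok) "" else " -- NOT two-state"))
  if (x$extrapolated) cat("  warning: pK extrapolated beyond sampled range\n")
  invisible(x)
}

#' Classify a mutant equilibrium phenotype against wild type
#'
#' Compares two titration fits on overlapping pH ranges and assigns one
#' label: `forward_shifted` when the mutant retains substantially more
#' Meta-II at the alkaline endpoint than wild type (or titrates
#' non-two-state with an elevated alkaline plateau); `meta_I_stabilized`
#' when the mutant pK is shifted down by more than `dpk_threshold`;
#' `unaffected` when both the pK and the plateau agree within thresholds;
#' `complex` otherwise. Comparing a fit with itself yields `unaffected`.
#'
#' @param reference_fit wild-type `titration_fit`.
#' @param mutant_fit mutant `titration_fit`.
#' @param plateau_threshold alkaline-plateau difference calling a forward
#'   shift (fraction units).
#' @param dpk_threshold pK downshift calling Meta-I stabilization
#'   (pH units).
#' @return a `mutant_phenotype` list with `label` and `evidence`
#'   (`delta_plateau`, `delta_pK`, `two_state_ok`).
#' @export
classify_shift <- function(reference_fit, mutant_fit,
                           plateau_threshold = 0.2, dpk_threshold = 0.3) {
  stopifnot(inherits(reference_fit, "titration_fit"),
            inherits(mutant_fit, "titration_fit"))
  r_rng <- range(reference_fit$fractions$pH)
  m_rng <- range(mutant_fit$fractions$pH)
  if (m_rng[1] > r_rng[2] || m_rng[2] < r_rng[1]) {
    stop("pH ranges of the two fits do not overlap")
  }
  d_plateau <- mutant_fit$alkaline_plateau - reference_fit$alkaline_plateau
  d_pK <- mutant_fit$pK - reference_fit$pK
  label <-
    if (d_plateau > plateau_threshold ||
        (!mutant_fit$two_state_ok && d_plateau > plateau_threshold / 2)) {
      "forward_shifted"
    } else if (d_pK < -dpk_threshold) {
      "meta_I_stabilized"
    } else if (abs(d_pK) <= dpk_threshold &&
               abs(d_plateau) <= plateau_threshold &&
               mutant_fit$two_state_ok) {
      "unaffected"
    } else {
      "complex"
    }
  structure(list(label = label,
                 evidence = list(delta_plateau = d_plateau,
                                 delta_pK = d_pK,
                                 two_state_ok = mutant_fit$two_state_ok)),
            class = "mutant_phenotype")
}

#' @export
print.mutant_phenotype <- function(x, ...) {
  cat(sprintf("phenotype: %s (delta plateau %+.2f, delta pK %+.2f, two-state %s)\n",
              x$label, x$evidence$delta_plateau, x$evidence$delta_pK,
              x$evidence$two_state_ok))
  invisible(x)
}
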