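## Shared fixtures: everything is generated in code, nothing read from disk.

default_params <- function() buildup_params()

## noiseless, normalized calibration table under the default parameters
noiseless_calibration_table <- function(params = default_params()) {
  tab <- generate_buildup_dataset(calibration_geometry(), params,
                                  noise_rms = 0)
  normalize_to_control(tab, "C12-C20")
}

## brute-force all-pairs contact scan used as an oracle for
## enumerate_contacts(); works directly on the atom table
brute_force_contacts <- function(model, resid_a, elety_a, resid_b, elety_b,
                                 cutoff) {
  a <- model$atoms
  A <- a[a$resid == resid_a & a$elety == elety_a, ]
  B <- a[a$resid == resid_b & a$elety == elety_b, ]
  hits <- 0
  dists <- numeric()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    same <- A$resid[i] == B$resid[j] && A$resno[i] == B$resno[j] &&
      A$elety[i] == B$elety[j]
    if (same) next
    d <- sqrt(sum((unlist(A[i, c("x", "y", "z")]) -
                     unlist(B[j, c("x", "y", "z")]))^2))
    if (d <= cutoff) dists <- c(dists, d)
  }
  sort(dists)
}

## sum of two logistic titrations: a deliberately biphasic curve
biphasic_fractions <- function(pH = seq(4.5, 9.0, by = 0.5),
                               pK1 = 5.5, pK2 = 8.5) {
  data.frame(pH = pH,
             meta_IIbH = 0.5 * hh_fraction(pH, pK1) +
               0.5 * hh_fraction(pH, pK2))
}
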