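test_that("noiseless build-up tables equal the closed-form model exactly", {
  p <- default_params()
  tab <- generate_buildup_dataset(c("C12-C20" = 2.4), p, noise_rms = 0)
  expect_identical(tab$intensity,
                   simulate_buildup(2.4, p, default_mixing_grid()))
})

test_that("calibration-pair curves are strictly ordered by distance", {
  p <- default_params()
  geom <- calibration_geometry()
  tab <- generate_buildup_dataset(geom, p, noise_rms = 0)
  for (t0 in default_mixing_grid()) {
    sub <- tab[tab$t_mix_ms == t0, ]
    ord <- order(geom$distance[match(sub$pair, geom$pair)])
    expect_true(all(diff(sub$intensity[ord][!duplicated(
      geom$distance[match(sub$pair, geom$pair)][ord])]) < 0),
      info = sprintf("t = %d ms", t0))
  }
})

test_that("seeded generation is bit-reproducible", {
  a <- generate_buildup_dataset(calibration_geometry(), noise_rms = 0.02,
                                replicates = 3, seed = 99)
  b <- generate_buildup_dataset(calibration_geometry(), noise_rms = 0.02,
                                replicates = 3, seed = 99)
  expect_identical(a, b)
  s1 <- generate_titration_series(noise_rms = 0.01, seed = 7)
  s2 <- generate_titration_series(noise_rms = 0.01, seed = 7)
  expect_identical(s1, s2)
})

test_that("generator rejects invalid geometry and grids", {
  expect_error(generate_buildup_dataset(data.frame(pair = character(),
                                                   distance = numeric())),
               "empty")
  expect_error(generate_buildup_dataset(c(a = -1)), "positive")
  expect_error(generate_buildup_dataset(c(a = 2), grid = c(-5, 10)),
               "non-negative")
  expect_error(generate_buildup_dataset(c(a = 2, a = 3)), "unique")
})

test_that("toy structures realize prescribed distances and round-trip PDB", {
  path <- withr::local_tempfile(fileext = ".pdb")
  spec <- data.frame(selector_a = "RET:C20", selector_b = "TYR268:CZ",
                     distance = 4.1)
  m <- generate_toy_structure(spec, path = path)
  expect_equal(pair_distance(m, "RET:C20", "TYR268:CZ"), 4.1,
               tolerance = 1e-3)
  ## written file parses back to the same atoms
  m2 <- read_structure(path)
  expect_equal(nrow(m2$atoms), 2)
  expect_equal(pair_distance(m2, "RET:C20", "TYR268:CZ"), 4.1,
               tolerance = 1e-3)
})

test_that("multi-constraint toy placements are exact", {
  spec <- pocket_distance_table("rhodopsin-1u19")
  m <- generate_toy_structure(spec)
  for (i in seq_len(nrow(spec))) {
    expect_equal(pair_distance(m, spec$selector_a[i], spec$selector_b[i]),
                 spec$distance[i], tolerance = 1e-3,
                 info = paste(spec$selector_a[i], spec$selector_b[i]))
  }
})

test_that("toy structure rejects degenerate specs", {
  expect_error(generate_toy_structure(
    data.frame(selector_a = "A1:X", selector_b = "A1:X", distance = 3)),
    "duplicate")
  expect_error(generate_toy_structure(
    data.frame(selector_a = c("A1:X", "A1:X"),
               selector_b = c("B1:X", "B1:X"), distance = c(3, 4))),
    "duplicate")
  ## triangle inequality violation is caught
  expect_error(generate_toy_structure(
    data.frame(selector_a = c("A1:X", "A1:X", "B1:X"),
               selector_b = c("B1:X", "C1:X", "C1:X"),
               distance = c(1, 1, 5))),
    "not realizable")
})

test_that("titration series mix the basis by the Henderson-Hasselbalch law", {
  basis <- default_basis()
  ## at pH = pK the spectrum is the exact 50/50 mixture
  s <- generate_titration_series(pK = 6.8, pH = c(5.8, 6.8, 7.8),
                                 basis = basis, noise_rms = 0)
  mix50 <- 0.5 * basis$components[, "meta_IIbH"] +
    0.5 * basis$components[, "meta_I"]
  expect_equal(unname(s$spectra[, "pH=6.8"]), unname(mix50),
               tolerance = 1e-12)
  ## far below the pK the spectrum is the pure Meta-IIbH+ component
  s_lo <- generate_titration_series(pK = 9.5, pH = c(3.0, 4.0, 5.0),
                                    basis = basis, noise_rms = 0)
  expect_equal(unname(s_lo$spectra[, "pH=3"]),
               unname(basis$components[, "meta_IIbH"]), tolerance = 1e-6)
  ## ground-truth fractions are monotone non-increasing and within [0,1]
  f <- attr(generate_titration_series(), "fractions_true")
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("titration generator validates inputs", {
  expect_error(generate_titration_series(pH = c(5, 4, 6)), "increasing")
  expect_error(generate_titration_series(pH = c(2, 5, 8)), "within")
  expect_error(generate_titration_series(hill = 0), "hill")
  bad_basis <- basis_set(seq(1796, 1600, by = -4),
                         cbind(meta_I = rnorm(50), meta_IIbH = rnorm(50)))
  expect_error(decompose_spectra(generate_titration_series(), bad_basis),
               "grids")
})

test_that("crosspeak tables and spectrum series survive file round-trips", {
  tab <- generate_buildup_dataset(calibration_geometry(), noise_rms = 0.02,
                                  seed = 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_crosspeak_table(tab, f1)
  back <- read_crosspeak_table(f1)
  expect_equal(back$intensity, tab$intensity, tolerance = 1e-9)
  expect_equal(back$pair, tab$pair)

  s <- generate_titration_series(noise_rms = 0.01, seed = 5)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_series(s, f2)
  s2 <- read_spectrum_series(f2)
  expect_equal(s2$pH, s$pH)
  expect_equal(unname(s2$spectra), unname(s$spectra), tolerance = 1e-9)
})
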