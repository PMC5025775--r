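test_that("read_structure keeps the retinal and reports missing chains", {
  path <- withr::local_tempfile(fileext = ".pdb")
  synthetic_pocket_model("rhodopsin-1u19", path = path)
  m <- read_structure(path)
  expect_true(any(m$atoms$resid == "RET"))
  expect_true(all(m$atoms$type[m$atoms$resid == "RET"] == "HETATM"))
  expect_error(read_structure(path, chain = "Z"), "available chains")
  expect_error(read_structure("no-such-file.pdb"), "no file")
})

test_that("pair distances are symmetric, non-negative, zero on identity", {
  m <- synthetic_pocket_model("rhodopsin-1gzm")
  d1 <- pair_distance(m, "RET:C20", "TYR268:CZ")
  d2 <- pair_distance(m, "TYR268:CZ", "RET:C20")
  expect_identical(d1, d2)
  expect_gt(d1, 0)
  expect_equal(pair_distance(m, "RET:C20", "RET:C20"), 0)
  expect_error(pair_distance(m, "RET:C20", "TRP265:CZ2"), "does not resolve")
})

test_that("contact enumeration matches the brute-force all-pairs oracle", {
  m <- synthetic_pocket_model("rhodopsin-1u19")
  for (cutoff in c(0.5, 4.2, 6.0, 12)) {
    got <- enumerate_contacts(m, list(resid = "TYR", elety = "CZ"),
                              list(resid = "GLY", elety = "CA"), cutoff)
    oracle <- brute_force_contacts(m, "TYR", "CZ", "GLY", "CA", cutoff)
    expect_equal(nrow(got), length(oracle), info = sprintf("cutoff %g", cutoff))
    expect_equal(got$distance, oracle, tolerance = 1e-9)
  }
  ## results come back sorted and duplicate-free
  got <- enumerate_contacts(m, list(resid = "TYR", elety = "CZ"),
                            list(resid = "GLY", elety = "CA"), 6.0)
  expect_false(is.unsorted(got$distance))
  expect_false(any(duplicated(paste(got$selector_a, got$selector_b))))
  expect_warning(
    empty <- enumerate_contacts(m, list(resid = "TRP", elety = "CZ2"),
                                list(resid = "GLY", elety = "CA"), 6.0),
    "empty")
  expect_equal(nrow(empty), 0)
})

test_that("toy structures with prescribed placements enumerate exactly", {
  ## six Tyr CZ / Gly CA pairs at the published distances -> six contacts
  spec <- pocket_distance_table("rhodopsin-1u19")
  tyr_gly <- grepl("^TYR", spec$selector_a) & grepl("^GLY", spec$selector_b)
  m <- generate_toy_structure(spec[tyr_gly, ])
  got <- enumerate_contacts(m, list(resid = "TYR", elety = "CZ"),
                            list(resid = "GLY", elety = "CA"), 6.0)
  expect_equal(nrow(got), 6)
  expect_equal(sort(got$distance), sort(spec$distance[tyr_gly]),
               tolerance = 1e-6)
})

test_that("restraint construction maps statuses and rejects unmapped pairs", {
  est <- data.frame(pair = c("p1", "p2", "p3"),
                    r_hat = c(5.6, NA, NA), sigma = c(0.3, NA, NA),
                    status = c("estimated", "upper_bound_only", "absent"),
                    stringsAsFactors = FALSE)
  mapping <- list(p1 = c("RET:C12", "TYR268:CZ"),
                  p2 = c("RET:C20", "TYR268:CZ"),
                  p3 = c("RET:C19", "TYR268:CZ"))
  rs <- restraints_from_estimates(est, mapping)
  expect_equal(rs$type, c("POSITIVE", "UPPER", "ABSENT"))
  expect_equal(rs$r[1], 5.6)
  expect_equal(rs$limit[2:3], c(6.5, 6.0))
  expect_error(restraints_from_estimates(est, mapping[1:2]), "p3")
  empty <- restraints_from_estimates(est[0, ], mapping)
  expect_equal(nrow(empty), 0)
  ## TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(rs, f)
  expect_equal(read_restraints(f)$type, rs$type)
})

test_that("model scoring counts satisfied restraints and flags violations", {
  m_nmr <- synthetic_pocket_model("meta2-nmr")
  m_xtal <- synthetic_pocket_model("meta2-crystal")
  rs <- restraints_from_estimates(
    data.frame(pair = c("C12-Tyr268", "C20-Tyr268"),
               r_hat = c(5.6, 4.4), sigma = c(0.3, 0.3),
               status = "estimated", stringsAsFactors = FALSE),
    list("C12-Tyr268" = c("RET:C12", "TYR268:CZ"),
         "C20-Tyr268" = c("RET:C20", "TYR268:CZ")))
  s_nmr <- score_model(m_nmr, rs)
  expect_equal(s_nmr$score, 1.0)
  ## the crystal orientation puts C12 at 3.9 A: >10 sigma from 5.6 +/- 0.3
  s_xtal <- score_model(m_xtal, rs)
  expect_lt(s_xtal$score, 1.0)
  expect_true("C12-Tyr268" %in% s_xtal$violations$label)
  ## unresolvable selectors drop out of the denominator with a warning
  rs_bad <- rbind(rs, data.frame(label = "ghost", type = "POSITIVE",
                                 selector_a = "HIS211:NE2",
                                 selector_b = "RET:C16",
                                 r = 4, sigma = 0.3, limit = NA_real_))
  expect_warning(s3 <- score_model(m_nmr, structure(rs_bad,
    class = c("restraint_set", "data.frame"))), "unevaluable")
  expect_equal(s3$n_evaluated, 2)
  expect_equal(s3$score, 1.0)
})

test_that("scoring is invariant under rigid-body motion", {
  m <- synthetic_pocket_model("meta2-nmr")
  rs <- restraints_from_estimates(
    data.frame(pair = "C12-Tyr268", r_hat = 5.6, sigma = 0.3,
               status = "estimated", stringsAsFactors = FALSE),
    list("C12-Tyr268" = c("RET:C12", "TYR268:CZ")))
  ## random rotation + translation
  set.seed(4)
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(qr_R)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 11.3
  m2$atoms$y <- xyz[, 2] - 4.2
  m2$atoms$z <- xyz[, 3] + 0.7
  expect_equal(score_model(m2, rs)$score, score_model(m, rs)$score)
  expect_equal(score_model(m2, rs)$verdicts$d_model,
               score_model(m, rs)$verdicts$d_model, tolerance = 1e-9)
})

test_that("model discrimination ranks the NMR orientation first", {
  models <- list(nmr = synthetic_pocket_model("meta2-nmr"),
                 crystal = synthetic_pocket_model("meta2-crystal"))
  rs <- restraints_from_estimates(
    data.frame(pair = c("C12-Tyr268", "C20-Tyr268"),
               r_hat = c(5.6, 4.4), sigma = c(0.3, 0.3),
               status = "estimated", stringsAsFactors = FALSE),
    list("C12-Tyr268" = c("RET:C12", "TYR268:CZ"),
         "C20-Tyr268" = c("RET:C20", "TYR268:CZ")))
  out <- discriminate_models(models, rs)
  expect_equal(out$ranking$model_id[1], "synthetic-meta2-nmr")
  expect_false(any(out$ranking$tied))
  ## identical models tie explicitly
  tie <- discriminate_models(list(a = models$nmr, b = models$nmr), rs)
  expect_true(all(tie$ranking$tied))
  expect_error(discriminate_models(models["nmr"], rs), ">= 2")
})
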