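Package: rhodomet
Title: Distance Restraints and Titration Analysis for Rhodopsin Photointermediates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference tools for magic-angle-spinning solid-state NMR and FTIR
    studies of the rhodopsin Meta-II photointermediate. Models DARR crosspeak
    build-up as a function of internuclear carbon-carbon distance, calibrates
    the transfer model on pairs of known separation, and inverts observed
    build-up curves into distance estimates with Monte-Carlo uncertainties.
    Converts the resulting estimates into positive, upper-bound and
    absent-contact distance restraints and scores candidate retinal
    orientations in PDB coordinate models against them. On the FTIR side,
    decomposes pH series of difference spectra (1800-1600 1/cm) into Meta-I
    and Meta-IIbH+ reference contributions by sum-to-one non-negative least
    squares, fits the titration to a Henderson-Hasselbalch law for an apparent
    pK, and classifies mutant equilibrium phenotypes. Includes seeded
    synthetic-data generators (build-up tables, toy coordinate files,
    titration spectrum series) with known ground truth for parameter-recovery
    testing, plus carbon-13 chemical-shift referencing and bookkeeping
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
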