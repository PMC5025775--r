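# rhodomet

Distance restraints and titration analysis for rhodopsin photointermediates.

Rhodopsin's light-activated Meta-II state is characterized by two
complementary measurements: magic-angle-spinning solid-state NMR, where
DARR crosspeaks between ^13^C-labelled retinal and protein sites report
internuclear distances below ~6–6.5 Å, and FTIR difference spectroscopy,
where pH series of difference spectra track the Meta-I ⇔ Meta-IIbH⁺
protonation equilibrium. `rhodomet` implements the inference machinery for
both, for spectroscopists who want calibrated distances, restraint-based
model discrimination, and titration phenotypes from tabulated data.

## The models

**Build-up inversion.** Crosspeak intensity versus mixing time is modelled
as

    I(t) = A (1 − exp(−k(r) t)) exp(−t / T_damp),   k(r) = k_ref (r_ref / r)^6

The three free parameters are calibrated by a joint least-squares fit over
pairs of known separation (retinal C5–C18 1.4 Å; C8–C19 and C12–C20 2.4 Å;
Cys110 Cβ–Cys187 Cβ 3.6 Å; Cys187 Cβ–Gly188 Cα 4.6 Å; Cys187 Cβ–Gly188
C=O 5.3 Å). Observed curves are then inverted for the distance by
least squares, with parametric-bootstrap uncertainties, a 3σ detection
gate, and absent contacts reported only as ≥ 6.0 Å. Estimates become
POSITIVE / UPPER / ABSENT restraints used to score and rank candidate
retinal orientations in PDB coordinate models.

**Titration decomposition.** Difference spectra over 1800–1600 cm⁻¹ are
unmixed per pH point into Meta-I and Meta-IIbH⁺ reference contributions
(non-negative least squares with a sum-to-one constraint), and the
Meta-II fraction is fit to f(pH) = 1 / (1 + 10^(pH − pK)) for the apparent
pK. Mutant fits are classified against wild type as forward-shifted,
Meta-I-stabilized, unaffected, or complex.

Seeded synthetic-data generators produce every input with known ground
truth — build-up tables, toy coordinate files realizing prescribed pair
distances, and titration spectrum series — so the full pipeline is
testable by parameter recovery. See the methods vignette
(`vignettes/rhodomet-methods.Rmd`) for the assumptions and defaults.

## Worked example

```r
library(rhodomet)

## calibrate the build-up model on noisy synthetic curves of the
## known-distance pairs, normalized to the C12-C20 internal control
params <- buildup_params()
tab <- generate_buildup_dataset(calibration_geometry(), params,
                                noise_rms = 0.02, replicates = 2, seed = 1)
tab <- normalize_to_control(tab, "C12-C20")
cal <- calibrate_buildup(tab, calibration_geometry())
cal
#> DARR build-up parameters:
#>   k_ref    0.0201485 /ms at r_ref 2.40 A (exponent 6)
#>   T_damp   1477.21 ms
#>   amp      1.01869

## invert a Meta-II retinal-tyrosine curve into a distance
curve <- simulate_buildup(5.6, cal)
infer_distance(curve, cal, noise_rms = 0.02, n_mc = 200, seed = 2,
               assume_present = TRUE, pair = "C12-Tyr268")
#> C12-Tyr268: r = 5.60 +/- 0.25 A (estimated)

## decompose a titration series and fit the apparent pK
basis <- default_basis()
s <- generate_titration_series(pK = 6.8, noise_rms = 0.005, seed = 3)
fit_titration(decompose_spectra(s, basis))
#> titration fit [wild-type]: apparent pK 6.80 (hill 1.00)
```

The calibrated rate and damping recover the generator's values from noisy
data; the inverted distance reproduces the generating 5.6 Å with a
bootstrap uncertainty of ±0.25 Å at this noise level; and the
decomposition-plus-fit chain returns the generator's pK of 6.8.

`run_nmr_pipeline()` and `run_ftir_pipeline()` chain these steps end to
end (simulate → calibrate → infer → restrain → score, and simulate →
decompose → fit → classify) from a config list or JSON file;
`inst/scripts/run-pipeline.R` is a thin command-line wrapper over them.

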