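---
title: "Models and methods behind rhodomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhodomet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodomet)
```

rhodomet implements the quantitative machinery used to characterize the
active Meta-II photointermediate of rhodopsin from two kinds of
measurement: magic-angle-spinning solid-state NMR distance restraints
between ^13^C-labelled sites (DARR crosspeaks), and FTIR difference-spectrum
titrations of the Meta-I ⇔ Meta-IIbH^+^ equilibrium. This vignette explains
the models, the defaults and why they were chosen, what the synthetic-data
generators do and do not emulate, and the numerical decisions a user should
know about.

## The DARR build-up model

In a 2D DARR experiment, a crosspeak between two ^13^C resonances appears
when the carbons are closer than roughly 6–6.5 Å, and its intensity grows
with the mixing time during which magnetization exchanges. No closed-form
intensity law is dictated by the experiment itself, so the package adopts
the minimal model that reproduces the observed rise-and-decay shape:

$$I(t) = A\,\bigl(1 - e^{-k(r)\,t}\bigr)\,e^{-t/T_\mathrm{damp}},
\qquad k(r) = k_\mathrm{ref}\left(\frac{r_\mathrm{ref}}{r}\right)^{n}.$$

A first-order transfer with a rate falling off as $r^{-6}$ captures the
dipolar origin of proton-driven spin diffusion; the exponential damping
models relaxation losses at long mixing. The exponent $n$ defaults to 6 but
is configurable, because build-up in multi-spin systems can deviate from
the ideal two-spin behaviour. Relayed transfer and chemical-shift-dependent
efficiencies are deliberately out of scope.

Parameters and defaults, chosen once:

* `r_ref = 2.4` Å — the intra-retinal C12–C20 separation, fixed in every
  photointermediate, which also serves as the normalization control.
* `k_ref = 0.02` ms^-1^ — transfer time constant of 50 ms at the reference
  distance, which puts the build-up of the 1.4–5.3 Å calibration pairs
  inside the sampled mixing-time window.
* `T_damp = 1500` ms, `amp = 1` (after normalization).
* mixing grid `{50, 100, 200, 400, 600, 800}` ms — six points spanning the
  initial rise through the damped plateau; the experimental grid is not
  published, so this is a package default.
* generator noise `noise_rms = 0.02` (intensities normalized to a control
  plateau of 1). With the defaults this puts the clean-signal 3σ detection
  crossing near 5.5–5.6 Å: a crosspeak at 5.6 Å sits right at the
  detection edge — mirroring the marginal, weak Meta-II crosspeaks near
  the observability band — while a 7 Å pair goes undetected in ≈96% of
  replicates.

### Calibration

`calibrate_buildup()` fits $(k_\mathrm{ref}, T_\mathrm{damp}, A)$ jointly
(Levenberg–Marquardt) over curves of pairs with known distances — the
intra-retinal C5–C18 (1.4 Å), C8–C19 and C12–C20 (2.4 Å) pairs and the EL2
backbone pairs at 3.6, 4.6 and 5.3 Å. A joint fit was chosen over per-pair
fits because the saturated short-distance curves pin the amplitude and
damping while the longer distances pin the rate constant; three distinct
distances are the identifiability minimum and fewer are rejected.
Mislabelled calibration distances are screened by deletion: the worst pair
is removed, the model refit, and the pair flagged when its residual under
the clean fit exceeds five times the median of the others.

### Inversion and uncertainties

`infer_distance()` minimizes the squared deviation between the observed
curve and the model over $r \in [1, 8]$ Å (golden-section search with a
local polish; a 0.001 Å brute-force grid search is used as an oracle in the
tests and agrees to < 0.05 Å). Because $I(t;r)$ is strictly decreasing in
$r$ at every $t>0$, the minimum is unique on the search interval — except
in the fully saturated regime ($r \lesssim 1.4$ Å under the defaults) where
curves coincide to machine precision; there the flat region is detected
explicitly, its shorter edge reported and the uncertainty widened to cover
it. Note that strict monotonicity holds mathematically everywhere but
collapses to ties in double precision for saturated curves; the tests
assert strictness only where the transfer is unsaturated.

Uncertainties are parametric-bootstrap standard deviations: 500 seeded
replicates of the best-fit curve plus Gaussian noise at the stated RMS,
each re-inverted. Estimates beyond 6.5 Å are reported as
`status = "absent"` (compatible with no observable crosspeak) rather than
as numbers; detection itself is a 3σ threshold on the maximum intensity,
the conventional choice given that only the 6–6.5 Å observability band is
stated experimentally.

The experiment quotes its distance uncertainty (± 0.3 Å) rather than an
intensity SNR. `noise_for_sigma()` converts one into the other: a
first-order delta-method estimate $\sigma_I = \sigma_r\,\lVert\partial
I/\partial r\rVert_2$, optionally refined by Monte-Carlo passes that
rescale the noise until the realized replicate spread matches the target.
The refinement matters because the $r^{-6}$ nonlinearity makes the
estimator's distribution right-skewed at this noise level, so the
first-order value understates the spread; the same skew gives the
replicate mean a small (≈ +0.05 Å) bias that is a property of the
estimator, not of the implementation.

## Chemical-shift bookkeeping

Shifts are stored with their referencing compound; TMS↔DSS conversion is
the exact ±2.01 p.p.m. offset. A state-to-state change is called
downfield/upfield only beyond ±0.2 p.p.m., the reproducibility bound of
repeated preparations. The hydrogen-bond direction rule — downfield Cβ
shift means increased Cβ–OH hydrogen bonding — is implemented only for
serine Cβ sites and refuses anything else: the analogous reading for
tyrosine Cζ is plausible but not established, so the package does not
formalize it.

## Structures, contacts and restraint scoring

`read_structure()` wraps bio3d's PDB parser, restricts to one chain (first
protein chain by default — deposited rhodopsin structures contain two
copies, and published distances are assumed to refer to one), and keeps
HETATM records so the retinal (`RET`, atoms C1–C20, PDB v3 names) stays
addressable. Distances are kept at full precision and rounded to 0.1 Å
only when compared against published values.

Distance estimates become restraints in three flavours: POSITIVE
($r \pm \sigma$), UPPER (≤ 6.5 Å, crosspeak observed but unquantified) and
ABSENT (≥ 6.0 Å, crosspeak not observed). Splitting the stated "6–6.5 Å"
band this way is conservative: a model distance inside the ambiguous zone
satisfies both bound types. `score_model()` counts satisfied restraints
(POSITIVE within $2\sigma$ by default) and `discriminate_models()` ranks
models by score, breaking ties by the summed normalized violation
magnitude; scoring depends only on internal distances and is therefore
invariant under rigid-body motion, which the tests verify.

Because the deposited crystal structures cannot be assumed present on
disk, the package ships `synthetic_pocket_model()`: toy coordinate files,
built by `generate_toy_structure()`, that realize the *published* pairwise
distances exactly (sequential geometric placement — fresh axis, circle
intersection, or trilateration — with disconnected constraint groups
offset 25 Å apart). These are geometric stand-ins, explicitly labelled
synthetic: they reproduce the published distance tables and nothing else
about the structures, and tests against them validate the package's
read/measure/enumerate path, not the crystallography.

## FTIR decomposition and titration

Difference spectra over 1800–1600 cm^-1^ (4 cm^-1^ resolution) are
decomposed per pH point onto reference spectra by non-negative least
squares with a sum-to-one constraint imposed as an augmented equality row —
exact on any noiseless in-span mixture, with the basis condition number
reported and degenerate bases rejected. The Meta-II fraction versus pH is
then fit to the Henderson–Hasselbalch law
$f(\mathrm{pH}) = 1/(1+10^{h(\mathrm{pH}-\mathrm{p}K)})$ with the Hill
slope fixed at 1 by default (a single apparent pK is what the experiment
reports; freeing the slope is available as an option). A fit is flagged
non-two-state when any per-point residual exceeds 0.05 — this is what
biphasic titrations trip. A pK more than one unit outside the sampled pH
range is flagged extrapolated.

The default synthetic basis is a documented invention: the two components
differ in an amide-I band near 1644/1661 cm^-1^ and in carboxylic C=O
marker bands between 1700 and 1780 cm^-1^, all Gaussian with widths
8–15 cm^-1^. Only the window and the 4 cm^-1^ step are experiment-fixed.
When no reference spectra are available, the lowest- and highest-pH
spectra of a series can serve as proxy basis (`basis_set()` accepts any
matrix on the grid), a fallback that inherits whatever contamination those
endpoint spectra carry.

Mutant phenotypes are classified against wild type with two documented,
invented thresholds chosen to separate the qualitative categories
robustly: a forward shift needs > 0.2 more Meta-II at the alkaline
endpoint (or a non-two-state titration with an elevated plateau), Meta-I
stabilization needs a pK downshift > 0.3 units; agreement within both
thresholds is "unaffected", anything else "complex". Comparing a fit with
itself always yields "unaffected".

## What the synthetic generators do and do not emulate

The generators produce: build-up tables with the closed-form intensities
plus i.i.d. Gaussian noise; toy coordinate files with exact pair
distances; titration series mixed by the logistic law (with an optional
`alkaline_floor` to emulate forward-shifted mutants that retain Meta-II at
high pH). They do **not** simulate 2D frequency-domain spectra, lineshapes,
relayed multi-spin transfer, correlated or baseline noise, Meta-II decay
kinetics, or temperature-dependent substate structure. Passing
parameter-recovery tests therefore demonstrates that the inference
machinery is correct and well-conditioned under the stated noise model —
not that the simple build-up law captures every systematic effect in real
spin diffusion.

## Problem sizes and determinism

All simulation-based checks are sized for interactive use: 200 replicates
for detection and titration noise studies, 400–500 for Monte-Carlo
uncertainty and recovery runs — past which the Monte-Carlo error on the
quantities checked is well below the tolerances asserted. Every stochastic
path takes an explicit integer seed, and identical configuration plus seed
reproduces outputs bit-for-bit.

## Known limitations

* The build-up law is phenomenological; absolute calibrated rates are only
  as transferable as the labelling scheme and spin environment allow.
* Distance estimates near the detection edge are biased upward by
  selection and by the $r^{-6}$ nonlinearity; the package reports the
  bootstrap spread but does not de-bias the point estimate.
* The stand-in pocket models carry no stereochemistry; they cannot be used
  for anything beyond distance bookkeeping.
* The two-component decomposition assumes the pH series stays within the
  span of the basis; additional substates present at higher temperature
  would require a larger basis.
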