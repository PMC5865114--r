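---
title: "Modeling time-dependent memory transformation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling time-dependent memory transformation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistmem)
```

# The scientific problem

Episodic memories transform with time: perceptual detail fades while the
semantic gist persists. The paradigm `gistmem` models probes this with a
recognition test containing three picture types — studied (*old*) pictures,
*related lures* sharing the gist of a studied picture, and unrelated
*novel* pictures — administered to two groups tested at different delays
(1 day vs 28 days after encoding). A "yes" to a related lure is a
gist-driven false alarm; jointly with the response to the corresponding old
picture it classifies each pair as **detailed** (old endorsed, lure
rejected), **transformed** (lure endorsed, irrespective of the old
response) or **forgotten** (both rejected). On the imaging side, ROI-level
deconvolution, representational similarity analysis (RSA) and
task-dependent connectivity (gPPI) ask how hippocampal representations —
especially along the anterior–posterior axis — change with memory age.

This vignette records the models the package implements, the free
parameters and their defaults, the numerical conventions, and the design
decisions taken where more than one reasonable choice existed.

# Behavioral scoring

Hit and false-alarm percentages use only trials that received a response;
a trial without a button press neither counts as an error nor enters the
denominator, and a picture type with no responded trials yields `NA`
rather than 0%. This convention is ours: the source paradigm does not
state how non-responses enter the rates (they are grouped with incorrect
answers only in the confidence-conditioned GLM), and excluding them keeps
the rate a genuine conditional probability.

The confidence score sums the 0–3 rating over hits (not at all = 0 …
very confident = 3), so 60 old pictures bound it at 180. It is kept as an
integer; percentages are real-valued.

Pair categorization follows the three rules above verbatim; any pair with
a non-response member is reported separately as *unclassified*, so the
four categories always partition the 60 pairs (the test suite enumerates
all 9 response combinations to verify totality).

# The synthetic cohort

Because no participant data ship with the package, the `synthetic_data`
module generates cohorts with the statistical structure the analyses
assume. Its defaults are the study conditions: 24 subjects per delay
group; 60 old/related pairs plus 60 novels, half emotionally negative;
TR 2.5 s with 832 retained scans; 3.5 s picture presentations separated by
uniform 7 ± 2 s fixation.

**Memory states.** Each pair draws one latent state — detailed, gist
(transformed), forgotten — from its group's categorical distribution.
Defaults are 1 d ≈ (0.70, 0.15, 0.15) and 28 d ≈ (0.30, 0.35, 0.35);
these are free parameters chosen once to reproduce the qualitative delay
pattern (fewer detailed, more transformed and forgotten pairs at 28 d),
not estimates of any real rates. Negative pairs receive an additive shift
(default 0.25) on the log-odds of the transformed and forgotten states
relative to detailed, a multinomial-logit formulation that keeps the
triple a valid distribution for any shift.

**Responses.** A detailed pair produces a hit with confidence drawn from a
distribution concentrated on 3 (default (0, .05, .15, .80) over 0–3) and a
correct rejection of the lure. A gist pair produces a lure endorsement
with mid-range confidence ((.10, .40, .40, .10)) and endorses the old
picture with probability 0.5 — the paradigm does not constrain how often
gist-only memory also accepts the original, so this is an explicit free
parameter (`p_old_yes_gist`). Forgotten pairs reject both. Novel pictures
draw false alarms at 5%. All of these are configurable.

**Voxel patterns.** For each ROI, trial patterns follow
`pattern = a·g + b·u + ε` with all latent vectors standard normal per
voxel: `g` is shared between an old picture and its related lure (novel
trials get their own `g`), `u` is trial-unique, `ε` is i.i.d. noise. The
expected old–lure correlation is `a²/(a²+b²+σ²)`; the default a = b = σ = 1
gives 1/3, and the gist weight defaults decline along the long axis
(aHC 1.0, mHC 0.7, pHC 0.4) to emulate stronger gist coding anteriorly.
An alternative `sharing = "old"` regime gives all old trials one common
component (the structure the "Old Distinct" model describes) for
recovery studies. Latent vectors are resampled per subject; nothing is
shared between subjects. 100 voxels per ROI by default.

**BOLD.** Condition responses are duration-boxcars convolved with the
canonical HRF (a duration-0 event is a unit impulse, so a single stick
reproduces the sampled HRF exactly); the microtime grid is 0.1 s and
boxcar bins are weighted by the grid step so the result approximates the
continuous convolution independently of the grid. Added to this are a slow
sinusoidal drift (periods 300 s and 180 s, random phases) and AR(1)
Gaussian noise (φ = 0.3, innovation SD 1) initialized from its stationary
distribution.

**Reproducibility.** Subject *k* uses an RNG stream seeded at
`(master_seed + 7919·k) mod (2³¹ − 1)`, so any subject can be regenerated
in isolation and the whole cohort is byte-identical under a fixed master
seed.

**What the generator does not emulate.** Spatial structure (no voxel
topology, no smoothing), physiological noise beyond drift + AR(1),
multi-run sessions, encoding-phase data, and any coupling between memory
states and pattern content or BOLD amplitude. Tests passing on these
cohorts therefore validate the estimators' statistical behavior, not
claims about real tissue.

# GLM and FIR conventions

- **Canonical HRF**: double-gamma with response peak 6 s, undershoot peak
  16 s, 1/6 amplitude ratio, normalized to unit peak; kernel support 48 s
  (the undershoot tail beyond that is < 10⁻⁷ of the peak).
- **High-pass filtering** is part of the model, not a preprocessing step:
  a discrete-cosine basis with `floor(2·N·TR/cutoff) + 1` columns
  including the constant (33 columns for 832 scans × 2.5 s at 128 s).
  Orthonormal by construction, so drift terms are exactly orthogonal to
  the constant and OLS stays exact and testable.
- **FIR basis**: 7 stick columns per condition at lags 0…6 TR (0–15 s at
  TR 2.5 s); onsets are assigned to the nearest scan (`round(onset/TR)`).
- **AR(1) prewhitening**: a single pooled φ estimated once from the OLS
  residuals' lag-1 autocorrelation, both sides filtered (first sample
  scaled by √(1−φ²)), one refit. The estimator is deliberately simple and
  global per series; the source methods do not specify one.
- **Peak window**: conditions are collapsed within participant, the bin
  with the maximal group mean is the numerical peak, and every other bin
  is compared to it with an uncorrected two-tailed paired t-test; the
  window is the peak plus all bins with p > 0.05, shared across conditions
  within an ROI. With the paradigm's timing this typically selects the
  5 s and 7.5 s bins in hippocampal ROIs, which the test suite reproduces
  on a simulated cohort whose planted response has equal ordinates at
  those two latencies.
- **Single-trial patterns**: least-squares-all (every trial regressor in
  one model, drift included), t = β/SE per voxel; least-squares-separate
  is available (`method = "lss"`) but not the default, matching the
  single-GLM description of the source analysis.
- **Long axis**: inclusive MNI Y bands, pHC [−40, −30], mHC [−29, −19],
  aHC [−18, −4]; everything else is `outside`.
- **gPPI**: the "neural level" of a condition is its unconvolved boxcar at
  TR resolution; the seed enters as its mean-centred BOLD time course
  directly — no hemodynamic deconvolution, which is ill-posed and
  unspecified in the source description. The interaction is
  (boxcar × centred seed) convolved with the HRF; the model holds the six
  psychological regressors, six interactions, the raw seed and the drift
  set. Interactions indistinguishable (|r| > 0.999) from the seed's own
  hemodynamic response or the psychological regressors are reported in
  `$collinear`. The seed time course is taken as the ROI mean (not the
  first eigenvariate), consistent with the ROI-averaged FIR analyses.
- **Event timing** is in seconds from the first retained scan (the first
  four volumes of the emulated acquisition are discarded before analysis
  begins, so 832 of 836 scans remain).

# RSA conventions

Dissimilarity is 1 − Pearson r between trial t-patterns; diagonals are 0
and values lie in [0, 2]. Lower-triangle vectorization (row-major over
i > j) is the fixed ordering for all summary statistics. Mean pattern
similarity averages raw r (no Fisher z; an option exists) over the strict
lower triangle. Rank scaling for visualization ranks the lower-triangle
population (average ranks for ties), maps ranks linearly onto [0, 1] and
mirrors — each unordered trial pair is ranked once. Cross-group similarity
is the Spearman correlation of lower triangles, and Spearman (average
ranks for ties) is used for all model fits, since no linear mapping
between binary hypotheses and correlation distances can be assumed.

**Model RDMs.** "Old Distinct" places 0 in old–old cells, "Old and
Related Similar" places 0 in all cells within {old, related}; everything
else is 1. The hypotheses say nothing about related–related and
novel–novel cells (for "Old Distinct") or novel–novel cells (for "Old and
Related Similar"); by default those cells are filled with 1 (a fully
binary model), and a masked variant excludes them from fits entirely.
Both variants are exposed because the choice is genuinely open; the
default was fixed for reproducibility rather than on scientific grounds.
For generative recovery studies the package uses the masked fits: scoring
each model only on cells it actually constrains makes the comparison a
contrast between the hypotheses rather than between their arbitrary
completions.

# Statistics

The mixed ANOVA handles one between-subject factor and up to two
within-subject factors with one observation per subject × cell. Sums of
squares come from `aov()` error strata; designs are required to be
balanced, where the Type I/II/III distinction vanishes (the test suite
verifies exact agreement with the multivariate-regression route of
`car::Anova` under sum-to-zero contrasts). Generalized η² is
`SS_effect / (SS_effect + ΣSS_error)` with the sum over all error strata
and no factor declared "observed". For within effects with more than two
levels, Mauchly's test and the Greenhouse–Geisser ε are computed from the
pooled within-group covariance of orthonormal-contrast-transformed
responses; corrected and uncorrected p-values are reported side by side.
Normality reports (Shapiro–Wilk) are always available, and ANOVAs are not
gated on them — with these cell counts the F-tests are robust to the
violations the rates typically show.

Welch's t is the default between-group test (pooled-SD Cohen's d);
paired t uses mean difference over SD of differences for d, and reports a
constant nonzero difference as an explicit error rather than an infinite
t. The Pearson–Filon z compares two overlapping dependent correlations
sharing one variable:
z = (r₁₂ − r₁₃)√n / √((1−r₁₂²)² + (1−r₁₃²)² − 2k) with
k = r₂₃(1 − r₁₂² − r₁₃²) − ½ r₁₂ r₁₃ (1 − r₁₂² − r₁₃² − r₂₃²).
This is the classical asymptotic form; at n ≈ 48 it runs slightly liberal
(true level ≈ 6% at α = 5% in our simulations), which is a property of
the statistic, not of the implementation — the asymptotic covariance term
is verified against brute-force simulation in the test suite. Bonferroni
correction across ROIs is applied at the reporting level only, never
inside estimators.

# Numerical choices and degenerate inputs

- Zero-variance inputs error with the offending trial/column named:
  constant patterns in `compute_rdm()`, collinear design columns in
  `fit_glm()`, constant vectors in `shapiro_wilk()`.
- Rate denominators of zero yield `NA` (flagged missing), never 0.
- A flat FIR curve set selects all 7 bins; identical collapsed curves
  compare with p = 1 by convention (zero-variance paired difference of
  exactly zero).
- Correlation-matrix triples passed to the Pearson–Filon test must be
  positive semidefinite (checked by eigenvalue, tolerance −10⁻¹⁰).
- Probability triples must sum to 1 within 10⁻¹²; RDM symmetry is
  enforced at 10⁻¹².

# Problem sizes used in the test suite

The suite exercises the estimators at sizes chosen to keep the default
run around a minute while leaving the tested properties scale-free:
BOLD-level checks mostly use 200–400-scan runs (the full 832-scan
geometry is used where the run length itself matters, e.g. drift-column
counts and the 179-trial RDM propagation); Monte-Carlo calibrations use
40–500 replicates in the unit tests and 2,000 for the Pearson–Filon null;
generative model-recovery uses 100 simulated subjects per regime. The
acceptance script re-runs the principal quantities at these same sizes
from a single command-line seed.

# Known limitations

- The ANOVA requires balanced designs; unbalanced data must be handled
  upstream (the source analyses are balanced by design).
- No signal-detection modeling (d′/criterion): raw rates only.
- No searchlight RSA, crossnobis distances or noise ceilings; no
  voxelwise whole-brain inference — the package is ROI-level throughout.
- gPPI without deconvolution attenuates interaction estimates when the
  true modulation is neural; a ridge-deconvolution variant is a natural
  extension point (`build_gppi_model()` isolates the neural-level step).
- The synthetic cohort's pattern model is exchangeable across voxels;
  analyses sensitive to spatial autocorrelation cannot be studied with it.
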