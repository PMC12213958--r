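---
title: "Models and methods behind smeloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smeloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smeloc)
```

`smeloc` is a desk-scale pipeline for studying encoding-phase EEG
predictors of children's source memory — the subsequent memory effect
(SME) — at both the scalp and the cortical-source level. Because the
participant data such studies rest on are not publicly available, the
package pairs the analysis pipeline with a synthetic-study generator whose
ground truth is fully known, so every stage (forward model, preprocessing,
ERP scoring, eLORETA inverse, group statistics) can be validated end to
end. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not establish about real recordings.

## The scientific setting

During encoding, two event-related potential (ERP) components carry
information about whether the source (context) of an item will later be
remembered: an early frontal positivity (P2, peaking between 120 and
250 ms after stimulus onset) and a late slow wave (LSW, a sustained
positivity at roughly 1100–1500 ms). The analysis contrasts encoding trials
whose source is later remembered correctly ("source correct") with those
remembered incorrectly ("source incorrect"), at the scalp via a 2 × 3 × 3
within-subject ANOVA over channel clusters, and in source space via current
density reconstruction (CDR) scores inside anatomically and fMRI-informed
regions of interest (ROIs), compared by paired t-tests under
Benjamini–Hochberg false-discovery-rate control with hemispheres corrected
separately.

## Head model and forward solution

The head is modeled as concentric homogeneous spherical shells
(`make_head()`); the default is a four-shell child-sized head — brain
(radius 0.08 m, 0.33 S/m), CSF (0.082 m, 1.79 S/m), skull (0.087 m,
0.01 S/m), scalp (0.092 m, 0.43 S/m). Conductivities are standard
literature values and are configuration-exposed; no claim is made that
they are subject-specific. The spherical substitution for a
finite-element head model is deliberate: it admits an exact series
solution, which makes the forward model *testable* — the equal-conductivity
case must match the closed-form homogeneous-sphere potential, and the test
suite holds it to 1e-6 relative error.

For a current dipole inside the innermost shell the potential is expanded
in Legendre harmonics; per degree $n$ the radial solution in each shell is
$A r^n + B r^{-(n+1)}$, with coefficients fixed by continuity of potential
and radial current density at every interface and zero current at the
scalp–air boundary. Two numerical points matter:

* **Per-shell normalization.** The radial basis in shell $k$ is normalized
  to that shell's outer radius, so the interface equations only involve
  ratios of adjacent radii. Without this the linear systems become
  numerically singular near $n \approx 100$; with it the series is stable
  beyond $n = 240$.
* **Truncation.** The series is truncated at $L = 60$ by default. For
  sources at up to 0.8 of the innermost radius (the grey-matter band
  reaches 0.85) the truncation error is below 1e-8 relative; doubling $L$
  changes nothing at working precision.

Electrodes are projected radially onto the outer shell before evaluation
(the analytic solution requires on-sphere sensors); the projection distance
is kept as a quality-control field. The lead field is assembled grid-major
with x/y/z moment columns per grid point, in μV per nA·m, and the
average-reference centering $H = I - \tfrac1n \mathbf{1}\mathbf{1}^T$ is
applied to its rows, mirroring the offline average re-referencing of the
data. Montage-to-head registration uses the Umeyama least-squares rigid
(optionally scaled) transform over named fiducial landmarks.

## Source space and ROI masks

The source space is a cubic lattice (default 3 mm pitch for production
use; the bundled demonstrations use 12 mm) clipped to a spherical
grey-matter band at 0.55–0.85 of the innermost radius. Eye sources are not
modeled: in the original tooling they exist to support ocular-artifact
modeling, which is out of scope here. Hemisphere labels follow the sign of
the lateral coordinate with a declared midline band of half a grid step.

Two mask families mimic the study's ROI sets: a bilateral medial-temporal
family (rostral and caudal parahippocampal gyrus, lateral and medial
posterior parahippocampal cortex, entorhinal cortex, temporal agranular
insula; six masks per hemisphere) seeded in the inferior-medial band of
the grid, and an fMRI-informed family (left IPL/SPL, IOG, left ITG, left
IFG, FuG, OFG) at frontal/parietal/occipital/temporal loci. Masks are
grown by nearest-neighbour accretion from fixed seed directions, are
disjoint within a family, and carry hemisphere and family tags. They are
*synthetic stand-ins*: they reproduce the ROI bookkeeping (names,
laterality, family-wise correction structure), not real anatomy.

## The synthetic study and its ground truth

`simulate_subject()` realizes a per-subject recording from a
`make_ground_truth()` record:

* **Components.** The P2 source time course is a Gaussian bump (default
  FWHM 50 ms) preceded by an N1-like negativity (115 ms, relative
  amplitude 0.5); the LSW is a logistic-onset plateau (onset 1050 ms, rise
  40 ms) that saturates within the 1100–1500 ms analysis range. The N1 is
  not incidental: the analysis re-baselines P2 epochs to the 130–140 ms
  interval — in real ERPs the trough between components. A lone Gaussian
  P2 would leak into that interval by a latency-dependent amount and the
  re-baselining would subtract away most of the planted effect for
  early-latency subjects; with the N1 in place the interval is a genuine
  trough and the planted contrast survives the prescribed re-baselining.
* **Latencies.** Each subject draws one P2 peak latency
  (190 ± 15 ms SD, truncated to 130–240 ms), consistent with a
  child-aged P2 and with per-subject window extraction.
* **Amplitudes and the planted effect.** Active sources sit at the first
  three grid points of each effect ROI, radially oriented with the sign
  chosen so the frontal scalp projection is positive. Population condition
  means are 45/33 nA·m (P2, correct/incorrect) and 42/30 nA·m (LSW). Each
  subject adds an effect deviation per (component, ROI), drawn with SD
  15 nA·m, so the planted standardized effect is
  $d = (45-33)/15 = 0.8$ per ROI. Deviations are independent across ROIs
  — subjects vary region by region in how strongly they express the
  effect — which makes the ROI-level statistics approximately independent
  draws rather than one shared coin flip per component. Defaults plant the
  P2 effect in all six left medial-temporal masks plus OFG and the LSW
  effect in left EC and the left parahippocampal masks, matching the
  qualitative result pattern the pipeline is meant to detect.
* **Noise and artifacts.** Sensor noise is white (6 μV SD) plus 1/f
  (6 μV SD, exponent 1), per channel and trial. Trial amplitudes jitter
  with CV 0.2 and subjects carry an overall scale factor with CV 0.15. A
  configurable fraction of trials (default 5%) receives a 350 μV
  low-frequency (1.25 Hz) artifact with an anterior–posterior topography,
  guaranteed to exceed the ±200 μV rejection rule.

Everything is a pure function of the design and the subject seed;
`simulate_study()` writes float32 epochs with JSON sidecars plus a hashed
manifest, and a rerun with the same master seed is byte-identical.

## Preprocessing and scalp ERP analysis

Preprocessing follows the recording protocol the pipeline targets: robust
bad-channel detection, subject exclusion beyond 8 bad channels, Perrin-style spherical
spline interpolation (order 4, 50 Legendre terms, ridge 1e-5), zero-phase
0.1–30 Hz band-pass, rejection of any trial exceeding ±200 μV, average
re-referencing, and exclusion below 10 surviving trials per condition.

Bad channels are judged on the noise they carry, not on the evoked signal:
the across-trial mean waveform is removed per channel and the residual
variance is screened — flatline channels directly, and otherwise a robust
z score of the log residual variance above 5 combined with a four-fold
deviation from the channel median. Screening raw variance instead would
conflate signal topography with channel faults: in a quiet recording,
channels rich in evoked activity legitimately carry several-fold more raw
variance than quiet ones.

The filter is a Hamming windowed-sinc FIR applied by FFT convolution with
reflective edge padding and exact group-delay removal, so it is strictly
zero-phase (a symmetric pulse stays symmetric to 1e-9). On 1.6-s epochs
the achievable low-edge transition is about 2 Hz — a genuinely sharp
0.1 Hz high-pass would need tens of thousands of taps — so the 0.1 Hz
cutoff is nominal on epoched data; this is a property of any epoch-domain
filter, and is why the slow LSW is quantified against its own re-baseline
rather than against DC.

Component windows follow the collapsed-localizer logic: the grand average
over all trials, conditions and subjects suggests the P2 search range (the
contiguous positive frontal deflection overlapping 120–250 ms); each
subject's P2 window is 50 ms centered on the *median* of per-trial frontal
peak latencies within the range (lower median for even counts; argmax ties
resolve to the earliest sample), and the LSW window is fixed at
1175–1225 ms for all subjects. Re-baselining subtracts the per-trial,
per-channel mean over 130–140 ms (P2) or 610–620 ms (LSW). Cluster
amplitudes average over trials, in-window samples and the channels of each
coronal × sagittal cell; the montage assigns cells by rank tertiles of the
anterior–posterior and left–right coordinates.

The 2 (condition) × 3 (coronal) × 3 (sagittal) within-subject ANOVA is
computed from the balanced cell-mean decomposition, with every
condition-involving effect tested against its interaction with subjects,
and only condition-involving effects reported. No sphericity correction is
applied by default (Greenhouse–Geisser is available by flag); the
condition main effect has one numerator degree of freedom and is
unaffected. Post hoc condition contrasts use estimated marginal means
within coronal × sagittal (or sagittal-only) cells: the contrast is the
mean per-subject condition difference in the cell, its standard error
pools the difference variance across the cells of the slice
(df = cells × (n−1)), and the Tukey adjustment evaluates the studentized
range with the total number of cell means in the family. With only two
conditions in a single cell the adjustment reduces to the unadjusted
paired comparison, as it should.

## eLORETA inverse and CDR scoring

The inverse is eLORETA: a weighted minimum-norm solution whose per-source
3 × 3 weights satisfy $W_j = (K_j^T M K_j)^{1/2}$ with
$M = (K W^{-1} K^T + \alpha c H)^{+}$, iterated to a relative block change
below 1e-6 (default cap 100 iterations; non-convergence returns the best
iterate with a warning). Pseudo-inverses use an eigenvalue floor of 1e-12
relative. The defining property — exact localization of noiseless point
sources at $\alpha = 0$ — is verified on a ~550-point grid with a 100%
hit rate in the test suite. One algebraic note: the weight fixed point is
invariant to an overall lead-field scaling (the inverse operator scales
inversely, leaving recovered moments in physical units); the tests assert
this invariance.

Regularization defaults to $\alpha = 0.05$ as a fraction of the mean
sensor-space eigenvalue for noisy data and 0 for noiseless property tests.
The inverse is applied to the condition-specific trial-average ERP over
each component window (not to single trials), re-baselined per component.
The CDR score at a grid point is the Euclidean norm of the moment vector
at each window sample, averaged over samples (norm-then-average; the
alternative average-then-norm would cancel moment rotations and
under-report sustained activity). ROI scores are arithmetic means over
member grid points; raw means are used (no normalization), with the
condition contrast taken as correct minus incorrect.

## Group inference

Per ROI and component, a classical paired t-test compares the per-subject
ROI means between conditions (df = n−1, two-sided; exactly-zero-variance
differences are flagged degenerate rather than silently producing NaN).
Benjamini–Hochberg correction is applied within correction families of
hemisphere × mask family × component for the bilateral medial-temporal
set, and mask family × component for the fMRI-informed set, reflecting
hemisphere-separate correction for bilateral ROIs. Two-sided tests are
kept despite the directional hypothesis because reversed scalp effects are
a real phenomenon in this design.

## Calibration and recovery at reduced scale

Two simulation experiments anchor the statistics (sizes chosen as the
package's own desk-scale defaults; both run in the test suite and in
`scripts/acceptance.R`):

* **Null calibration.** Across 200 replicate null studies (no planted
  effect, 12 subjects, 12 trials per condition, 32 electrodes, 128 Hz,
  16 mm grid) the condition main effect rejects at the nominal 5% rate
  (binomial band), and the average per-family false discovery proportion
  at BH 0.05 stays at or below 0.05 plus Monte-Carlo tolerance. The
  replicate studies run the full simulate → preprocess → ERP → inverse →
  stats path; only geometry and the inverse operator, which are
  study-constant, are computed once.
* **Recovery.** Across 50 seeded studies with the default planted
  d = 0.8 effects (20 subjects, 20 trials per condition, 64 electrodes,
  256 Hz, 12 mm grid), the planted (component, ROI) pairs are flagged at
  q < 0.05 in well over 80% of cases, with no significantly reversed ROI.
  Spatial leakage is visible and expected: neighbouring masks of a
  planted region often reach significance too, which is exactly the
  low-resolution behaviour of minimum-norm-family inverses (and matches
  the empirical pattern of whole-MTL significance this design produces).

## What the synthetic validation does not show

The generator emulates component morphology, 1/f sensor noise, latency and
amplitude variability, artifact trials and inclusion attrition. It does
not emulate realistic cortical geometry or orientation fields, ocular or
muscular artifact physiology, volume-conduction errors from non-spherical
anatomy, inter-channel noise correlations, or behavioral response
processes. Passing tests therefore certify the *pipeline* — its
algorithms, bookkeeping, calibration and power behaviour under a known
truth — not the anatomical accuracy of any single-subject source
reconstruction.

## Known limitations and open choices

* The P2 re-baseline interval (130–140 ms) lies inside the P2 search range
  (120–250 ms); it is implemented exactly as specified. The generator's
  N1 makes the interval a trough, but subjects with extreme early
  latencies still lose part of the planted contrast.
* "Median peak amplitude" is read as the median of per-trial peak
  latencies; the latency-of-median-amplitude reading would differ for
  skewed trials.
* Component windows default to 50 ms; 150 ms variants are supported
  through `window_ms`.
* Manifest hashes use MD5 (fast, universally available in base R); they
  serve change detection, not cryptography.
* The printed group statistics of the motivating study depend on
  non-public participant data and are not reproduction targets; the
  pipeline's validation is property-based throughout.
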