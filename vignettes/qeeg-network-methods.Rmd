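---
title: "Quantitative EEG band power, source connectivity and brain networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG band power, source connectivity and brain networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegnet)
```

# What this package computes

`qeegnet` implements the quantitative-EEG endpoint chain of a three-arm
randomized lifestyle-intervention trial in older adults at risk of
dementia: resting-state sensor EEG is band-pass filtered and epoched,
artifact epochs are rejected, spectral band powers and ratios are
computed per channel, a standardized minimum-norm inverse projects the
sensor data onto 68 cortical regions (Desikan-Killiany naming), band-wise
functional connectivity among regions is quantified by the imaginary part
of coherency, each connectivity matrix is thresholded to a 25%-density
binary network whose graph metrics (degree, clustering, nodal and global
characteristic path length, small-worldness) are the network endpoints,
and the trial statistics layer compares arms with FDR control and handles
missing follow-ups by chained-equation multiple imputation.

Because participant EEG from such trials is not publicly deposited, the
package carries a first-class synthetic-cohort generator with known
ground truth; every stage is tested against it.

# The signal model behind the generator

Each region's source series is a sum of band-limited Gaussian
oscillations (one per band of the eight-band scheme: delta 1–4, theta
4–8, alpha1 8–10, alpha2 10–12, beta1 12–15, beta2 15–20, beta3 20–30,
gamma 30–45 Hz) plus a `1/f` background. Band components are white noise
shaped by the squared-magnitude response of a 4th-order Butterworth
band-pass — exactly the zero-phase transfer a forward–backward filter
realizes — drawn directly on the FFT grid, which is
distribution-identical to filtering white noise and keeps spectral
leakage controlled.

Directed functional coupling is planted as *lagged linear mixing*: for a
coupling edge (source region, target region, band, lag, strength), the
target receives `strength ×` the source's band component delayed by the
lag rounded to the nearest sample (applied circularly, so the delay is
exact and stationarity is preserved). A non-zero lag is what produces a
non-zero imaginary part of coherency between the pair; instantaneous
mixing alone cannot.

Sensor data are produced by strictly instantaneous mixing through a toy
spherical leadfield (sensors on the upper cap of a unit sphere, sources
on an inner sphere, gain `1/(0.1 + d²)`, columns normalized) plus white
sensor noise. This mimics volume conduction — the confound the imaginary
part of coherency is designed to reject — without an anatomical head
model. The leadfield is full rank (19) and its columns are spatially
smooth.

Default amplitudes (µV) fall off with frequency (delta 2, theta 2,
alpha1 3, alpha2 2, beta1 1, beta2 0.8, beta3 0.6, gamma 0.4) over a
pink background of SD 2 µV and sensor noise of 1 µV; together with the
column-normalized gain this puts sensor signals at EEG-scale amplitudes
(a few tens of µV peak-to-peak), comfortably inside the default
100 µV rejection threshold while injected 300–400 µV blinks are
comfortably outside it.

What the generator does **not** emulate: ERP morphology, sleep stages,
eyes-open/eyes-closed differences (a single resting condition is
generated and labeled `eyes-closed`), non-stationary rhythms,
test-retest correlation of a subject's connectivity across visits (the
two visits are independent realizations), or realistic cortical
geometry. Passing tests therefore demonstrate correctness of the
*analysis machinery* under a controlled model, not performance on real
recordings.

# The trial design in the simulator

Cohorts follow the trial structure: three arms (facility-based
intervention FMI, home-based intervention HMI, control) randomized
1:1:1 by center-stratified permuted blocks with block sizes 3 and 6;
every complete block is exactly balanced. Recordings are generated at
both visits (default 250 Hz, 180 s, matching a 3-minute resting
acquisition). At follow-up, intervention-arm subjects' alpha1 coupling
strengths increase by `group_effect` times a per-subject multiplier
drawn from U(0.75, 1.25); the same multiplier drives a cognitive index
change (`10 × realized effect` points plus noise, i.e. +5 points at the
arm level for `group_effect = 0.3`), so the within-arm association
between connectivity change and cognitive change that the regression
stage estimates is genuinely present. Follow-ups go missing completely
at random at the configured rate, or missing-at-random through a
logistic model in standardized age (slope 1). The cohort randomization
is retried until arms are exactly balanced, reflecting a fixed-size
design.

The flow-accounting helper reproduces trial bookkeeping: analyzable
(modified intention-to-treat) N per arm equals subjects with EEG at both
visits, plus early-termination EEGs accepted into analysis, minus
exclusions for bad signal quality.

# Preprocessing choices

* **Filter.** 0.5–70 Hz, 4th-order Butterworth applied
  forward–backward (zero phase), realized as cascaded high-pass and
  low-pass halves for numerical stability at a 0.5 Hz corner.
* **Epochs.** 4 s, no overlap by default: 0.25 Hz resolution resolves
  every band edge, including the 1 Hz delta edge. Welch-style
  overlapping epochs are available where more cross-spectral averages
  are needed.
* **Artifact handling.** Epoch rejection by three explicit rules —
  peak-to-peak amplitude above 100 µV, channel range below 0.5 µV
  (flat), sample-to-sample jump above 25 µV — replaces
  independent-component cleaning. These thresholds are declared package
  defaults, not values taken from any clinical pipeline; the artifact
  injector provides ground truth to verify them. The rejection report
  records the first triggering rule per epoch in the fixed order
  amplitude, flat, jump.
* **Channel names.** The legacy labels T3/T4/T5/T6 are normalized to
  T7/T8/P7/P8 at construction and read time, since both nomenclatures
  circulate.

# Spectral conventions

Power spectra are epoch-averaged periodograms (Hann taper by default,
density scaling, one-sided). Band powers integrate the PSD over
half-open bands `[low, high)`, which partitions 1–45 Hz without double
counting the shared printed edges (4, 8, 10, 12, 15, 20, 30 Hz).
Relative power divides by the total over the eight bands — i.e. the
1–45 Hz range, not the full filtered bandwidth — so relative powers sum
to one by construction. Ratio composites are interpretive and logged
as such: TAR and DAR use alpha = alpha1 + alpha2; TBR uses
beta = beta1 + beta2 + beta3; TB2R uses beta2 alone, as its name
dictates. The alpha peak frequency is the largest strict local PSD
maximum in 7–13 Hz refined by three-point quadratic interpolation; a
monotone spectrum yields an explicit absent flag rather than a boundary
value.

# Source estimation

The inverse is the standardized minimum norm: kernel
`K = Lᵀ(LLᵀ + αI)⁺` with a rank-tolerant pseudo-inverse, each source
standardized by the square root of the corresponding diagonal of the
resolution matrix `R = KL`. With `α = 0` this has provably zero
localization error for noiseless single sources (`R` is a symmetric
idempotent, so `R_ij²/R_ii ≤ R_jj` with equality at the true source) —
the property the test suite verifies for all 68 regions. The default
regularization is `α = 0.05 ×` mean eigenvalue of `LLᵀ`, an
SNR-agnostic convention, overridable everywhere. Sources are scalar
(fixed orientation), matching the toy leadfield. Region aggregation is
the unweighted mean of member sources after sign-aligning each member
to the region's leading singular vector; with one source per region it
is the identity. Connectivity is computed on region *time series* (not
power envelopes), as required for a meaningful imaginary part.

# Connectivity and networks

Cross-spectra are epoch-averaged tapered FFT products; coherency is the
cross-spectrum normalized by the auto-spectra; the band connectivity
value is the mean of `|Im C(f)|` over the band's bins. The absolute
value (rather than the signed mean) keeps the measure in `[0, 1]` and
non-negative, at the cost of discarding directionality — the signed
alternative would estimate lead/lag structure but can cancel across
bins. At least two epochs are required; single-epoch coherency is
degenerate.

Graphs keep the `floor(density × n(n−1)/2)` strongest pairs — exactly
569 edges at the trial's 25% density on 68 nodes — with a fully
deterministic tie-break (descending weight, then ascending row/column
index). Nodal characteristic path length is the mean finite BFS distance
from a node, with unreachable pairs excluded and their fraction
reported, so occasional disconnected 25%-density graphs still yield
finite per-region values. Small-worldness is
`σ = (C/C_rand)/(L/L_rand)` with the reference values averaged over
degree-preserving double-edge-swap surrogates (default 20 surrogates,
10 swaps per edge, seeded); a lattice reference is not used. σ is only
meaningfully "small-world" in regimes where the lattice path-length
penalty dominates, which the tests exercise on 100-node lattices.

# Statistics layer

The two-group test defaults to Student's pooled-variance t (the
conventional reading of an unqualified "independent t-test"), with Welch
behind a flag. The Mann-Whitney U test is exact by enumeration for
combined samples of at most 12 without ties, otherwise a tie-corrected
normal approximation; the mode used is recorded. FDR control is
Benjamini-Hochberg step-up with one family per 68-region set per band
per contrast. ANCOVA fits `outcome ~ baseline + group`; the package
defaults to change scores as the outcome (end − baseline throughout),
with end-score-adjusted analysis available by passing end scores — the
change-score default is one of two defensible readings and is logged
here deliberately. Covariate-adjusted association uses OLS of change on
change with age, sex (reference-coded) and education.

Missing data: fully conditional specification with predictive mean
matching, written in this package — per incomplete variable, a Bayesian
linear regression on all other variables, posterior-drawn coefficients,
and imputation from the `k = 5` closest-predicted-mean donors;
`m = 20` chains of 20 iterations by default (the iteration count
matches the method's convention; `m` is not dictated by it and is set
equal for symmetry). Chain means are returned for convergence
inspection. Pooling follows Rubin's rules with Barnard-Rubin degrees of
freedom when a complete-data df is supplied.

# Numerical and testing choices

* Problem sizes in the test suite are deliberately modest: unit tests
  run seconds-long recordings at 128 Hz; the end-to-end recovery study
  uses 20 subjects per arm, 180-second recordings at 90 Hz (the lowest
  rate that still resolves the 45 Hz gamma edge), 50%-overlapping 4 s
  epochs, and four replicate cohorts. These sizes are the package's
  own trade-off between statistical resolution and a test suite that
  runs everywhere.
* Detection in the recovery study reads out the planted structure:
  subject-level change in alpha1 imaginary coherence averaged over the
  planted coupled pairs, and change in nodal path length averaged over
  the coupled regions, each compared between pooled intervention arms
  and control by Mann-Whitney at p < 0.05 with the correct sign.
* The imaginary-coherence increase is a high-power readout at these
  sizes (subject-level effect around 1.4 SD). The nodal path-length
  decrease is intrinsically noisier: it reacts only through edge flips
  near the density threshold, and at a planted coupling increase of 0.3
  its subject-level effect is below 1 SD, so path-length detection
  hovers near the 80% replicate bar and can fall short in any given
  run — a genuine power limit of a binary-graph endpoint at this effect
  size, not an implementation artifact. Repeated-cohort calibration at
  30 subjects per arm shows the same pattern.
* Numerically degenerate inputs are flagged, not silently propagated:
  zero total power, zero ratio denominators, all-rejected recordings,
  zero-edge graphs and empty p-value families each produce explicit
  flags or typed errors.

# Known limitations

The toy leadfield is not an anatomical forward model, so region labels
carry no geometry; source leakage in the inverse smears planted
couplings onto neighboring region pairs, which is realistic in kind but
not in degree. The generator's two visits are independent draws, making
change scores noisier than real test-retest EEG; trial power computed on
this simulator is therefore conservative. No weighted-graph metrics,
threshold sweeps, directed connectivity, or mixed-effects models are
provided.
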