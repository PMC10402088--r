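---
title: "Modeling temporal sensitivity to chromatic and achromatic flicker with flickerfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling temporal sensitivity to chromatic and achromatic flicker with flickerfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerfit)
```

## Overview

`flickerfit` analyzes BOLD fMRI experiments in which a spatially uniform
field flickers at log-spaced frequencies (0--64 Hz) along the three
post-receptoral channels: achromatic light flux (LMS), red-green (L−M,
written `LM`), and blue-yellow (S). The pipeline runs from stimulus-design
construction through joint HRF + amplitude estimation, Watson
temporal-sensitivity fitting with bootstrap, carry-over (adaptation)
estimation, multi-vertex pattern similarity and decoding, eccentricity
aggregation, and an eccentricity-integrated model of retinal ganglion cell
output. Because raw participant recordings for this kind of experiment are
typically not shareable, the package ships a first-class synthetic-data
generator whose outputs have the statistical structure the analysis
assumes; every downstream stage is validated against it.

## Experimental design

Each 336 s acquisition presents 28 trials of 12 s, one flicker frequency
per trial from {0, 2, 4, 8, 16, 32, 64} Hz. Trial order follows a
first-order counterbalanced master sequence over the 7 conditions: a
50-element ordering in which every ordered pair of conditions, including
immediate repeats, occurs exactly once among consecutive elements. Such
sequences are exactly the Eulerian circuits of the complete directed graph
with self-loops on 7 nodes; `make_counterbalanced_sequence()` finds one by
a seeded randomized Hierholzer walk (such a circuit always exists, so the
bounded-restart loop is a safety net, not a probabilistic search).

The master sequence is split into halves A (elements 1--25) and B
(26--50), each padded with three 0 Hz trials; six blocks each present the
six acquisitions LMS~A~, LM~A~, S~A~, S~B~, LM~B~, LMS~B~, for 36
acquisitions and 12,096 volumes at TR = 1 s. Two package-level choices
deserve note, both made because the source design leaves them open:

- **Rotation of the circuit.** The split severs exactly one consecutive
  pair (elements 25→26). We rotate the closed circuit — which preserves
  the exactly-once pair property — so that element 26 is the 0 Hz
  condition. The severed pair then coincides with the (element 25, 0 Hz)
  pair that A's padding recreates, so all 49 ordered pairs keep at least
  one supporting trial in the study and the carry-over design below stays
  full rank.
- **Coverage of both halves.** A random circuit can place all seven
  occurrences of one condition in a single half, which would zero one
  design-matrix column in the other half's acquisitions. The study
  schedule therefore requires every condition to appear in both halves,
  trying rotations and fresh seeds until the constraint holds.

The A/B split as first/second 25 elements is itself an assumption; it is
the natural reading and nothing downstream depends on the alternative.

Attention events (a 250 ms dimming; modeled as unit impulses) occur with
probability 0.33 per trial, uniformly within the trial but excluded from
its first and last 2 s.

## Hemodynamic response model

The HRF is a weighted sum of three orthonormal temporal kernels on a
0--28 s support at 1 s resolution. The basis is obtained by SVD of 512
double-gamma responses sampled over plausible ranges (time-to-peak 4--8 s,
undershoot delay 12--18 s, dispersion 0.6--1.4, undershoot ratio
0.1--0.5). The basis is a fixture of this package: any 3-component
orthonormal basis spanning plausible HRFs serves, and no test depends on
exact basis values. The first component correlates > 0.99 with the family
mean, and any family member is reconstructed with R² > 0.9 from its three
loadings.

A joint fit of HRF shape and response amplitudes is degenerate along the
shared scale. We resolve it with a physical convention: the fitted kernel
is normalized so that a 12 s unit boxcar evokes a unit-peak response.
Amplitudes are then the peak percent-signal-change evoked by one trial.

## Joint time-series fit

Per vertex, the model is linear in the per-acquisition covariate
amplitudes (7 frequency boxcars + 1 attention column per acquisition, 288
covariates for the full study) given the three HRF weights, so the fit is
separable: amplitudes are profiled out by ordinary least squares and a
Nelder-Mead search runs over the weights only, initialized at the
projection of the canonical double-gamma onto the basis. Because the
design is block-diagonal by acquisition, the OLS step reduces to 36
independent 8 × 8 normal-equation solves on precomputed cross-products,
making the objective cheap. Model and data are both projected against a
per-acquisition discrete-cosine set (constant plus cosines below
0.0387 Hz, 27 regressors per 336 s) before the L2 norm is taken; the
projection is idempotent and convolution never crosses acquisition
boundaries.

Two numerical facts shape the tests:

- The seven frequency covariates tile the acquisition, so their sum is
  nearly constant and the high-pass almost removes the common mode. Raw
  per-acquisition amplitudes therefore carry a large shared-offset
  uncertainty (closed-form OLS SE ≈ 0.77 %BOLD at the default 0.5 %BOLD
  noise), while differences between covariates — in particular the 0
  Hz-relative amplitudes every downstream stage consumes — are well
  determined. The fit attains the closed-form OLS error bound given the
  true HRF, which is the meaningful optimality statement; recovery
  quality is asserted on crossing-averaged relative amplitudes.
- Only drift inside the cosine span is removed exactly. A generic slow
  sinusoid leaves a small leakage residual (for a unit 0.01 Hz sinusoid,
  ≈ 0.04 % of its power), which perturbs mainly the ill-conditioned
  common mode; relative amplitudes move by < 0.05 %BOLD.

R² is computed on attention-cleaned data averaged across the six A and six
B acquisitions per direction (concatenated), so attention-task variance is
excluded; vertices with R² > 0.1 (strict) enter all regional averages.
Zero-variance input yields amplitudes 0 and R² = 0 rather than an error.

## Watson temporal sensitivity model

Response amplitude versus frequency is fit with a difference of cascaded
exponential low-pass filters: center order 9, surround order 10 (both
fixed), free parameters the center time constant τc ∈ [10⁻⁴, 0.1] s, the
surround/center ratio r ∈ [1, 20], the relative surround gain Gs ∈ [0, 1],
and the overall gain G ≥ 0. These bounds realize the fit's linear
constraints; G is profiled out analytically (one-dimensional non-negative
least squares), and unimodality of the amplitude profile — at most one
maximal run of first differences on the interpolation grid — is enforced
by a quadratic penalty and verified on the dense grid before a fit is
returned. Multi-start over a lattice of 24 bounded start points guards
against local minima; bootstrap replicates are warm-started from the
full-data fit. Peaks are read off a log-spaced grid from 0.5 to 100 Hz at
0.01 log10 resolution.

The model is over-parameterized: materially different parameter vectors
reproduce six noiseless samples at 2--64 Hz to relative SSE ~10⁻¹² while
extrapolating differently below 2 Hz. Peak summaries are therefore only
identified when the interpolated peak lies inside the sampled band, and
parameter values themselves are never interpreted — only the peak
frequency and amplitude are consumed downstream. Negative amplitudes are
fit as-is against the non-negative model; display layers may flag them.

`bootstrap_tsf()` resamples the 12 acquisitions per direction with
replacement (1,000 replicates by default), averages relative amplitudes
per frequency, refits, and reports per-frequency and peak medians with
interquartile ranges.

## Carry-over analysis

First-order adaptation is estimated from the residual of the main fit,
averaged over selected vertices: one covariate per ordered (prior,
subsequent) frequency pair — a 12 s boxcar on every trial whose
predecessor within the acquisition had the prior frequency — giving 49
covariates per stimulus class (achromatic = LMS acquisitions; chromatic =
L−M and S pooled). The first trial of each acquisition has no prior and is
excluded rather than assigned a synthetic 0 Hz predecessor. Covariates are
convolved with the region-average fitted HRF and high-pass filtered
identically to the residual (the source design does not say whether it
filtered them; filtering both is the consistent choice). Coefficients are
arranged as a 7 × 7 matrix; cells whose pair lacks support are NA, not 0.
Across participants, cells with |mean| > 2 · SEM are flagged.

Because the main GLM absorbs each acquisition's per-frequency mean
response, a uniform multiplicative suppression after (say) 64 Hz does not
push every cell of the 64 Hz row negative — non-suppressed trials acquire
positive residual deviations, and OLS redistributes across the collinear
convolved covariates. A generative oracle (regressing the known injected
signal, residualized against the same design, on the same covariates)
shows identical behavior, so recovery is asserted on the row mean.

## Pattern similarity and decoding

Within each acquisition, the across-vertex pattern of 0 Hz-relative
amplitudes at each of the six non-zero frequencies is standardized to mean
0 and unit (population) SD; the 0 Hz pattern is identically zero and
cannot be standardized, which is why matrices and decoding use six
candidates — consistent with a 1/6 ≈ 0.167 chance level. For every
unordered split of the 12 acquisitions into halves (462 partitions),
patterns are averaged within halves and correlated across them; each
partition's matrix is symmetrized with its transpose before averaging, so
the result is symmetric to machine precision. Decoding counts a case
correct only when the held-out target frequency is the strictly best
match; ties are incorrect (conservative, and measure-zero for continuous
data).

## Retinal output model

Per-class temporal gain tables (spikes·s⁻¹ per % contrast; "on" and "off"
responses averaged upstream) at eccentricity centers 5°, 25°, 40° are
converted to spike rates at the stimulus contrasts (LMS 90%, L−M 8%, S
50%), with parasol cells saturating at 25% contrast. LMS output is the sum
of midget and parasol achromatic responses; L−M is midget chromatic; S is
small bistratified (tabulated only at 5° and 25°, so no S prediction at
40°). Responses are scaled by receptive-field density (an exponential
decline with eccentricity — configuration, not an empirical claim), class
proportions (midget-dominated centrally, parasol share rising
peripherally; also configuration), and annular area 2π·e in deg² (whether
the original computation used deg² or mm² is unstated; deg² is used and
documented). Peaks are extracted by log-quadratic interpolation around the
tabulated maximum — the gain grids are coarse, so interpolation, not grid
argmax, mirrors "the frequency of the peak response". Amplitudes are
normalized to the across-eccentricity mean LMS peak.

The packaged gain table (`inst/extdata/rgc_gains_synthetic.tsv`) is a
synthetic fixture with plausible magnitudes and shapes (band-pass parasol
speeding up peripherally; low-pass chromatic midget; low-pass
bistratified). It is replaceable input: all retina-module behavior is
defined relative to whatever table is supplied, and no test treats the
fixture's numbers as empirical values.

## Eccentricity aggregation and maps

V1-style eccentricity bands use edges 0, 2.8, 5.6, 11.25, 22.5, 45, 90°,
half-open on the right with 90° included in the last band (a deterministic
assignment rule). Band summaries average amplitudes over R²-selected
vertices before Watson fitting (band-averaged TSFs, not averaged fits).
Relative peak-frequency maps z-score log10 peak frequency across vertices
per direction and average the three z-maps; the map is invariant to
rescaling frequency by any constant. Visual-field projection deposits a
2-D Gaussian per vertex (σ = pRF width) at its field position and
normalizes by total weight, flagging pixels below a 10⁻⁶ weight floor as
empty.

## Synthetic data: what it does and does not emulate

The generator draws vertex eccentricities log-uniform on [0.5, 90]°, with
pRF width increasing with eccentricity. Neural amplitudes follow
per-direction Watson truths (defaults: peaks near 16, 12, and 8 Hz with
peak amplitudes 2.0, 1.6, and 1.2 %BOLD for LMS, L−M, and S — fixture
values chosen to resemble achromatic-faster-than-chromatic cortical
sensitivity, not measured claims). Carry-over is injected
multiplicatively on neural amplitude (a habituation-like mechanism that
the residual regression can recover); per-frequency vertex patterns are
Gaussian templates (SD 0.15 %BOLD) added to the trial amplitudes;
attention events add 0.5 %BOLD impulses; drift is a slow sinusoid (1
%BOLD at 0.005 Hz, random phase); measurement noise is white Gaussian
(0.5 %BOLD), matching the GLM's implicit noise model. Real fMRI has
temporally autocorrelated, spatially structured physiological noise,
scanner drift that is not a single sinusoid, and HRF variation across
cortex — none of which the generator emulates, so green tests certify the
analysis logic, not robustness to those realities.

## Problem sizes and numerical choices

The test suite exercises the full 36-acquisition design throughout; vertex
counts are kept modest (1--100 depending on the property under test), the
decoding null uses 10⁵ Monte-Carlo draws, and bootstrap checks compare a
10³-replicate run against a 10⁴-replicate oracle — sizes chosen to give
sub-percent Monte-Carlo error on every asserted quantity. Nelder-Mead
tolerances are 10⁻¹⁴ (HRF weights) and 10⁻¹⁰/10⁻¹² (Watson fits);
rank-deficient filtered designs raise an error naming the offending
acquisition; empty vertex selections return empty results rather than
errors.

## Known limitations

- Watson parameter values are not identified (only peak summaries are).
- Absolute per-acquisition amplitude levels are weakly identified by
  design; use relative amplitudes.
- No prewhitening/AR noise model; no spatial regularization; carry-over is
  first-order only.
- The retina module's gain table, density model, and class proportions are
  configuration; its outputs are qualitative predictions, not fits to
  recordings.
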