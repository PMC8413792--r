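---
title: "Methods: fNIRS functional-connectivity analysis of sleep deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fNIRS functional-connectivity analysis of sleep deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nirsconn` implements a complete graph-theoretical functional-connectivity
analysis for block-design fNIRS studies with a two-level within-subject
manipulation (here: before vs. after sleep deprivation) crossed with seven
task states (rest and six finger-tapping stimuli). This vignette documents
the model, the tunable parameters and the numerical choices, and states what
the synthetic-data generator does and does not emulate.

## Measurement model

A continuous-wave fNIRS channel is a source-detector pair measuring light
attenuation at two wavelengths (760 and 850 nm). The packaged montage places
16 sources and 16 detectors over prefrontal and motor cortex (10-10 labels),
each source paired with three adjacent detectors, giving 48 channels at a
nominal 3 cm separation. The exact source-to-detector pairing is not a
property of the algorithms — it is package data, and any montage present in a
SNIRF file overrides it. Channels are ordered lexicographically by (source
index, detector index) so every table has a deterministic channel numbering.

Raw intensities `I(t)` are converted to optical-density change relative to
the channel's temporal mean, `OD(t) = -log10(I(t) / mean(I))`. The temporal
mean is the conventional CW baseline; any constant rescaling of intensity
cancels, which is also why the quality-control statistic below is computed on
intensities rather than on the zero-mean OD.

## Preprocessing

The chain is fixed in this order: wavelet artifact suppression, low-pass
filtering, Beer-Lambert conversion, CBSI.

**Wavelet artifact suppression** (`wavelet_artifact_removal()`). Motion
artifacts are sharp transients that concentrate in few large detail
coefficients of an orthogonal wavelet decomposition. The series is
reflection-padded to a power-of-two length, decomposed with the 4-tap
Daubechies filter (implemented in-package; the transform satisfies perfect
reconstruction and energy preservation, both asserted in tests), and detail
coefficients falling outside the interquartile fence
`[Q1 - f*IQR, Q3 + f*IQR]` of their level are zeroed (`f = 1.5` by default,
configurable as `preprocess$wavelet$iqr_factor`). Two deliberate choices:

* Only coefficients whose support lies entirely inside the original signal
  are thresholded. The padding seam otherwise produces large detail
  coefficients that would be "removed", corrupting the reconstruction; with
  this rule a clean signal passes through unchanged to machine precision.
* The decomposition depth keeps at least 32 coefficients in the coarsest
  detail band. Deeper levels hold the slow hemodynamics we must not touch,
  and quartile fences from a handful of coefficients are unstable.

The residual of a suppressed spike is confined to roughly the spike's
coefficient support (a few tens of samples); the surrounding signal is
untouched at machine precision.

**Low-pass filter** (`lowpass()`). A 5th-order Butterworth design with 0.4 Hz
cutoff (both configurable), applied forward and backward. Zero-phase
filtering was chosen because the analysis epochs are only 10 s long: a
single-pass group delay would shift response energy across epoch boundaries.
The price is that the effective magnitude response is the square of the
single-pass response — the amplitude gain at the cutoff is 0.5, not 0.707 —
which the tests assert on a steady-state sinusoid. The series mean is removed
before filtering and restored afterwards, so DC is preserved exactly and
start-up transients from nonzero initial conditions are avoided.

**Modified Beer-Lambert law** (`od_to_hemoglobin()`). Per channel and time
point the 2x2 system `OD(lambda) = (eps_HbO(lambda) dHbO +
eps_HbR(lambda) dHbR) * d * DPF(lambda)` is solved for the concentration
changes (micromolar). The packaged extinction coefficients are the standard
compiled hemoglobin spectra values at 760/850 nm; the differential pathlength
factor defaults to 6.0 at both wavelengths and the separation to 3 cm. All
constants are configuration, and the generator uses the same forward model,
so forward-then-inverse is the identity to 1e-9 (asserted). A collinear
extinction matrix is rejected with an explicit error.

**CBSI** (`cbsi()`). Evoked responses raise HbO and lower HbR; systemic and
motion components move both in the same direction. CBSI exploits this by
recombining the pair into exactly anticorrelated components:
`alpha = sd(HbO)/sd(HbR)`, `HbO* = (HbO - alpha HbR)/2`,
`HbR* = -HbO*/alpha`. Zero-variance inputs are an error. HbT is recomputed as
`HbO* + HbR*` afterwards, preserving the `HbT = HbO + HbR` invariant at every
stage.

**Quality control** (`subject_qc()`). Per channel, the coefficient of
variation (sd/mean) of the raw intensity is computed for both wavelengths and
the worse one kept; a channel with non-positive mean intensity gets CV = Inf.
A subject is excluded when strictly more than 80% of channels exceed a CV of
7.5% (both thresholds configurable; both comparisons are strict, so a
fraction exactly at the limit is retained). The statistic is computed on raw
intensity because the CV of a zero-mean OD series is ill-defined.

## Connectivity and thresholding

Connection matrices are built from the CBSI-treated total-hemoglobin series.
Each of the six stimulus epochs contributes its full 10-s window; the resting
state contributes one 10-s window centered in the 60-s rest block (start
index `floor(25 * fs)`, half-open epochs `[onset, onset + duration)`), so all
seven states rest on the same number of samples — `floor(10 * fs) = 39` at
3.9 Hz. The Pearson matrix treats the diagonal as 0 (never an edge);
zero-variance channels yield zero rows rather than being dropped, keeping
`N = 48` constant across states so the density normalization `1/(N-1)` is
comparable everywhere.

Three complementary edge-selection rules, each yielding a weighted and a
binarized graph, with no negative coefficient ever surviving:

* **Absolute**: keep `c_ij >= tau`, default grid 0.15 to 0.75 in steps of
  0.05. A coefficient exactly at the cutoff is kept (the discard rule is
  "strictly less than").
* **Cost**: keep the `round(cost * M)` largest positive coefficients of the
  `M = N(N-1)/2` pairs, grid 0.10 to 0.85 in steps of 0.05. Ties are broken
  by (row, column) order, which makes the edge sets deterministic and nested
  across increasing cost (asserted as a property test).
* **Surrogate**: keep positive coefficients individually significant under
  the exact t transform `t = c sqrt((n-2)/(1-c^2))`, two-sided, at
  `alpha = 0.05`. `|c| = 1` is treated as p = 0. The 39-sample epochs are
  autocorrelated, so the nominal per-edge level is optimistic; this mirrors
  the treatment of the correlations as i.i.d.-sample statistics and is a
  known fidelity limitation. The p-values are deliberately not corrected for
  the 1128 simultaneous edges — the scheme is a per-edge filter, not an
  inference. Under an independent-noise null the retained fraction is
  `alpha/2` (only the positive tail is kept), which the acceptance tests
  verify by simulation.

## Network metrics

For node `i` of an N-node graph with nonnegative weights `c_ij`:

* local (weighted) density `WD_loc(i) = sum_j c_ij / (N-1)`; for binary
  graphs the numerator is the degree `k_i`;
* global density `D = mean_i D_loc(i)`, the network's wiring cost; for binary
  graphs `D (N-1)` is the average degree;
* binary clustering coefficient
  `C = mean_i [ sum_{j,h} a_ij a_ih a_jh / (k_i (k_i - 1)) ]`, with the
  convention that nodes of degree < 2 contribute 0;
* binary global efficiency `E = mean_i [ sum_{j != i} d_ij^{-1} / (N-1) ]`
  with BFS path lengths and `d^{-1} = 0` for disconnected pairs.

Clustering and efficiency are computed on binary graphs only; comparing them
fairly across states requires equal edge counts, hence they are evaluated on
the cost-thresholded graphs and *summed* across the cost grid
(`cost_integrated_metrics()`). A mean across the grid would differ only by a
constant factor and leaves the ANOVA unchanged; the sum is implemented as the
literal reading of the summation across cost levels. All metrics are checked
against closed forms, brute-force enumeration (edge counting, triple
enumeration, Floyd-Warshall) and igraph on random graphs to 1e-12.

## Statistics

Metric tables are log-transformed first (`log(value + 1e-6)`; the epsilon
guards empty networks and is configurable). The repeated-measures ANOVA
(`rm_anova()`) handles balanced fully-within designs with any number of
factors: each effect is evaluated on orthonormal (normalized Helmert)
contrast scores, the effect's error term being its interaction with
subjects. Sphericity is assessed per effect with Mauchly's W (including the
standard two-term chi-square approximation, matching `stats::mauchly.test`),
and the Greenhouse-Geisser-corrected p is adopted automatically whenever
Mauchly's p < 0.05; both raw and corrected p are always reported. The
implementation is validated against `car::Anova` on shared fixtures to 1e-8
(F, p, epsilon) for two- and three-factor designs. Because a marked threshold
dependence of density is expected, the absolute-scheme ANOVA includes the
threshold as a third within factor (an ordered grid treated as categorical
levels); the surrogate scheme has a single parameter and uses the two-factor
model. Under the null the interaction test is calibrated — the acceptance
suite verifies a type-I rate within [0.02, 0.08] at alpha = 0.05 over 500
null cohorts of 10 subjects.

Comparisons of each stimulus against rest use Dunnett-style paired contrasts
(`dunnett_vs_rest()`): the adjusted p of contrast `j` is the probability that
the maximum absolute component of a multivariate t variable (correlation
estimated from the subject-level difference vectors, `n-1` degrees of
freedom) exceeds `|t_j|`, evaluated by Monte-Carlo with 1e5 draws under a
fixed internal seed. There is no closed form for arbitrary contrast
correlation; the Monte-Carlo route is reproducible and reduces exactly to the
paired t-test for a single contrast (asserted within Monte-Carlo error).
Adjusted p-values are clamped to be at least the raw p.

The sleep-deprivation effect on global connection strength is
`dWD = (mean over stimuli of WD - rest WD)_after - (same)_before`, computed
per subject from the weighted surrogate-thresholded density, and correlated
(Pearson, two-sided, uncorrected) with each cognitive-score change; missing
scores are dropped pairwise. Channel-wise contrast maps run a one-sample t
per channel on the task-minus-rest change (or its between-state difference)
and apply Benjamini-Hochberg FDR across the 48 channels. Between-subject
concordance of the channel-wise sleep-deprivation effect is summarized by
Kendall's W with tie correction; the effect ranked per subject is the
after-minus-before difference of the channel's task-minus-rest local weighted
density — the statistic being ranked is an interpretation choice, since
"concordance of channel-wise effects" admits several, and it is exposed as
plain data so alternatives are easy.

## The synthetic-data generator

`generate_cohort()` emulates the study conditions so that every downstream
stage can be tested without real recordings: the 48-channel montage, 3.9 Hz
sampling, the rest + six-stimulus schedule, and per-channel signals composed
of (a) a latent HbO process drawn from a multivariate Gaussian whose
correlation matrix follows a planted block structure — imposed exactly per
epoch via the Cholesky factor of the target matrix, with eigenvalue clipping
at 1e-10 and rescaling when a block design is indefinite; (b) HbR as
`-gamma HbO` plus independent noise (gamma = 1/3); (c) double-gamma HRF
responses (peak 6 s, undershoot 16 s, ratio 1/6) convolved with the 10-s
boxcar, added on contralateral motor channels (odd stimuli are left-hand and
activate right-hemisphere motor channels, and vice versa); (d) systemic
sinusoids at cardiac (1.1 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz)
frequencies with 2% frequency jitter and random per-channel phases; (e) white
noise; and (f) Poisson-timed motion spikes (0.5/min by default) with
amplitudes 5-20 times the channel's OD standard deviation and 0.5-s
exponential tails. Signals are converted to two-wavelength optical density
with the same forward Beer-Lambert model the preprocessing inverts.

The connectivity plan defaults encode the qualitative pattern the analysis
is designed to detect: resting correlations of 0.35 within / 0.10 between
four channel communities, a task-epoch drop of 0.12 in all off-diagonal
correlations, and a 0.08 weakening of that drop in the sleep-deprived
session, with per-subject Gaussian jitter (sd 0.02) on both modulations. No
effect sizes are reported for the original study, so these defaults were
chosen once as plausible magnitudes for correlation-level modulations in
block-design fNIRS; power-oriented tests use explicitly larger planted
effects and say so. Cognitive-score changes are linearly coupled to each
subject's planted connectivity change (default slopes: PAL -40 points per
unit of planted change, RTI and RVPA 0) plus noise.

What the generator does **not** emulate: photon transport and layered
scalp/skull optics, spatially structured (distance-dependent) connectivity,
serial correlation of the latent process within epochs, scalp-hemodynamic
confounds shared across channels, and non-Gaussian score distributions.
Passing tests therefore demonstrate that the pipeline recovers structure it
can represent — not that real recordings satisfy these assumptions.

## Problem sizes in the test suite

The suite exercises: oracle equivalence of the graph metrics on 200 random
12-node graphs; the surrogate null retention over 200 replicate 39-sample,
30-channel noise matrices; ANOVA type-I calibration over 500 null
10-subject tables; interaction power and sign recovery over 100 simulated
20-subject cohorts at the large planted effect; and recovery of the planted
negative dWD-PAL coupling over 20 simulated 50-subject low-noise cohorts.
Simulation-based checks run the generator end to end but disable the wavelet
and low-pass stages, which are identity-like on the clean signals those
configurations produce.

## Known limitations

* Surrogate p-values ignore within-epoch autocorrelation (39 samples at
  3.9 Hz), so the per-edge alpha is nominal.
* The wavelet stage does not clean artifacts within about one coefficient
  support of the series ends.
* Dunnett adjustment is Monte-Carlo; adjusted p-values carry sampling noise
  of order 1e-3 at the default 1e5 draws.
* `C` and `E` are binary-only, matching the analysis they serve; weighted
  variants are out of scope.
* The SNIRF reader handles continuous-wave amplitude data (dataType 1) only
  and is validated against files written by this package.
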