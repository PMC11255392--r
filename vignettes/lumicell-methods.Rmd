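---
title: "Methods: from luminance protocols to Purkinje-cell attribution"
author: "lumicell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from luminance protocols to Purkinje-cell attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumicell)
```

`lumicell` implements a complete analysis chain for population two-photon
calcium imaging of luminance responses in the larval zebrafish cerebellum:
granule cells (GCs) and inferior olive neurons (IONs) on the input side,
Purkinje cells (PCs) on the output side. This vignette explains the models
and procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Stimuli and regressors

Stimuli are piecewise-constant luminance schedules. Two protocols are
built in: `build_steps_protocol()` presents 5 s steps at 5%, 20% and 100%
of maximal luminance with 7 s dark interstimulus intervals, ordered as an
Eulerian circuit over the four levels so that every one of the 12 ordered
level transitions occurs exactly once per repetition;
`build_flashes_protocol()` presents 3, 7 and 21 s flashes at full
brightness between 7 s dark intervals. Schedules are discretized on the
imaging clock by midpoint sampling (`sample_protocol()`), with epochs
half-open on the right; sampling refuses a frame period longer than the
shortest epoch because the schedule would alias.

Candidate response predictors come from two families
(`build_regressor_bank()`): *luminance* regressors — the luminance profile
under gamma corrections 1, 1/2 and 2, plus the gamma-2 minus gamma-1
difference, whose profile peaks at intermediate levels — and *transition*
regressors — impulse trains at ON, OFF and all transitions. Every
regressor is convolved with a calcium-indicator kernel and standardized to
zero mean and unit variance; standardization is harmless because all
downstream use is Pearson correlation, which is scale-free.

Indicator kernels (`make_kernel()`) are causal single-exponential decays
with unit area, truncated where the amplitude falls below 1e-4 of the
peak. The decay constants are 0.85 s for GCaMP6fEF05 and 1.25 s for
GCaMP6s — the midpoints of the indicators' reported 0.7–1 s and 1–1.5 s
ranges — and are exposed as arguments. The regressor-analysis kernel is
the GCaMP6fEF05 kernel truncated at 3 s of support. A boxcar would have
been an alternative reading of a "3 s kernel"; the truncated exponential
was chosen because it matches the indicator's impulse response, and the
form is configurable. Deconvolution (`deconvolve_kernel()`) inverts the
truncated causal convolution exactly by forward substitution on the
triangular Toeplitz system; for the decaying kernels used here the
leading tap dominates, so noise amplification stays moderate (the
noiseless roundtrip is exact to machine precision by construction).

## Imaging: motion correction and ROI segmentation

`align_plane()` registers each frame to the mean of 50 frames (the first
50 by default; the offset is an argument) by the integer-pixel peak of the
FFT cross-correlation, and corrects with a rigid integer translation only
— no subpixel interpolation, so photon counts are preserved. Frames whose
displacement exceeds 10 µm are motion artifacts: they are set to missing
in place, never dropped, and missingness propagates through every later
statistic by pairwise deletion. `align_across_planes()` chains
cross-correlations of consecutive plane averages into cumulative
per-plane shifts.

`correlation_map()` assigns each pixel the Pearson correlation between its
time course and the mean of its eight neighbours (border pixels use the
neighbours that exist). `grow_rois()` then grows ROIs from the highest
unassigned map value: 4-connected neighbours are evaluated in decreasing
map order and join when their correlation with the ROI's current mean
trace reaches `grow_threshold` and they lie within `max_radius` µm of the
seed. Defaults are `seed_floor = 0.3`, `grow_threshold = 0.35`,
`max_radius = 5` µm, `min_pixels = 4`; these are package defaults, not
published values, and all are arguments. Ties in map value break in
row-major pixel order so outputs are deterministic. Pixels of ROIs
discarded for falling under `min_pixels` are consumed rather than
returned to the seed pool, which guarantees termination. Cells spanning
several planes are merged (`merge_rois_across_planes()`) when footprints
overlap by at least half of the smaller footprint *and* mean traces
correlate; a multi-plane cell's per-plane recordings are treated as
additional protocol repetitions, not averaged, because each plane was
acquired in a separate pass.

## Responsiveness, clustering, timing

The *reliability index* of a cell is the mean Pearson correlation over all
unordered pairs of stimulus repetitions. The pairwise mean — rather than
correlation with the trial average — is used because the quantity of
interest is between-presentation consistency. The population's score
histogram is bimodal (a near-zero peak plus a responsive tail), and the
responsive/unresponsive cut is Otsu's threshold over a fixed 256-bin
histogram (`otsu_threshold()`); when the between-class variance is flat
across an empty valley, the cut is placed at the middle of the maximal
plateau. Fixed binning was chosen over adaptive binning for
reproducibility.

Mean responses of responsive cells are z-scored per cell — so clusters
group response *shapes*, not amplitudes — and clustered with Ward linkage
on Euclidean distance (`cluster_responses()`, via `stats::hclust`,
method `ward.D2`). The tree cut is a required parameter, as the cluster
count is a judgement call; `cut_height_for_k()` reproduces a cut at a
known cluster count. Cluster ids are renumbered by decreasing size so
labels are stable for a fixed input order.

Response timing is summarized by the *center of mass* (COM): the time at
which the cumulative integral of the baseline-subtracted,
floored-at-zero trace reaches half its total, linearly interpolated
between frames. The baseline is the mean of the 1 s preceding the
analysis window (flooring and baseline handling are the package's
choices; the closed-form anchors — a symmetric pulse lands at the window
midpoint, a linear ramp of duration $T$ at $T/\sqrt{2}$ — pin the
convention). COM sorting is cross-validated: trials are split into fixed
even/odd halves, one half determines the order, the other is displayed,
so sorted displays are not fit to the plotted data.

## Decoding

Per-frame population vectors are assembled from trial-wise traces with
cells drawn independently across trials, deliberately destroying noise
correlations — the same caveat as in the source experiments, where cells
come from different fish. Time since stimulus onset is decoded with ridge
regression (closed-form penalized least squares; features standardized
with training statistics); instantaneous luminance with an RBF
support-vector regression (`e1071::svm`). In both cases training uses 10
randomly chosen trials and testing 2 others, only cells with at least 12
trials are eligible, and the single regularization parameter is chosen by
leave-one-trial-out grid search over a 9-point logarithmic grid (1e-4 to
1e4 for the ridge penalty, 1e-2 to 1e2 for the SVR cost — the grids are
package choices). Performance is $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ on
pooled test frames. `subsample_decode()` repeats the analysis on seeded
random cell subsets to compare populations at matched size.

## The Purkinje-cell attribution model

Each PC trace is modelled as

$$\mathrm{PC}_i(t) = \mathrm{offset}_i + \sum_j \mathrm{GCcoeff}_{ij}\,
\mathrm{GCreg}_j(t) + \sum_k \mathrm{IONcoeff}_{ik}\,\mathrm{IONreg}_k(t)$$

with the offset bounded to $[-5, 5]$ and all coefficients nonnegative and
bounded by 1000 (both populations excite PCs; the wide bound reflects the
regressors' unit-integral normalization against z-scored traces).
Regressors are the GC and ION cluster mean responses, deconvolved with
the GCaMP6fEF05 kernel and re-convolved with the GCaMP6s kernel so all
traces share the PC indicator's timescale, shifted to be strictly
positive (by 1e-3 of their range) and scaled to unit integral
(`build_cluster_regressors()`).

PC trials are z-scored per trial, high-pass filtered at 1/80 Hz
(first-order Butterworth run forward–backward, so drift is removed with
zero phase) and smoothed with a centered 3-point boxcar
(`preprocess_pc()`). Two repetitions are held out as the test set.

The fit minimizes the mean squared error on the concatenated fit trials
plus $\lambda$ times the L1 norm of the coefficients. Because the
coefficients are nonnegative, the penalty is linear on the feasible box
and the whole objective is a convex quadratic; `fit_pc()` solves it with
exact active-set iterations (Lawson–Hanson style), so solutions are
deterministic, reproducible, and accurate to the conditioning of the
normal equations — there is no iterative-optimizer tolerance. $\lambda$
is chosen per cell by leave-one-out cross-validation over a logarithmic
sweep from 1e-7 to 1e-2 (`crossval_lambda()`; ties resolve toward the
strongest penalty), and the population is refit with the shared average
$\lambda$ so weights are comparable across cells. The average is the
geometric mean: the candidates span five decades, where an arithmetic
mean would be dominated by the largest value.

Fit quality is benchmarked against a *regressor-wise shuffle null*: each
regressor's column of fitted weights is permuted independently across
cells, each cell's intercept is refit to its own fit trials (the
regressors are all positive, so a permuted total weight would otherwise
shift the prediction mean and penalize every recombination regardless of
shape), and test costs of all shuffled fits are pooled into a single null
distribution. A cell's fit is better than chance when its test cost lies
below the pooled 5th percentile. Relative GC vs ION drive is summarized
by the index $(\sum \mathrm{GC} - \sum \mathrm{ION}) / (\sum \mathrm{GC}
+ \sum \mathrm{ION}) \in [-1, 1]$, and its relation to response
reliability is tested with a Spearman correlation.

Two caveats established on synthetic data are worth stating. First, with
noisy data and a shared cross-validated $\lambda$, the L1 trade can
substitute a small fraction of weight between correlated GC and ION
regressors, so cells built from one population alone score near, but not
exactly at, $\pm 1$; exact $\pm 1$ holds in the identifiable regime
(noiseless traces, unpenalized fit). Second, for cells whose planted GC
and ION sums are nearly balanced, or whose profile mixes strongly
anti-correlated regressors (sustained ON vs OFF under luminance steps),
the sign of the index is intrinsically unstable: in simulations about
8% of uniformly drawn sparse mixtures flip sign at the shared $\lambda$,
and neither the penalty level, relaxed refitting, nor penalty
standardization removes the effect. The index should therefore be read
as a graded summary, not a classifier, near zero.

## Behavior

Swim bouts are maximal runs of speed above threshold, with runs closer
than 0.1 s merged (`detect_bouts()`). Bout onsets are folded to their
phase within the protocol repetition and binned into equal bins of
approximately the requested width (no ragged remainder bin), normalized
per repetition (`bout_histogram()`). The dark-transition suppression
test compares the mean bout probability within 1.5 s after the OFF
transitions with the first percentile of a bootstrap distribution
obtained by resampling the histogram's total count multinomially over
bins and reading the same-size window at random placements
(`offset_suppression_test()`). The bootstrap scheme — multinomial count
resampling plus random window placement — is stated explicitly because
the null construction is underdetermined by a histogram alone; its
false-positive rate calibrates below the nominal 5% on homogeneous
synthetic fish.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth
(`gen_population()`, `gen_movie()`, `gen_pc_traces()`,
`gen_bout_train()`), each a pure function of its seed. Response classes
(`response_class()`) are noiseless drives — saturating ON/OFF functions
of luminance with thresholds and saturation points, an
intermediate-luminance bump, transition impulses, first-order ramps, and
a post-suppression ramp — optionally adapted with a class-specific time
constant and mixed with a transient component, then convolved with the
indicator kernel and normalized to unit peak so the amplitude parameter
reads as peak dF/F. The default recipe
(`default_population_recipe()`) mirrors the reported composition (eight
GC-like classes, six ION-like classes); classes additionally differ in
adaptation dynamics because, with only three nonzero luminance levels,
purely static tuning curves span a three-dimensional space and the
downstream cluster-regressor matrix would otherwise be rank-deficient.
The templates are mutually distinguishable (all pairwise correlations
below 0.8 on the steps protocol).

Noise is i.i.d. Gaussian per frame and trial (unresponsive cells can add
AR(1) drift); bouts are a thinned continuous-time Poisson process with a
0.5 s refractory period. What the generator does *not* emulate: shot
noise and photon statistics, neuropil contamination, slow photobleaching,
correlated (noise-correlation) variability across cells, non-rigid tissue
motion, and indicator nonlinearity. Passing recovery tests on these
synthetics therefore demonstrates the correctness of the analysis chain
under its own assumptions — not robustness to every artifact of real
recordings.

## Problem sizes and default conditions

The packaged analyses and tests run at deliberate scales: 64×64-pixel
movies with 20 planted cells and 360 frames for segmentation; 400-cell
populations with 6 repetitions at 0.5 s frame period for gating and
clustering; 30-cell populations with 12 repetitions for decoding; 50
synthetic PCs at the 248.88 ms cerebellum frame period, with per-frame
noise 0.3, for the attribution model; 36 stimulus repetitions at 0.8
bouts/s for behavior. Planted PC weights are drawn 3-of-14 uniform on
[10, 50]: unit-integral regressors have mean value ~1/T per frame, so
weights of tens produce order-one traces on the z-score scale — the
scale the model's 0–1000 coefficient bound anticipates.

## Known limitations

Rigid, integer-pixel registration only; no spike inference; the
dendrogram cut is manual by design; the decoders are limited to ridge and
RBF-SVR; reliability-based gating assumes repeated identical stimulus
presentations. The cluster count of real recordings depends on a manual
cut height that synthetic ground truth cannot choose for you.
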