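---
title: "Models and methods behind pose2thal"
author: "pose2thal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pose2thal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pose2thal links the posture and movement of a freely moving mouse,
reconstructed in 3D from multi-camera landmark tracking, to the spiking of
simultaneously recorded single units. This vignette explains the models the
package implements, the parameters that matter, the design decisions that
were genuinely open, and what the synthetic-data generator does and does not
emulate.

## The statistical shape model

The animal's body is tracked as `Np = 11` landmarks (nose, ears, head
stage, neck, body centre, flanks, hips, tail base). A pose is an `11 x 3`
matrix `X`. The statistical shape model (SSM) expresses a pose as

    X = (Xbar + sum_i b_i P_i) R + T

where `Xbar` is the mean pose, `P_i` are orthonormal eigenposes, `b_i`
their scores (the shape parameters), `R` a rotation, and `T = 1 t'`
replicates the translation vector `t` across landmarks. The model is
trained by generalized Procrustes superimposition of annotated poses with
the scale parameter fixed at 1, followed by probabilistic PCA on the
flattened (landmark-major: x, y, z interleaved per landmark) aligned poses.
The eigenvalues `lambda_i` are the retained sample-covariance eigenvalues
and the residual noise variance `sigma^2` is the maximum-likelihood
estimate, the mean of the discarded eigenvalues.

Two details are deliberate choices rather than forced:

* **Rotation family.** `procrustes_align()` and `fit_pose()` default to
  rotations about the vertical axis only (`rotation = "yaw"`). A freely
  moving rodent's pose is gravity-referenced: pitch-like deformation (body
  arch, rearing) is body shape, not camera-frame nuisance. Full 3D
  superimposition silently absorbs the pitch content of the arch mode into
  the rigid transform and deflates the leading eigenvalue (the test suite
  demonstrates this on sampled training sets). Full 3D rotation remains
  available (`rotation = "full"`).
* **Eigenpose count.** The number of retained eigenposes is the smallest
  count explaining 95% of variance (floor of 3) unless given explicitly.
  The first three scores are always exported as the behavioural variables
  body arch (`Bar`), body left/right (`Blr`) and body lunge (`Blu`).

## Robust pose fitting

Raw 3D poses come from direct-linear-transform triangulation of per-camera
landmark detections; landmarks seen by fewer than two cameras are missing,
and occlusions produce gross outliers. Each frame is therefore fitted by
minimizing, over the valid landmarks only,

    C(b, R, T) = sigma^-2 ||X - (Xbar + sum_i b_i P_i) R - T||_F^2
                 + alpha sum_i b_i^2 / lambda_i

with `alpha = 0.01`. The two blocks have closed forms: given `b`, `(R, t)`
is a rigid Procrustes problem; given `(R, t)`, back-rotating the data into
shape space leaves a ridge system `(sigma^-2 G + alpha Lambda^-1) b =
sigma^-2 g`. Alternating these exact half-steps decreases `C` monotonically;
iteration stops when the cost changes by less than `1e-8` (at most 100
iterations). Tests verify against a multi-restart generic optimizer that
the alternating scheme reaches the global optimum on random instances.
Note one consequence of the ridge term: on noise-free data the optimum
shrinks `b` by a factor of order `alpha sigma^2 / lambda_i`, so "exact"
recovery is only meaningful when `sigma^2` is small.

Outliers are removed by a chi-square loop: while `C` exceeds the inverse
chi-square CDF at probability 0.99 with `3 Np` degrees of freedom (`Np` =
current valid landmark count), the landmark contributing most to the data
term is dropped, `Np` decremented, and the pose refitted; removal stops at
a floor of 6 landmarks, below which the frame is flagged low-confidence.
The corrected pose is the model synthesis at the converged parameters,
which simultaneously fills in missing and rejected landmarks.

Two caveats are worth stating plainly. First, the probability level of the
threshold is a convention (0.99 by default, configurable); second, the
`3 Np` degrees of freedom do not account for the roughly `K + 4` parameters
the fit consumes, so the minimized cost on clean data sits near
`chi2(3 Np - K - 4)` and the loop flags clean frames at a rate an order of
magnitude below `1 - 0.99`. The rule is kept in this conservative form —
it under-flags clean data, never the reverse — and the package's
calibration simulation reports the realized rate rather than assuming the
nominal one.

Frames with fewer than four triangulated landmarks cannot be fitted at all;
they are imputed from the model prior (`b = 0`) at the last known rigid
parameters and flagged.

## Behavioural state variables

Fourteen variables are derived per frame from the corrected poses and fits:

* **Postures.** Head elevation `Hel` (degrees): elevation of the
  neck-to-nose vector above the horizontal plane. Head left/right `Hlr`
  (degrees): signed horizontal angle between the body midline (tail base to
  neck) and the neck-to-nose vector, positive leftward (counter-clockwise
  from above). `Bar`, `Blr`, `Blu`: the first three shape scores. Rearing
  `Re`: the vertical translation `t_z`.
* **Movements.** The six temporal derivatives `dHel ... dRe` (consecutive-
  frame differences times the frame rate, masked at epoch starts),
  locomotion `Lc` (planar displacement of the body centre per frame step)
  and overall motion `OM` (summed 3D landmark displacement per frame step).
  `OM` uses the sum convention across landmarks; sum and mean differ by the
  constant `1/11`, which z-scoring erases.

All variables are z-scored per session before any coupling analysis.
Derivatives are computed on raw postures and then z-scored.

The variable-grouping analysis discretizes each variable into five
equal-occupancy levels, estimates bias-corrected mutual information for
every pair, converts the matrix to the dissimilarity
`1 - MI / max(off-diagonal MI)` (clipping negative corrected estimates at
zero), and clusters with weighted pair-group (WPGMA) linkage. The
MI-to-distance transform is a package choice; the two-cluster cut separates
postures from movements on typical synthetic sessions (see the generator
section for the honest caveat).

## Information estimation

Spike counts in 0.67 s bins are related to discretized behavioural
variables through Shannon information, `MI = H(R) - H(R|S)`, computed from
joint frequency histograms. Counts are top-coded at their 99th percentile
to bound the response alphabet; behavioural variables use five quantile
levels (5 x 5 joint states for pairs). The plug-in estimator's upward bias
is corrected by quadratic extrapolation: the estimate is recomputed on
random halves and quarters of the data (10 random subsamples each), a
quadratic in inverse sample size is fitted through the three points, and
its intercept is the reported value. Calibration targets: on a binary
symmetric channel with flip probability 0.11 and `n = 10^4` the corrected
estimate is within 0.02 bits of the closed form (0.50 bits); on independent
data it is within 0.02 bits of zero; and correction reduces the mean
absolute error relative to the plug-in at `n = 250, 1000, 4000`.

For pairs of variables, the single-variable control re-estimates the pair
MI after permuting the time order of one variable or the other and keeps
the larger value, so that the one- and two-variable estimates share the
same state space and bias.

## Correlograms, coherence, prediction

**Cross-correlograms** use 0.0667 s count bins, lags up to 2 s (61 lags).
Counts and variable are standardized within each recording epoch, the
correlogram is computed per epoch (normalized so the zero-lag
self-correlation is exactly 1 and all values lie in `[-1, 1]`), and epochs
are averaged weighted by length. Significance uses a permutation null that
shuffles the order of the count epochs 1000 times while the behaviour stays
in place; a curve is significant when any lag leaves its `[0.0005, 0.9995]`
null band. A quantile that extreme cannot be resolved from 1000 values at a
single lag (the closest order statistics give a markedly larger effective
level, inflating the familywise error severalfold), so each lag is
studentized by its null mean and SD and the extreme quantiles are estimated
from the standardized values pooled across the exchangeable lags; the
validation suite measures the realized familywise error on 10^4 independent
synthetic units against the nominal `1 - 0.999^61 = 5.9%`. Positive lags
mean spiking follows behaviour. A batched implementation vectorizes the identical computation
across units for calibration studies; tests assert bit-level agreement with
the per-unit path.

**Coherence** is Welch magnitude-squared coherence (Hann window, 64-bin
segments, 50% overlap) per epoch, averaged across epochs, from 0 to the
7.5 Hz Nyquist of the frame rate; the null band is the mean plus/minus two
standard deviations over 100 circular random shifts of the behavioural
series within epochs.

**Encoding/decoding** uses gradient-boosted trees (learning rate 0.025, 500
rounds, maximum depth 3, gamma 1, subsample 1, CPU histogram method) with a
Poisson log-likelihood objective for count targets and squared error for
continuous targets. The series is bisected into two halves at an epoch
boundary; the first half trains and the held-out Pearson correlation on the
second half is the accuracy. The shift control swaps the two halves of the
feature series, destroying the association while preserving within-half
temporal structure.

**Tuning stability across conditions** concatenates each unit's `Bar` and
`OM` correlograms, correlates them between conditions per unit, and
compares the mean against 10,000 random re-pairings of units.

## Unit typing

Each unit is summarized as a 5 x 5 grid of mean firing rate over joint
quantile bins of `Bar` and `OM`; cells with fewer than 5 samples are
imputed with the unit's mean rate and flagged, and the grid is z-scored on
the occupied cells. Units are connected when the Spearman correlation of
their flattened grids strictly exceeds the median of the off-diagonal
correlation distribution (edge density one half by construction). The graph
is partitioned by Newman's leading-eigenvector method: bisect along the
sign of the leading eigenvector of the modularity matrix, recurse with the
generalized modularity matrix, stop when the leading eigenvalue or the
modularity gain is non-positive. Each bisection is fine-tuned by greedy
single-vertex moves — the refinement stage of the spectral method — because
on small random graphs the bare eigenvector split regularly lands more
than 5% below the exhaustive bipartition optimum, while the refined split
passes the suite's exhaustive-oracle comparison (`refine = FALSE` restores
the bare split). The community with the higher mean z-rate in the top
`Bar` quantile is labelled look-up, the rest look-down; a single community
returns "unclassified".

## The synthetic generator

The generator produces sessions with the statistical structure the analysis
assumes, with exact ground-truth bookkeeping:

* **Recording protocol.** 15 Hz frames in epochs of 15-24 s separated by
  30-40 s gaps; epochs are simulated independently from stationary initial
  conditions.
* **Kinematics.** Shape scores follow first-order mean-reverting dynamics
  around state-dependent targets. Three latents organize the session the
  way spontaneous exploration does: a slow up/down latent (quiet rest with
  crouched targets, active exploration, and rearing bouts that drive the
  arch and lunge scores while the vertical translation tracks the positive
  part of the arch score); a slow turn latent driving the lateral-bend
  score, with variance gated by the up/down state (curled rest posture with
  a random side per quiet episode, straightened body during rears) and an
  independently-sided head tuck driving the head-sweep mode; and an
  independent log-normal motion-energy latent multiplying all fast
  innovation SDs, which couples the movement variables to each other
  without coupling them to posture. Locomotion bouts translate the body
  at a set speed along a diffusing heading; trajectories reflect at the
  arena walls.
* **Ground-truth shape model.** A hand-constructed 11-landmark mean pose
  with four orthonormal modes: body arch, lateral bend, fore-aft lunge and
  a head-only lateral sweep. The head sweep exists so that head and body
  left/right angles are correlated but not redundant copies of one score.
  Rigid displacement fields are projected out of every mode.
* **Observations.** Pinhole projections into a four-camera rig (azimuths
  0/90/180/270 degrees, elevation 30 degrees), isotropic Gaussian pixel
  noise, a configurable fraction of large-displacement outliers (at least
  20 times the noise SD) and missing detections, all logged exactly.
* **Spikes.** Inhomogeneous Poisson counts with
  `rate = exp(baseline + beta_ud * Bar_z + beta_om * OM_z)` spikes/s,
  spike times uniform within bins, optional coupling lag. The default
  population is half look-up (`beta_ud = +0.5`), half look-down (`-0.5`),
  all positively motion-modulated (`beta_om = 0.5`), baseline 5 spikes/s.

What the generator does **not** emulate: photorealistic detector behaviour
(2D errors are iid, real detector errors are correlated in time and across
landmarks), smooth musculoskeletal dynamics (first-order processes leave a
`1/f^2` spectral tail, so strong instantaneous couplings remain weakly
coherent above 2 Hz instead of vanishing there), eye/pupil state, arousal
covariates, and inter-animal variability. Passing tests on this generator
demonstrate correctness of the estimators and the recovery machinery under
the assumed statistical structure, not performance on real videography.

One property is deliberately qualitative: with default motif parameters the
two-cluster cut of the MI matrix separates postures from movements on most
sessions, and the test suite pins one such seed. The split is a discrete
function of a noisy matrix and is not guaranteed for every seed.

## Problem sizes and tolerances

The validation suite uses: 350 training poses for shape-model recovery
(eigenvalue fractions within 3 percentage points, `sigma^2` within 10%);
50 random instances for the fit-vs-optimizer comparison at `1e-6`; 2000
corrupted and 10^4 clean frames for the outlier loop; 10^4 samples for the
information calibrations; 10^4 independent units (10 epochs of 15 s at the
correlogram bin) for the familywise-error measurement and 60 lag-coupled
units for peak recovery; a 10-minute session with 60 units for the
look-up/look-down recovery; 200 random graphs of up to 12 nodes against
the exhaustive bipartition oracle; and 50 seeded encoding runs. These sizes
are the package's validation conditions; `scripts/acceptance.R` recomputes
all of them from scratch.
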