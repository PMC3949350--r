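---
title: "Choice probability from ongoing behavior: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choice probability from ongoing behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behaviorcp)
```

`behaviorcp` quantifies how much a rodent's continuous head trajectory
predicts its binary report in a duration-categorization task. This vignette
is the package's account of the underlying models: what is assumed, which
parameters matter and why they default to the values they do, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The task and its observables

On each self-initiated trial two brief tones (150 ms, 7 kHz) delimit an
interval drawn uniformly from eight durations
{0.6, 1.05, 1.26, 1.38, 1.62, 1.74, 1.95, 2.4} s, symmetric about a 1.5 s
categorical boundary in four difficulty levels. The animal reports
"long" or "short" at lateral nose ports; correct reports are rewarded,
errors are punished with an 11 s timeout, and pokes before interval offset
("premature" responses) are punished the same way and force the stimulus to
repeat so long intervals cannot be skipped. Head position is filmed from
above and reduced to its component along the axis on which the nose ports
are aligned; motion orthogonal to that axis (including out-of-plane motion,
which a top-mounted camera cannot see) is discarded.

## The generative model behind the synthetic sessions

No behavioral dataset ships with the package, so every analysis is
validated on synthetic sessions whose ground truth is known. The generator
(`simulate_session()`) encodes exactly the statistical structure the
analysis chain is designed to detect:

* **Choice.** Trial $t$'s probability of a long report is
  $\mathrm{logit}^{-1}\!\big(\beta\,(\ln I_t - \ln 1.5) + b + z_t + w\,R_{t-1}\big)$
  with slope $\beta$ on log-duration, constant bias $b$, a latent bias
  $z_t$, and the signed previous-reward code $R_{t-1} \in \{-1, 0, +1\}$
  (+1 after a rewarded long choice, −1 after a rewarded short choice, 0
  after no reward).
* **Latent bias.** $z_t$ is AR(1) across trials,
  $z_t = \rho z_{t-1} + \varepsilon_t$, stationary SD $\sigma_z$. A slowly
  drifting state is a modeling choice, not an empirical claim: nothing in
  the phenomenon pins down the temporal statistics of the bias, and the
  analyses below do not depend on $\rho$ (they only require that $z$ exists
  and couples to both choice and trajectory). Default $\rho = 0.9$.
* **Trajectory.** Row $t$ of the trajectory matrix is
  $T_s(\tau) + g\, z_t\, m(\tau) + \eta_t(\tau)$ on a grid from −0.5 s to
  2.5 s around interval onset: an idiosyncratic per-subject template
  $T_s$ (smooth periodic profiles, near-orthogonal between subjects), the
  latent bias carried into behavior by a fixed half-cosine ramp $m(\tau)$
  that rises from −0.5 s to +0.5 s and then saturates (so coupling is
  time-extended and already present before onset), and temporally smooth
  AR(1) noise $\eta$ (time constant 0.1 s). With coupling gain $g = 0$ the
  trajectories carry no choice information by construction — the null used
  to calibrate every significance procedure.
* **Premature responses** occur with probability proportional to the
  stimulus duration (longer waits, more premature pokes), are never
  rewarded, and force the next trial's stimulus to repeat.

### Parameter defaults and their calibration

| parameter | default | units | rationale |
|---|---|---|---|
| `psycho_slope` | 10 | 1/log-s | with $\sigma_z = 1$, marginal accuracies are ≈ 96% / 67% / 84% on easiest / hardest / all stimuli, the regime of well-trained subjects in this task |
| `latent_noise_sd` | 1.0 | logit | same calibration; also yields CP-bin bias spans of a few hundred ms, the size of bias effect the method is meant to resolve |
| `latent_ar_coeff` | 0.9 | — | decorrelation over ~10 trials: slow relative to a trial, fast relative to a session |
| `history_reward_weight` | 0.4 | logit | a previous-reward effect of the magnitude that a model-3-style GLM detects with a likelihood ratio in the low hundreds at a few thousand trials |
| `traj_coupling_gain` | 4 | px/logit | equal to the trajectory noise SD, so single-timepoint CP is modest while the 120-dimensional window is clearly informative |
| `traj_noise_sd`, `traj_noise_tau` | 4 px, 0.1 s | | smooth wander of a head held near a port |
| `premature_rate_base` | 0.067 | prob. | mean premature rate of trained rats |
| trials/session | 456 | | mean daily session length for trained rats |

Seeded runs are bit-identical; `simulate_experiment()` derives per-session
seeds from a master seed by stable hashing (`stage_seed()`), so any session
can be regenerated in isolation.

### What the generator does not emulate

Real trajectories are not Gaussian about a template: animals exhibit
discrete postural classes, occasional grooming, and out-of-plane motion
that the port-axis projection cannot represent (one real subject timed
intervals essentially motionlessly — a regime in which instantaneous CP is
uninformative even though choice-predictive micro-movements may exist).
Choice lapses, motivation drifts tied to reward history, and
session-boundary effects are absent. Passing tests therefore certify the
*estimators* — calibration of nulls, recovery of planted effects,
correctness of formulas — not that real data will show these effects.

## Instantaneous choice probability

At each timepoint the head positions of long- and short-choice trials are
compared by the area under the ROC curve, computed from midranks (exactly
equivalent to exhaustive pair counting with ties worth ½) and rectified
about 0.5 so that CP ∈ [0.5, 1] measures separability regardless of
direction. Chance level is estimated by shuffling choice labels 100 times
and taking the per-timepoint 95th percentile of the shuffled (rectified)
CPs; a timepoint is significant when its CP exceeds that band. The band is
one-sided by construction — rectified CP can only exceed chance — and its
empirical false-positive rate on null data is the nominal ~5% (verified
over 500 decoupled synthetic series in the test suite). Because ranks do
not depend on labels, the implementation ranks each timepoint once and
re-aggregates per shuffle, making the 100-shuffle null cheap. The analysis
is applied separately per subject and stimulus; `select_max_variance_stimulus()`
implements the convention of profiling the stimulus with the highest
pooled choice variance.

## Trajectory-level choice probability

Trajectory vectors are head positions in the 1 s window centered on
interval onset, resampled to a common 120-sample grid when the source
frame rate differs (90 fps mouse video is linearly interpolated). This
window precedes any stimulus information, so trials of all stimulus types
pool.

Class-conditional densities $P(\mathbf{H}\,|\,C)$ are Gaussian mixtures fit
by weighted EM: weights enter as multiplicities in responsibilities and
sufficient statistics, each trial weighted by the binomial choice variance
$n\hat p(1-\hat p)$ of its (session, stimulus) cell. The rationale: for
easy stimuli the stimulus itself is a near-sufficient predictor of choice,
so only ambiguous cells can reveal trajectory-driven variability;
unanimous cells get weight 0 and provably no influence. Priors $P(C)$ use
the same weights. Posteriors are evaluated entirely in the log domain
(Cholesky factors, log-sum-exp), so extreme trajectories cannot produce
`NaN`, and the posterior is invariant to any common rescaling of the
likelihoods.

Numerical choices: 2 components per class with full covariances (the
density is at least bimodal-capable without inviting degeneracy), a
$10^{-6}$ ridge on covariance diagonals escalated tenfold on Cholesky
failure, seeded k-means initialization, and weights normalized to mean 1
per class for optimizer stability. A flat-weight fit is available by
passing `weights = NULL`.

**Dimensionality guard.** A full 120-dimensional covariance has 7260 free
parameters per component; fitting it from a few hundred effective trials
memorizes the training set, and the in-sample posteriors saturate at 0 or
1 — at which point CP bins capture choice identity rather than the
underlying bias. The guard therefore measures each class's *effective*
sample size (Kish, $(\sum w)^2/\sum w^2$, equal to the raw count under flat
weights — the choice-variance weights typically halve it) and, below 5
effective trials per dimension-parameter per component, fits in the
subspace of leading principal components retaining ≥ 90% of pooled
trajectory variance. At the trial counts where this analysis is run in
practice (thousands of pooled trials per subject) the guard caps the
model around 15 dimensions for the default generator; the threshold and
retained-variance fraction are exposed as arguments.

Trials are then split into 6 equal-count bins of posterior CP (quantile
binning, stable tie-breaking) and a psychometric function is fit per bin.
Under the generative model the bias points must order monotonically in bin
index — higher $P(\text{long}\,|\,\mathbf{H})$ means a shorter duration is
judged long half the time — while every bin's curve still asymptotes near
0 and 1 at the extreme stimuli: a bias effect, not a lapse. One asymmetry
is worth knowing: the stimulus set spans 0.92 log-units below the boundary
but only 0.47 above, so the long-side asymptote of the most short-biased
bin is the tightest of the four and approaches its nominal value only at
pooled-subject trial counts (thousands of trials).

## Psychometrics

Session fits are plain maximum-likelihood logistic regressions of
P(long) on log-duration; the log scale is the default because the stimulus
set is near-geometric in difficulty spacing (linear duration is available,
and the two differ only slightly over this 4:1 range). No lapse parameter
is fit — well-trained subjects' curves reach 0 and 1 — and complete
separation is flagged (`converged = FALSE`) rather than penalized, since a
separated session carries no usable slope estimate. Subject summaries
average the fitted parameters over converged sessions and recompute the
bias point from the averaged parameters. Session screening by performance
on the easiest stimuli is a configurable filter (`filter_sessions()`), not
an automatic step.

## Trajectory similarity

Reproducibility is measured on the trials of the longest interval (the
longest uninterrupted unfolding of the behavioral sequence), over the
window [0, 2.4) s by default (configurable; the exact analysis window is
not dictated by anything structural). Pearson correlations between all
trial pairs are partitioned into same-session, same-subject/different-
session, and different-subject groups; trajectories are not z-scored first
since Pearson is location/scale invariant pair-wise. Flat (zero-variance)
trajectories have undefined correlations and are excluded with a count.
Group distributions are compared with two-sample KS tests; when the
asymptotic tail underflows (`ks.test` returns `NA` at extreme D with large
samples) the Kolmogorov series is evaluated directly.

## Head tracking

The tracker follows the standard background-subtraction recipe: per-pixel
median background (robust to the animal's transit as long as it occupies
each pixel in under half the frames; mean is available), absolute
difference thresholded to a binary image, largest 8-connected component
kept if it reaches the minimum blob area. The blob's principal axis comes
from the second-order moments of the mask; its endpoints are the extreme
mask pixels along that axis, and the head end is chosen as the endpoint
nearest the previous frame's head (the first frame takes a caller hint).
Near-circular masks have no well-defined axis and are flagged degenerate.
Missing detections are filled by linear interpolation up to 5 consecutive
frames; longer gaps flag the trial unusable. Threshold (40/255), minimum
blob area (20 px) and the tip rule are package defaults — the upstream
recipe specifies none of them — validated end-to-end on rendered
fixtures with planted paths (recovery to well under 2 px RMSE).

## The choice-GLM ladder

The four models are specified as main-effect term sets over subject
(categorical), current interval (linear seconds — the ladder's convention,
distinct from the psychometric module's log default), the first two
trajectory PC scores (PCA pooled across the whole dataset, not per
subject), and the three history variables. Exclusions: the first trial of
each session, premature trials, and their immediate successors. Criteria
use the binary-response identities deviance = −2 log L,
AIC = deviance + 2k, BIC = deviance + k ln n with k counting all estimated
coefficients including the intercept. Prediction success is in-sample
(fitted P ≥ 0.5 predicts long; ties go to long — some rule is needed and
none is canonical).

Stepwise refinement is greedy best-first over single moves: remove a term
(main effects only when not involved in a retained interaction) or add a
pairwise interaction between current main effects — final specifications
in this family of analyses contain only pairwise interactions — accepting
the move with the lowest BIC until none improves. The search is
deterministic given the data; ties resolve by candidate order. Perfect
separation in any fit is flagged and its coefficients replaced by a
lightly ridge-penalized refit (λ = 10⁻³ on non-intercept terms), keeping
the reported deviance finite. Likelihood-ratio tests are only run for
pairs whose expanded term sets are ordered by inclusion; anything else is
refused rather than silently computed.

## Problem sizes used in validation

The test suite validates the chain at sizes chosen to make each property
measurable: 1000 random samples for exact auROC/pair-counting equivalence;
500 null series × 100 shuffles for the 5% ± 2% false-positive calibration;
20 replicates of 3600-trial subjects (the scale of a subject's pooled
sessions) for the CP-bin bias ordering and asymptote checks; 50 + 50
replicates of 5000-trial, 3-subject experiments for model-ladder recovery
(full model wins with both effects present, base model with neither, ≥ 90%
of replicates each); 100 sessions of 450 trials for psychometric bias
recovery to < 50 ms median error; and noiseless rendered stacks for
tracking recovery (< 2 px RMSE, r > 0.99).

## Known limitations

* The GMM posterior is estimated in-sample, as is conventional for this
  analysis; the dimensionality guard controls, but does not eliminate,
  optimistic bias in single-trial CP at small effective sample sizes.
  A cross-fitted variant would trade that bias for noisier bins.
* Instantaneous CP requires overt movement; a subject that times
  motionlessly yields flat trajectories and (correctly) uninformative CP.
* The tracker is single-animal, 2-D, and assumes a static background.
* Premature-response modeling is minimal (rate scales with duration); the
  GLM stage excludes those trials anyway.
* `compare_models()` tests nesting on term labels after interaction
  expansion; models built outside the package's term vocabulary should be
  compared by hand.
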