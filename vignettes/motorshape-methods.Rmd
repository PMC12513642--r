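---
title: "Elastic shape analysis of wearable movement curves: models and methods"
author: "motorshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic shape analysis of wearable movement curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(motorshape)
```

## The problem

Wrist-worn gyroscopes record angular velocity while children with
neuromuscular disorders (Duchenne muscular dystrophy, spinal muscular
atrophy) and healthy controls perform simple activities of daily living such
as an arm curl or a knocking motion. Each repetition yields one scalar curve
$\beta_i(t)$ (deg/s). Two children performing the *same* movement produce
curves that differ both in *amplitude* (how large and how shaped the
velocity profile is) and in *phase* (when, within the repetition, each part
of the movement happens). Phase variability is severe in paediatric data —
movement tempo varies hugely with age and ability — and it corrupts naive
cross-sectional statistics: the pointwise mean of temporally misaligned
curves is flattened and skewed even when every individual curve has the same
symmetric shape. `motorshape` implements the elastic (square-root velocity)
framework that separates these two sources of variation, summarizes the
amplitude variation by interpretable principal modes, and condenses those
modes into a single clinically anchored motor-function index.

Angular velocity is used rather than linear acceleration because it is
insensitive to limb length, which differs strongly across a growing
paediatric cohort. Each repetition is resampled to a common uniform grid of
$N = 200$ points and its time axis rescaled to $[0,1]$; nothing is lost by
the rescaling because gyroscope values are rates, so between-subject speed
differences survive in the amplitude of the curve.

## Elastic registration

A time warp is a boundary-pinned, strictly increasing reparameterization
$\gamma : [0,1] \to [0,1]$. Under the square-root velocity function (SRVF)

$$q(t) = \operatorname{sign}(\dot\beta(t))\sqrt{|\dot\beta(t)|},$$

warping acts by $(q, \gamma) \mapsto (q \circ \gamma)\sqrt{\dot\gamma}$,
which preserves the L2 norm. The optimal alignment of curve 2 onto curve 1,

$$\gamma_2^\ast = \arg\min_\gamma \| q_1 - (q_2\circ\gamma)\sqrt{\dot\gamma}\|^2,$$

is solved by dynamic programming over monotone lattice paths whose local
slopes lie in $\{p/q : 1 \le p,q \le 3\}$; ties between equal-cost paths are
broken toward the diagonal so the least-warping minimizer is returned
deterministically. The attained misfit is the *amplitude distance* $d_a$,
which is invariant (up to discretization) to arbitrary warps of either
input: it compares what was done, not how fast.

Two numerical refinements matter in practice and are part of the package's
design:

* **De-quantization of the lattice warp.** The DP path pins $\gamma$ to
  grid nodes and its slopes to a seven-element ratio set; the resulting
  slope zigzag inflates the misfit because SRVFs have square-root cusps
  wherever $\dot\beta = 0$. After a short symmetric smoothing pass, each
  node of the warp is polished by a coarse-to-fine golden-section coordinate
  descent on the continuous objective. Every node is constrained to stay
  within a few grid steps of its DP position: the refinement removes
  quantization error, it is not a free optimizer. Unconstrained node-wise
  optimization was rejected because, on noisy curves, it chases measurement
  noise and pinches the warp.
* **Derivative and inversion conventions.** $\dot\beta$ is computed by
  centred differences (one-sided at the endpoints), the inverse SRVF map by
  cumulative trapezoidal quadrature, and all norms and inner products by the
  same $(T/J)\sum_j f(t_j)^2$ rule, so distances, PCA inner products and
  projections are mutually consistent.

The Karcher (Fréchet) mean shape minimizes
$\sum_i \min_{\gamma_i} \|q - (q_i \circ \gamma_i)\sqrt{\dot\gamma_i}\|^2$
and is computed by alternating alignment and averaging. The iteration stops
when the relative L2 change of the mean falls below `tol` (default
`5e-3`): re-alignment has a small discretization jitter of about
$10^{-3}$–$2\times 10^{-3}$ in relative terms, so markedly tighter
tolerances are never reached and the loop would always exhaust `max_iter`.
The mean is initialized at the input SRVF closest to the cross-sectional
SRVF average, which is deterministic and robust to the warps in the inputs.

Each curve is then decomposed as $\beta_i = \tilde\beta_i \circ \gamma_i^*$
into an amplitude $\tilde\beta_i$ (the aligned curve) and a phase
$\gamma_i^*$. By default the phases are re-centred so that their pointwise
mean is the identity; because warp composition is nonlinear the centring is
iterated (at most five times) until the mean phase is the identity to
$10^{-4}$. The accumulated correction is composed into each warp **once**
and the curves re-warped from the originals — re-warping already-warped
curves repeatedly compounds interpolation error into a systematic artefact
mode that contaminates the smaller principal components. Centring makes
"the mean shape is symmetric when the underlying movement is symmetric" a
well-posed statement: the symmetric representative of the amplitude class
is the one whose phases average to the identity.

```{r bump-demo, fig.height = 3.2}
be <- bump_ensemble(21, warp_intensity = 0.8, seed = 1)
km <- suppressWarnings(karcher_mean(be$curves))
op <- par(mfrow = c(1, 2))
matplot(sapply(be$curves, `[[`, "values"), type = "l", lty = 1,
        col = "grey70", ylab = "value", xlab = "sample",
        main = "warped symmetric bumps")
plot(be$template$grid, euclidean_mean(be$curves)$values, type = "l",
     col = "red", lwd = 2, xlab = "t", ylab = "value",
     main = "Euclidean (red) vs shape mean (blue)")
lines(be$template$grid, km$mean_trajectory$values, col = "blue", lwd = 2)
par(op)
```

## Vertical (shape) PCA

After phase removal, functional PCA is performed in SRVF space: the aligned
SRVFs are mean-centred, their covariance (with $1/(n-1)$ normalization) is
decomposed by SVD, and the projections
$c_{ik} = \langle q_i - \mu, U_k \rangle$ are the *vertical principal
components* (VPCs). Components are orthonormal under the discrete L2 inner
product and their sign is fixed so each component is nonnegative at the
grid point of maximal raw variance; sign alignment *across* repeated fits
is handled separately (below). In gyroscope data VPC1 is a speed/scale mode
and VPC2 an asymmetry mode (a weakened upward phase against a
gravity-assisted downward phase); `mode_traversal()` reconstructs
$\mu \pm s\sigma_k U_k$ as curves so modes can be labelled by eye, and
`asymmetry_statistic()` — the normalized peak–trough imbalance
$(|peak| - |trough|)/(|peak| + |trough|)$ — labels them objectively.

Defaults: three components are retained per activity for reporting; the
index uses VPC1 and VPC2 of each activity (four features).

## Handling repeated visits

Subjects contribute unequal numbers of visits. Shape PCA is therefore
refitted `n_runs` times (default 100), each run using one uniformly sampled
visit per subject; each run's components are sign-aligned to the first
run's (a component is flipped when its inner product with the reference
component is negative), and the per-subject scores are averaged across
runs. The across-run standard deviation is kept as a dispersion diagnostic.
A projection-only mode (`refit = FALSE`) fits the alignment and PCA once on
all curves and only resamples which visit's projections enter the average;
it is much faster and appropriate when the alignment is stable.

## The motor-function index

The wearable block $X$ (four VPC features) and the clinical block $Y$ (age,
average echogenicity, normalized elbow torque, Brooke score) are related by
two-block PLS in canonical mode: both blocks standardized, per component
the weight pair is the leading singular-vector pair of the cross-covariance
matrix, and both blocks are deflated symmetrically on their own scores.
Canonical mode was chosen (over regression mode) because the figure of
merit is a *canonical correlation* between paired latent scores; the mode
is configurable in spirit but canonical deflation is the implemented
default. The first component's X-side weights define the index. Healthy
controls are excluded from the index fit because the Brooke score is only
collected in patient cohorts; the complete-case rule enforces this
automatically.

Sampling variability is quantified by a subject-level bootstrap (default
10000 replicates): each replicate draws `round(0.7 n)` subjects with
replacement as a training set, holds out the subjects never drawn, fits PLS
on the training set and records the Pearson correlation of the held-out
subjects' paired first scores — the *test canonical correlation*. The
hold-out is a by-product of sampling with replacement, so its expected size
(roughly half the subjects) exceeds the nominal 30%; replicates with fewer
than three held-out subjects or a zero-variance score are skipped and
counted. Replicate weight vectors are flipped to have positive inner
product with the full-data point fit so coefficient histograms are
comparable. Both the 2.5–97.5 and the 5–95 percentile intervals are
reported; the 5–95 pair is the default display.

The identical bootstrap harness is applied to two baselines —
functional PCA of the unaligned curves (`stats::prcomp`) and non-negative
matrix factorization of the unaligned, non-negatively shifted curves
(seeded Lee–Seung multiplicative updates, written in-package because no
NMF implementation is available among the package's dependencies) — so the
comparison isolates the effect of elastic alignment rather than any
difference in the statistical machinery.

## Age trends

Per-visit VPC1 scores are modelled with `lme4::lmer` as
`score ~ age * cohort + (1 | subject)`: a random intercept per subject
absorbs repeated visits, and the age-by-cohort interaction measures whether
a patient cohort's speed mode drifts with age faster than the healthy
reference. Inference uses two-sided Wald $z$-tests on the fixed effects with
Benjamini–Hochberg correction across the non-intercept coefficients and a
significance level of $\alpha = 0.01$. Singular fits are reported through an
attribute, never raised as errors.

## The synthetic cohort generator

The study's wearable recordings are not public, so the package ships a
generator whose output has the statistical structure the analysis assumes,
with full ground truth. It is first-class, tested code, and every
downstream validation runs against it.

* **Templates.** `curl` is a normalized Gaussian derivative (one positive,
  one negative lobe), `knock` a Gaussian-windowed sine with two cycles. The
  `speed` latent scales amplitude linearly and compresses the movement
  width by $1/\sqrt{speed}$ — under per-repetition time normalization most
  of a speed difference appears as amplitude, with a mild duration
  signature. The `asymmetry` latent scales the positive-going part by
  $(1-a)$ and the negative-going part by $(1+a)$, a balanced contrast that
  is orthogonal to pure scaling, so the two latents generate distinct modes
  of shape variation; for a curl at unit speed,
  `asymmetry_statistic` $= -a$ exactly.
* **Warps.** $\gamma(t) = t + a\sin(\pi t)/\pi$ with
  $a \sim U(-c, c)$, $c \in [0,1)$; the derivative $1 + a\cos(\pi t)$ is
  strictly positive, so every draw is admissible.
* **Cohorts.** Defaults mirror the analysis set of the motivating study
  design (DMD 15, SMA 7, Healthy 9), one to three visits each, activities
  curl and knock. Patients are slower on average and decline with age
  (speed latent slope −0.010/yr for DMD, −0.015/yr for SMA), SMA carries
  the largest asymmetry latent, and per-visit jitter, sinusoidal warps
  (intensity 0.4) and i.i.d. observation noise (SD 0.03 on unit-scale
  curves) are applied per repetition. Clinical covariates are noisy linear
  functions of the latents: Brooke (ordinal 1–6, patients only) and
  echogenicity increase as speed drops and asymmetry rises, torque tracks
  speed, echogenicity additionally drifts with age.
* **Bump ensemble.** For the registration demonstration, a symmetric bump
  is scaled by per-curve amplitudes and warped. The drawn warp coefficients
  are centred (and rescaled back into range, not clipped, so the centring
  is exact) — the ensemble carries timing variability but no net phase
  drift — and amplitude is mildly coupled to the warp coefficient, as slow,
  late repetitions in real data are also performed larger. The coupling
  gives the Euclidean mean a systematic skew instead of one that averages
  away with $n$, which is precisely the failure mode elastic registration
  repairs.
* **Feature-level generator.** `simulate_features()` emits $X$ with i.i.d.
  standard-normal columns, a latent $u = Xw$ with known unit weights, and
  $Y = u\mathbf{1}^\top + \varepsilon$ at a chosen per-column
  signal-to-noise variance ratio; it validates the PLS layer in isolation,
  including against a 50 000-sample population fit.

What the generator does *not* emulate: biomechanically realistic limb
dynamics, accelerometer channels, raw 200 Hz sensor streams, segmentation
artefacts, or missing/corrupted repetitions. Passing tests therefore
demonstrate that the pipeline recovers structure *of the kind it models*;
they cannot certify behaviour on pathologies the generator does not
contain.

## Noise and pre-smoothing

The SRVF transform differentiates the curve, which multiplies white
observation noise by roughly $\sqrt{2}/(2h) \approx 140$ at $N = 200$ —
enough to drown the derivative signal at realistic sensor noise. Noisy
curves must be smoothed before elastic analysis; `smooth_trajectory()` fits
a GCV-selected cubic smoothing spline and is applied by default inside
`run_pipeline()` (`pre_smooth = TRUE`). The SRVF transform itself keeps
pre-smoothing off by default so that the elementary operations remain exact
on clean inputs.

## Validation design and problem sizes

The test-suite and the acceptance script validate each claim at sizes
chosen to finish comfortably on a single CPU while leaving clear margins:
DP-versus-exhaustive equality on 16-point grids (50 pairs; the exhaustive
search shares the DP's edge costs but enumerates every admissible path);
warp invariance of $d_a$ on 100 same-activity template pairs with a minimum
latent separation of 0.15 (a relative criterion is meaningless between
near-identical curves) and warp intensities up to 0.5, beyond which the
warp needed to undo the perturbation leaves the aligner's slope range;
mean-shape fidelity on the 21-curve bump ensemble at intensity 0.8; latent
recovery on a 200-subject single-activity cohort; PLS recovery at
$n = 200$, SNR 3:1, against a 50 000-sample population oracle; and
mixed-model calibration over 100 simulations (coverage of 95% Wald
intervals and type-I behaviour at $\alpha = 0.01$). Bootstraps in tests use
200–2000 replicates; the package default remains 10000.

## Known limitations

* The aligner's slope range $[1/3, 3]$ bounds the warps it can express;
  extreme rate differences (beyond threefold local speed-ups) are clipped.
* $d_a$ is computed asymmetrically (curve 2 onto curve 1), exactly as the
  pairwise alignment problem is posed; symmetry holds only approximately on
  a finite grid.
* Elastic alignment can absorb a small part of genuine amplitude
  differences into phase ("pinching"); the bounded refinement and the
  slope-constrained lattice limit, but do not eliminate, this.
* Comparing structurally different movements (e.g. a one-cycle curl to a
  two-cycle knock) sits at the edge of the warp space and yields unstable
  distances; all cohort analyses compare within activity.
* The mixed model treats age as a between-subject covariate (cross-sectional
  design); longitudinal change modelling is out of scope.
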