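# motorshape

Elastic shape analysis of wrist-gyroscope movement curves and a
shape-based motor-function index for paediatric neuromuscular cohorts.

## What it is for

Children with Duchenne muscular dystrophy (DMD) or spinal muscular atrophy
(SMA) are still assessed with observational scales (e.g. the 6-point Brooke
Upper Extremity Scale) that are coarse and partly subjective. Wrist-worn
gyroscopes record angular velocity while a child performs simple activities
— an arm curl, a knocking motion — and every repetition yields a scalar
curve β(t) in deg/s. Paediatric curves differ wildly in *tempo* (phase) as
well as in *shape* (amplitude), and the tempo variation corrupts naive
pointwise statistics: the cross-sectional mean of misaligned curves is
flattened and skewed even when every child's movement has the same
symmetric profile.

`motorshape` implements the elastic functional-data pipeline for this
problem:

1. **SRVF registration.** Curves are represented by their square-root
   velocity function q = sign(β̇)·√|β̇|, under which time warping acts by
   the norm-preserving map (q∘γ)√γ̇. The optimal warp between two curves is
   found by dynamic programming over slope-constrained monotone lattice
   paths, and the residual misfit d_a(β₁, β₂) = inf_γ ‖q₁ − (q₂∘γ)√γ̇‖ is a
   rate-blind *amplitude distance*.
2. **Phase–amplitude separation.** The Karcher mean shape
   μ̂ = argmin_q Σᵢ min_γ ‖q − (qᵢ∘γ)√γ̇‖² is computed by alternating
   alignment and averaging; every curve is decomposed as
   βᵢ = β̃ᵢ ∘ γᵢ* into an aligned amplitude and a phase.
3. **Shape PCA.** SVD of the covariance of the aligned, mean-centred SRVFs
   yields vertical principal components (VPCs): in this data VPC1 is a
   speed/scale mode and VPC2 an asymmetry mode (weak upward phase,
   gravity-assisted downward phase).
4. **Motor-function index.** Per-subject VPC scores (averaged over repeated
   random-visit refits with sign alignment) form the wearable block X; age,
   muscle echogenicity, normalized elbow torque and Brooke score form the
   clinical block Y. Two-block canonical-mode PLS with a subject-level
   bootstrap (train on 70% drawn with replacement, test canonical
   correlation on the never-drawn subjects) yields the index — the first
   X-side weight vector — with percentile intervals, plus baseline
   comparisons against unaligned functional PCA and NMF, a per-cohort
   Pearson panel, and an age-by-cohort mixed model (`lme4`) with
   Benjamini–Hochberg-corrected Wald tests.

Because the motivating study's recordings are not deposited, the package
includes a fully seeded synthetic cohort generator (`generate_cohort()`,
`bump_ensemble()`, `simulate_features()`) with known speed/asymmetry
latents, random time warps, multi-visit structure and clinical covariates
tied to the latents, so every stage is testable against ground truth.

## Worked example

```r
library(motorshape)

co     <- generate_cohort(cohort_config(seed = 1))   # DMD 15 / SMA 7 / Healthy 9
curves <- lapply(co$curves, smooth_trajectory)       # sensor noise vs. SRVF derivative

curls <- curves[vapply(curves, `[[`, "", "activity") == "curl"]
sep   <- separate_phase_amplitude(curls)
sep
#> <separation> 58 curves, 9 iterations (converged), mean amplitude distance to mean shape 0.3645

pca <- fit_shape_pca(sep, n_retained = 3)
pca
#> <shape_pca> 58 curves, 3 retained components
#>   variance explained: VPC1 71.2%, VPC2 9.6%, VPC3 6.1%

emb <- repeated_shape_pca(curves, n_runs = 10, seed = 2)
pat <- co$clinical$subject_id[co$clinical$cohort != "Healthy"]
X   <- emb[emb$subject_id %in% pat, attr(emb, "features")]
Y   <- co$clinical[match(emb$subject_id[emb$subject_id %in% pat],
                         co$clinical$subject_id),
                   c("age", "avg_echo", "net", "brooke")]

idx <- bootstrap_pls(X, Y, n_boot = 2000, seed = 3)
idx
#> <motor_index> 22 subjects, 2000 bootstrap replicates (0 skipped)
#>   component 1: median r = 0.91, [5-95]% = [0.70, 0.98]
#>   index weights (full-data fit):
#>  VPC1_curl  VPC2_curl VPC1_knock VPC2_knock
#>     -0.688     -0.050      0.690      0.220
```

Reading the output: the first phase–amplitude separation aligns the 58 curl
repetitions and converges in 9 sweeps; shape PCA attributes 71% of the
aligned variance to the speed mode and 10% to the asymmetry mode; and the
bootstrapped canonical index correlates its wearable combination with the
clinical block at a median held-out Pearson r of 0.91. The index is
dominated by the two speed modes with opposite signs — in this
parameterization the curl and knock speed scores point in opposite
directions relative to latent speed, exactly the sign structure the
generator encodes.

`run_pipeline(pipeline_config(...))` executes all stages end to end
(separation, PCA, embedding, index, correlation panel, mixed model,
baselines) and writes CSV/JSON artifacts plus a manifest with per-stage
seeds; a fixed config reproduces every artifact bit for bit.

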