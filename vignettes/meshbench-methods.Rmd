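---
title: "Benchmarking MEG source reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking MEG source reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MEG source reconstruction is ill-posed: many cortical current distributions
explain the same sensor data, and every inversion algorithm resolves the
ambiguity with different prior assumptions. Comparing algorithms on a
hand-picked task or simulation biases the comparison toward whichever
algorithm's assumptions match that scenario. `meshbench` implements an
alternative: score algorithms by their *anatomical discrimination* on
resting-state-like data. Resting activity is partitioned into
quasi-stationary network states, each state's data is inverted onto a
library of progressively distorted copies of the cortical surface, and an
algorithm is judged by how small a distortion it can still statistically
distinguish from the true anatomy. The logic is that MEG data are generated
by currents normal to the grey-matter surface, so a better inversion should
be *more* sensitive to anatomical error.

The package runs this benchmark end to end on synthetic data (so every
stage has a known ground truth) and accepts user-supplied meshes, sensor
geometries, recordings and gain matrices at each module boundary.

## Pipeline

1. **Synthesis** (`gen_mesh`, `gen_sensor_array`, `simulate_recording`): a
   folded genus-0 cortex, a quasi-uniform magnetometer cap outside a
   spherical conductor, and a recording in which a small number of network
   states switch on a ~100-200 ms timescale, each state activating fixed
   cortical sources carrying band-limited (1-90 Hz) Gaussian time courses.
2. **Preprocessing** (`preprocess_recording`): zero-phase 4th-order
   Butterworth band-pass 1-90 Hz and band-stop 48-52 Hz, then resampling to
   250 Hz.
3. **State partitioning** (`pca_reduce`, `fit_hmm`, `epoch_modal`,
   `partition_states`, `dominant_states`): PCA to standardized components,
   a Gaussian-observation hidden Markov model decoded by Viterbi into a
   statepath, 200 ms epochs tagged by their modal state, and selection of
   the most-occupied states.
4. **Mesh libraries** (`build_library`): weighted Fourier series
   reconstructions of the true surface at harmonic orders 1..L_max.
5. **Forward models** (`gain_matrix`): Sarvas single-sphere lead fields for
   unit dipoles normal to each surface.
6. **Inversion** (`temporal_reduce`, `prior_*`, `reml_fit`, `map_sources`):
   empirical-Bayes covariance-component estimation, identical for all four
   algorithms except the prior source covariance.
7. **Benchmark** (`run_bench`, `group_stats`): held-out-channel
   cross-validation and free energy per mesh, normalized against the true
   mesh (dCV, dF), group statistics, the highest distinguishable harmonic
   (HDH), and its conversion to millimetres.

## Models and conventions

### Weighted Fourier series surfaces

Each vertex of a genus-0 mesh is mapped to the unit sphere (radial
projection for package-generated meshes, Laplacian inflation for external
ones), coordinates are expanded in orthonormal real spherical harmonics
S_lm, and the surface at order L is

    v_L(w) = sum_{l<=L} sum_m exp(-l(l+1) sigma) f_lm S_lm(w),

with the coefficients f_lm obtained by least squares on the vertex sampling
(`fit_wfs` solves the full system once; reconstructions are weighted partial
sums). The smoothing bandwidth sigma defaults to 1e-4; at the harmonic
orders used here the exponential weights are within a few percent of 1, so
the order L is the operative resolution control. Order 1 is a smooth ovoid;
the library approaches the true mesh as L grows. All library meshes share
the face array and vertex correspondence with the truth, so anatomical
error is summarized by corresponding-vertex distances, reported both as the
upper 95th percentile (the headline statistic, robust to the mass of
near-zero distances) and as the mean.

The harmonics are fully normalized, Condon-Shortley-free, and evaluated by
the standard three-term recurrence on normalized associated Legendre
functions, which is stable far beyond the orders used here.

### Forward model

A homogeneous spherical conductor with the Sarvas closed form, sources
constrained to mesh vertices with moments along the outward surface
normals, gains in fT/nAm. Radial moments are exactly silent, which the
tests exploit as an identity. The model is analytic and exactly testable;
users with realistic head models can supply their own `gain_matrix` objects
to every downstream function, since nothing after the forward stage depends
on how the gains were produced.

### State HMM

The observation model is a full-covariance Gaussian per state on the
standardized PCA scores. This is a deliberate simplification: the
partitioning role of the HMM only requires segments that are self-similar
in second-order structure, and the downstream benchmark is agnostic to the
observation model. EM uses k-means-initialized restarts (5 by default),
relative log-likelihood tolerance 1e-4, and ridge-regularizes any
degenerate state covariance with a warning. Forward-backward and Viterbi
are implemented in C++ (log-space) and validated against brute-force path
enumeration. The model is fitted per subject, never group-concatenated, so
state indices are subject-specific.

Modal-state ties in an epoch go to the lower state index; so do ties in the
dominance ranking. Both rules are arbitrary but deterministic.

### Empirical-Bayes inversion

All four algorithms share one observation model for the reduced data
Y (C x n):

    Sigma_y = exp(l0) Q_eps + sum_k exp(lk) L C_k L',

with Q_eps diagonal sensor noise and C_k the source-covariance components
that define the algorithm:

* **MMN** - a single identity component (classical unweighted minimum norm);
* **LOR** - a single smooth component G G', G = exp(s A) the graph heat
  kernel on the row-normalized vertex adjacency (surface Green's-function
  smoothing, no depth weighting), s = 0.6 by default;
* **EBB** - a single diagonal component with beamformer variances
  1/(l_i' Cy^-1 l_i) estimated from the unregularized sensor covariance,
  normalized to unit trace;
* **MSP** - many rank-1 patch components g_k g_k' at quasi-uniform seed
  vertices (farthest-point sampling on the mesh graph), 512 at full scale.

Hyperparameters are optimized on the log scale by Fisher scoring with a
step-halving line search, so the objective is non-decreasing by
construction, under weak Gaussian hyperpriors N(-32, 256) per log weight
(components and data are trace-normalized internally, which makes the
hyperprior effectively scale-free). The reported free energy is the
Gaussian log evidence plus the hyperprior penalty and the Laplace
(posterior-precision) term; at fixed hyperparameters it reduces to the
closed-form log evidence, which the tests verify to 1e-6. For MSP the
optimization prunes components whose log weights collapse below -16 on the
normalized scale (ARD-style), a greedy variant of the full search; the
benchmark treats MSP generically rather than individually optimized.

Temporal reduction projects each 50-sample epoch onto the top R = 16
eigenvectors of the epoch-summed temporal covariance; the reduced data is
the concatenation over epochs (C x 16E), so the effective sample count for
ReML is 16E. Modes are recomputed per cross-validation fold from the
retained channels only, since whether they should be shared across folds
is not determined by the protocol; recomputing is the conservative choice
(no information flows from held-out channels into the fit).

### Cross-validation and group statistics

Each fold holds out floor(0.10 C) channels drawn independently per fold
(folds are independent draws, not a partition - with 272 channels this
gives the 245/27 split), the model is fitted on the rest, held-out data is
predicted as L_out J mapped back through the temporal modes, and scored as
100 (1 - ||y - yhat||^2 / ||y||^2). Scores are averaged over 10 folds and
the dominant state datasets; free energy comes from full-channel fits
(it needs no holdout). Both metrics are normalized by subtracting the
true-mesh value (dCV, dF), making the true mesh exactly zero.

Across subjects, each harmonic gets a two-sided one-sample t-test of dCV
against zero, and a random-effects Bayesian model comparison of dF
(Dirichlet posterior over model frequencies, Gibbs-sampled with seeded
draws; the exceedance probability that the distorted mesh is the more
frequent model). The HDH is the largest harmonic with p < 0.05 and
negative mean delta, uncorrected for multiplicity, matching the reporting
convention the benchmark mirrors; because an isolated significant harmonic
can make that rule liberal, the contiguous variant (every order up to h
significant) is reported alongside. The millimetre conversion applies the
per-subject 95th-percentile vertex distance at the group HDH and reports
the mean and SEM across subjects, with the mean-of-means also emitted.

## The synthetic generator: what it does and does not emulate

The generator reproduces the statistical structure the benchmark relies
on: a closed cortical surface with mesh-scale folds, sensors outside a
spherical conductor, source activity switching between spatially distinct
states on a 100-200 ms timescale, and calibrated broadband sensor noise
(power-based SNR pooled over channels and samples; the power convention is
an explicit choice, flagged in the configuration). Its folds are a random
band-limited spherical-harmonic field over degrees 2..12 with per-degree
RMS proportional to 1/l: a red spectrum keeps every reconstruction order
informative, which a single pure degree would not. It does not emulate
gradiometer pickup geometry, head movement, physiological artifacts,
realistic conductivity geometry, or 1/f spectral structure, and its
handful of point sources per state is far sparser than real cortical
activity. Passing benchmark properties on this generator therefore
demonstrates that the machinery ranks forward models correctly when its
generative assumptions hold - not that any particular millimetre figure
transfers to real recordings, where the forward model, source statistics
and noise are all richer.

## Numerical choices

* Resampling is Fourier-domain (exact unit passband gain, no FIR ripple);
  the recording is band-limited to 90 Hz before decimation to 250 Hz, so
  spectral truncation is clean. Output length is exactly
  round(T fs_out / fs_in).
* Percentiles use the linear-interpolation convention of R's default
  quantile type 7.
* The Green's kernel is a truncated Taylor series of exp(s A), terms added
  until below 1e-12; A row-normalized so the series converges fast.
* ReML stops when the free-energy gain falls below 1e-7 relative, or when
  no step-halving improves it; non-convergence at max_iter returns the
  best iterate with a warning.
* The fold-field RMS normalization makes `fold_amplitude` exactly the RMS
  radial fold depth in mm.
* Degenerate cases are explicit errors, not silent results: all-zero
  recordings for SNR calibration, zero held-out data in `cv_percent`,
  never-visited states in `state_sensor_map`, non-genus-0 meshes in the
  spherical parameterization.

## Desk-scale study conditions

The packaged study conditions (`tiny_config()`) are a 642-vertex cortex
(level-3 icosphere, ~7 mm vertex spacing), 64 channels, 60 s of 2-state
data at 600 Hz and +5 dB SNR, harmonic orders 1..8, a 4-state HMM on 16
PCA components with 2 restarts, the 2 dominant states, 16 temporal modes,
10 folds, and 8 synthetic subjects. These sizes keep a full group
benchmark in the minutes range on one core while exercising every stage;
`default_config()` pins the full-scale constants (33k-vertex-class meshes,
272 channels, 8 states, 40 components, 4 dominant states, 512 MSP patches,
orders 1..50) for users with the compute to match.

## Known limitations

* The spherical conductor makes absolute millimetre estimates
  model-specific; only within-benchmark comparisons are meaningful.
* At low harmonic orders the lead-field fidelity of the reconstructions is
  not guaranteed to be monotone in L even though geometric error is:
  truncated harmonic series can distort surface normals non-monotonically,
  and the smooth order-1 ovoid occasionally outperforms order 2-3. This is
  a property of the geometry, visible mainly at small L_max.
* The MSP implementation is the generic pruning variant; a full greedy
  search over patch subsets would likely improve its showing, as would an
  optimized minimum-norm variant for MMN.
* HMM state recovery degrades gracefully with SNR; at -20 dB the
  partitioning is essentially arbitrary, which is exactly the regime the
  noise-degradation control exercises.
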