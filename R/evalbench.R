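#' Random held-out channel folds
#'
#' Each fold is an independent random draw of `floor(holdout_frac * C)`
#' channels to hold out (folds are independent draws, not a partition), so
#' e.g. 272 channels at 10% give 27 held-out / 245 fitted channels per fold.
#'
#' @param labels channel names.
#' @param n_folds number of folds (default 10).
#' @param holdout_frac fraction of channels held out per fold (default 0.10).
#' @param seed RNG seed.
#' @return list of `n_folds` lists with integer `fit` and `holdout` indices.
#' @export
make_folds <- function(labels, n_folds = 10, holdout_frac = 0.10, seed = 1) {
  C <- length(labels)
  m <- floor(holdout_frac * C)
  if (m < 1) stop("holdout fraction leaves no held-out channel")
  if (m >= C) stop("holdout fraction leaves no fitted channel")
  withr::with_seed(seed, lapply(seq_len(n_folds), function(f) {
    hold <- sort(sample.int(C, m))
    list(fit = setdiff(seq_len(C), hold), holdout = hold)
  }))
}

#' Percent of held-out data explained
#'
#' `100 * (1 - ||y - yhat||_F^2 / ||y||_F^2)`; 100 for a perfect
#' prediction, 0 for predicting zero, negative when the prediction is worse
#' than predicting zero.
#'
#' @param y_true,y_pred matrices of identical shape.
#' @return scalar percentage.
#' @export
cv_percent <- function(y_true, y_pred) {
  stopifnot(all(dim(y_true) == dim(y_pred)))
  denom <- sum(y_true^2)
  if (denom == 0) stop("held-out data identically zero: CV percent undefined")
  100 * (1 - sum((y_true - y_pred)^2) / denom)
}

# mesh-dependent priors are built once per mesh; EBB depends on the data and
# is rebuilt per fold from the retained channels
build_prior <- function(kind, mesh, gain, reduced_data, msp_patches = 512,
                        smooth_s = 0.6, seed = 1) {
  switch(kind,
         MMN = prior_mmn(nrow(mesh$vertices)),
         LOR = prior_lor(mesh, smooth_s),
         EBB = prior_ebb(gain, reduced_data),
         MSP = prior_msp(mesh, msp_patches, smooth_s, seed),
         stop("unknown prior kind: ", kind))
}

#' Run the mesh-library benchmark for one subject
#'
#' For every mesh in the library (all harmonic orders plus the true mesh)
#' and every state dataset: fits the empirical-Bayes model on the retained
#' channels of each cross-validation fold, predicts the held-out channels
#' from the source estimates and scores the percent of data explained; a
#' full-channel fit per mesh and state records the free energy. CV scores
#' are averaged over folds and state datasets per mesh.
#'
#' @param datasets list of `state_dataset`s (the dominant states).
#' @param library a [build_library()] result.
#' @param gains named list of `gain_matrix` objects, one per library mesh
#'   plus `"true"`; e.g. from [library_gains()].
#' @param prior_kind one of "MMN", "LOR", "EBB", "MSP".
#' @param folds channel folds from [make_folds()].
#' @param R number of temporal modes (default 16).
#' @param msp_patches,smooth_s prior parameters.
#' @param seed seed for the MSP patch placement.
#' @return a `bench_scores` list: `table` (data.frame: mesh, harmonic, state,
#'   fold, cv), `per_mesh` (data.frame: mesh, harmonic, mean_cv, free_energy),
#'   `prior_kind`.
#' @export
run_bench <- function(datasets, library, gains, prior_kind, folds, R = 16,
                      msp_patches = 512, smooth_s = 0.6, seed = 1) {
  mesh_ids <- c(names(library$meshes), "true")
  meshes <- c(library$meshes, list(true = library$true_mesh))
  stopifnot(all(mesh_ids %in% names(gains)))
  rows <- list()
  per_mesh <- list()
  for (mi in mesh_ids) {
    mesh <- meshes[[mi]]
    gain <- gains[[mi]]
    mesh_prior <- if (prior_kind != "EBB")
      build_prior(prior_kind, mesh, gain, NULL, msp_patches, smooth_s, seed)
    F_states <- numeric(length(datasets))
    for (di in seq_along(datasets)) {
      d <- datasets[[di]]
      tr_full <- temporal_reduce(d, R)
      prior_full <- if (prior_kind == "EBB")
        prior_ebb(gain, tr_full$reduced) else mesh_prior
      fit_full <- reml_fit(gain, tr_full$reduced, prior_full)
      F_states[di] <- fit_full$F
      for (fi in seq_along(folds)) {
        fit_idx <- folds[[fi]]$fit
        hold_idx <- folds[[fi]]$holdout
        d_fit <- list(epochs = d$epochs[fit_idx, , , drop = FALSE])
        tr <- temporal_reduce(d_fit, R)
        g_fit <- subset_gain(gain, fit_idx)
        g_hold <- subset_gain(gain, hold_idx)
        prior <- if (prior_kind == "EBB")
          prior_ebb(g_fit, tr$reduced) else mesh_prior
        fit <- reml_fit(g_fit, tr$reduced, prior)
        J <- map_sources(fit, g_fit, tr$reduced, prior)
        pred <- predict_heldout(J, g_hold, tr$modes)
        truth <- flatten_epochs(d$epochs[hold_idx, , , drop = FALSE])
        rows[[length(rows) + 1]] <- data.frame(
          mesh = mi,
          harmonic = suppressWarnings(as.integer(mi)),
          state = d$state_id, fold = fi,
          cv = cv_percent(truth, pred))
      }
    }
    tab_mi <- do.call(rbind, rows[vapply(rows, function(r) r$mesh[1] == mi,
                                         logical(1))])
    per_mesh[[length(per_mesh) + 1]] <- data.frame(
      mesh = mi, harmonic = suppressWarnings(as.integer(mi)),
      mean_cv = mean(tab_mi$cv), free_energy = mean(F_states))
  }
  structure(list(table = do.call(rbind, rows),
                 per_mesh = do.call(rbind, per_mesh),
                 prior_kind = prior_kind),
            class = "bench_scores")
}

subset_gain <- function(gain, idx) {
  structure(list(values = gain$values[idx, , drop = FALSE],
                 channel_labels = gain$channel_labels[idx],
                 mesh_id = gain$mesh_id),
            class = "gain_matrix")
}

flatten_epochs <- function(ep) {
  matrix(ep, nrow = dim(ep)[1])
}

#' Gain matrices for every mesh in a library
#'
#' @param library a `mesh_library`.
#' @param sensors a `sensor_array`.
#' @return named list of `gain_matrix` objects (orders plus `"true"`).
#' @export
library_gains <- function(library, sensors) {
  g <- lapply(names(library$meshes), function(mi)
    gain_matrix(library$meshes[[mi]], sensors, mesh_id = mi))
  names(g) <- names(library$meshes)
  g$true <- gain_matrix(library$true_mesh, sensors, mesh_id = "true")
  g
}

#' Normalize scores against the true mesh
#'
#' `Delta(harmonic) = score(harmonic) - score(true mesh)`, so the true mesh
#' is exactly 0 and distorted meshes are negative when they fit worse.
#'
#' @param per_mesh the `per_mesh` data.frame of a [run_bench()] result.
#' @return data.frame with `harmonic`, `dcv`, `df` for the harmonic meshes.
#' @export
delta_metrics <- function(per_mesh) {
  truth <- per_mesh[per_mesh$mesh == "true", ]
  lib <- per_mesh[per_mesh$mesh != "true", ]
  data.frame(harmonic = lib$harmonic,
             dcv = lib$mean_cv - truth$mean_cv,
             df = lib$free_energy - truth$free_energy)
}

#' One-sample t-test of per-subject deltas against zero
#'
#' Two-sided, df = n - 1. A zero-variance sample returns p = 1 when the
#' mean is 0 and p = 0 otherwise (the degenerate limit).
#'
#' @param deltas per-subject values at one harmonic.
#' @return list with `t`, `p`, `df`, `mean`.
#' @export
group_ttest <- function(deltas) {
  n <- length(deltas)
  stopifnot(n >= 2)
  if (sd(deltas) == 0) {
    return(list(t = if (mean(deltas) == 0) 0 else sign(mean(deltas)) * Inf,
                p = if (mean(deltas) == 0) 1 else 0,
                df = n - 1, mean = mean(deltas)))
  }
  tt <- t.test(deltas, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, df = n - 1,
       mean = mean(deltas))
}

#' Random-effects Bayesian model comparison exceedance probability
#'
#' Compares {distorted mesh, true mesh} across subjects from per-subject
#' log-evidence differences (dF = F_distorted - F_true) using the
#' random-effects scheme: a Dirichlet prior over model frequencies, Gibbs
#' sampling alternating subject-level model assignments and the Dirichlet
#' posterior, and the exceedance probability that the distorted model is
#' the more frequent one.
#'
#' @param df_subjects per-subject dF values (nats).
#' @param n_draws Gibbs draws (default 1e5).
#' @param burn_in discarded initial draws.
#' @param alpha0 Dirichlet prior count (default 1 per model).
#' @param seed RNG seed.
#' @return list with `exceedance` (P(freq_distorted > freq_true)),
#'   `expected_freq`.
#' @export
bmc_exceedance <- function(df_subjects, n_draws = 1e5, burn_in = 1000,
                           alpha0 = 1, seed = 1) {
  stopifnot(all(is.finite(df_subjects)))
  nS <- length(df_subjects)
  # subject-level log evidence for (distorted, true); only differences matter
  lev <- cbind(df_subjects, 0)
  withr::with_seed(seed, {
    r <- c(0.5, 0.5)
    exceed <- 0L
    rsum <- c(0, 0)
    kept <- 0L
    for (it in seq_len(n_draws + burn_in)) {
      lp <- sweep(lev, 2, log(r), "+")
      lp <- lp - apply(lp, 1, max)
      p1 <- exp(lp[, 1]) / (exp(lp[, 1]) + exp(lp[, 2]))
      z1 <- runif(nS) < p1
      cnt <- c(sum(z1), nS - sum(z1))
      g <- rgamma(2, shape = alpha0 + cnt)
      r <- g / sum(g)
      if (it > burn_in) {
        kept <- kept + 1L
        rsum <- rsum + r
        if (r[1] > r[2]) exceed <- exceed + 1L
      }
    }
    list(exceedance = exceed / kept, expected_freq = rsum / kept)
  })
}

#' Highest distinguishable harmonic
#'
#' The largest harmonic order whose mesh is still statistically worse than
#' the true mesh: p < alpha and mean delta < 0. No multiplicity correction
#' is applied (flagged in the output). Also reports the contiguous variant
#' (largest h such that every order <= h qualifies).
#'
#' @param harmonics harmonic orders (ascending).
#' @param p_values per-harmonic p-values.
#' @param mean_deltas per-harmonic group-mean deltas.
#' @param alpha significance level (default 0.05).
#' @return list with `hdh` (largest qualifying order or NA), `hdh_contiguous`,
#'   `alpha`, `multiplicity_corrected = FALSE`.
#' @export
find_hdh <- function(harmonics, p_values, mean_deltas, alpha = 0.05) {
  stopifnot(length(harmonics) == length(p_values),
            length(harmonics) == length(mean_deltas),
            !is.unsorted(harmonics))
  qual <- p_values < alpha & mean_deltas < 0
  hdh <- if (any(qual)) max(harmonics[qual]) else NA_integer_
  contig <- NA_integer_
  if (any(qual)) {
    run <- cumprod(qual) == 1
    if (any(run)) contig <- max(harmonics[run])
  }
  list(hdh = hdh, hdh_contiguous = contig, alpha = alpha,
       multiplicity_corrected = FALSE)
}

#' Convert a group HDH to a millimetre resolution estimate
#'
#' Per subject, the distance distribution between corresponding vertices of
#' the subject's mesh at the group HDH and the true mesh is summarized by
#' its upper 95th percentile (and, for comparison, its mean); the group
#' mean and SEM across subjects are reported.
#'
#' @param libraries list of per-subject `mesh_library` objects.
#' @param hdh the group-level highest distinguishable harmonic (NA gives an
#'   explicit NULL estimate).
#' @param q percentile (default 95).
#' @return list with `per_subject_q` (mm), `per_subject_mean`, `mm_mean`,
#'   `mm_sem`, `mm_mean_of_means`, `q`, `hdh`; or NULL-valued fields when
#'   `hdh` is NA.
#' @export
hdh_to_mm <- function(libraries, hdh, q = 95) {
  if (is.na(hdh)) {
    return(list(per_subject_q = NULL, per_subject_mean = NULL,
                mm_mean = NA_real_, mm_sem = NA_real_,
                mm_mean_of_means = NA_real_, q = q, hdh = NA_integer_))
  }
  pq <- vapply(libraries, function(lib) {
    stopifnot(hdh %in% lib$harmonic_orders)
    distance_percentile(vertex_distances(lib$meshes[[as.character(hdh)]],
                                         lib$true_mesh), q)
  }, numeric(1))
  pm <- vapply(libraries, function(lib)
    mean(vertex_distances(lib$meshes[[as.character(hdh)]], lib$true_mesh)),
    numeric(1))
  list(per_subject_q = pq, per_subject_mean = pm,
       mm_mean = mean(pq), mm_sem = sd(pq) / sqrt(length(pq)),
       mm_mean_of_means = mean(pm), q = q, hdh = hdh)
}
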