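#' Benchmark run configuration
#'
#' `default_config()` pins the full-scale analysis parameters: an 8-state
#' HMM on 40 PCA components, 200 ms epochs, the 4 most dominant states, 16
#' temporal modes, 512 MSP patches, 10 cross-validation folds holding out
#' 10% of channels, WFS bandwidth sigma 1e-4 and harmonic orders up to 50.
#' `tiny_config()` is the desk-scale preset used throughout the package's
#' examples and tests: a 642-vertex cortex with 64 channels, 60 s of 2-state
#' data at +5 dB SNR, harmonic orders up to 8, a 4-state HMM on 16
#' components and the 2 dominant states.
#'
#' @param ... named overrides merged into the preset (nested lists are
#'   merged per field).
#' @return a `run_config` list with elements `mesh`, `sensors`, `sim`,
#'   `wfs`, `hmm`, `inversion`, `cv`, `stats`, `seed`.
#' @export
default_config <- function(...) {
  cfg <- list(
    mesh = list(n_vertices = 2562, fold_amplitude = 5, fold_frequency = 12,
                radius = 70),
    sensors = list(n_channels = 272, cap_radius = 110, conductor_radius = 95),
    sim = list(n_states = 4, state_dwell_ms = 200, sources_per_state = 3,
               source_amplitude = 20, snr_db = 5, duration_s = 600, fs = 600),
    wfs = list(L_max = 50, sigma = 1e-4),
    hmm = list(K = 8, n_pca = 40, epoch_ms = 200, n_dominant = 4,
               n_restarts = 5, target_fs = 250),
    inversion = list(priors = c("EBB", "MMN", "LOR", "MSP"), R = 16,
                     msp_patches = 512, smooth_s = 0.6),
    cv = list(n_folds = 10, holdout_frac = 0.10),
    stats = list(alpha = 0.05, bmc_draws = 1e5),
    seed = 1L)
  merge_config(cfg, list(...))
}

#' @rdname default_config
#' @export
tiny_config <- function(...) {
  cfg <- default_config()
  cfg$mesh$n_vertices <- 642
  cfg$sensors$n_channels <- 64
  cfg$sim$n_states <- 2
  cfg$sim$duration_s <- 60
  cfg$wfs$L_max <- 8
  cfg$hmm$K <- 4
  cfg$hmm$n_pca <- 16
  cfg$hmm$n_dominant <- 2
  cfg$hmm$n_restarts <- 2
  cfg$inversion$msp_patches <- 64
  cfg$stats$bmc_draws <- 2e4
  merge_config(cfg, list(...))
}

merge_config <- function(cfg, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the chosen preset.
#'
#' @param path YAML file.
#' @param base preset to merge into: "tiny" or "default".
#' @return a `run_config`.
#' @export
read_config <- function(path, base = c("tiny", "default")) {
  base <- match.arg(base)
  over <- yaml::read_yaml(path)
  cfg <- if (base == "tiny") tiny_config() else default_config()
  merge_config(cfg, over)
}

# deterministic sub-seed streams, one per named stage
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + 7919 * k) %% 2147483647)
}

#' Generate one synthetic subject: anatomy, sensors, gains, mesh library
#'
#' @param config a `run_config`.
#' @param seed subject seed (one synthetic subject per seed).
#' @return list with `mesh`, `sensors`, `gain_true`, `library`, `gains`.
#' @export
subject_setup <- function(config, seed) {
  mesh <- gen_mesh(config$mesh$n_vertices, config$mesh$fold_amplitude,
                   config$mesh$fold_frequency, config$mesh$radius,
                   seed = derive_seed(seed, 1))
  sensors <- gen_sensor_array(config$sensors$n_channels,
                              config$sensors$cap_radius,
                              config$sensors$conductor_radius,
                              seed = derive_seed(seed, 2))
  library <- build_library(mesh, config$wfs$L_max, config$wfs$sigma,
                           subject_id = sprintf("synth%d", seed))
  gains <- library_gains(library, sensors)
  list(mesh = mesh, sensors = sensors, gain_true = gains$true,
       library = library, gains = gains)
}

#' Simulate a subject's recording (noiseless unless the config sets SNR)
#'
#' @param setup a [subject_setup()] result.
#' @param config a `run_config`.
#' @param seed subject seed.
#' @param snr_db overrides `config$sim$snr_db` (use NULL for noiseless).
#' @return a [sensor_recording()].
#' @export
subject_recording <- function(setup, config, seed,
                              snr_db = config$sim$snr_db) {
  cfg <- sim_config(n_states = config$sim$n_states,
                    state_dwell_ms = config$sim$state_dwell_ms,
                    sources_per_state = config$sim$sources_per_state,
                    source_amplitude = config$sim$source_amplitude,
                    snr_db = NULL, duration_s = config$sim$duration_s,
                    fs = config$sim$fs, seed = derive_seed(seed, 3))
  rec <- simulate_recording(setup$mesh, setup$sensors, cfg, setup$gain_true)
  if (!is.null(snr_db)) rec <- add_noise_db(rec, snr_db, derive_seed(seed, 4))
  rec
}

#' Partition a recording into its dominant state datasets
#'
#' Preprocess (filter + downsample), PCA-reduce, fit the HMM, epoch by
#' modal state and keep the dominant states.
#'
#' @param rec a [sensor_recording()].
#' @param config a `run_config`.
#' @param seed subject seed.
#' @return list of `state_dataset`s.
#' @export
subject_datasets <- function(rec, config, seed) {
  rec <- preprocess_recording(rec, target_fs = config$hmm$target_fs)
  pca <- pca_reduce(rec, config$hmm$n_pca)
  hm <- fit_hmm(pca$scores, config$hmm$K, fs = rec$fs,
                seed = derive_seed(seed, 5),
                n_restarts = config$hmm$n_restarts)
  tagged <- epoch_modal(rec, hm$statepath, config$hmm$epoch_ms)
  ds <- partition_states(tagged, config$hmm$K)
  dominant_states(ds, config$hmm$n_dominant)
}

#' Benchmark one subject under one prior
#'
#' @param datasets dominant `state_dataset`s.
#' @param setup a [subject_setup()] result.
#' @param config a `run_config`.
#' @param prior_kind one of "EBB", "MMN", "LOR", "MSP".
#' @param seed subject seed (drives fold draws and MSP patch placement).
#' @return the [run_bench()] result with `$delta` appended.
#' @export
subject_bench <- function(datasets, setup, config, prior_kind, seed) {
  folds <- make_folds(setup$sensors$labels, config$cv$n_folds,
                      config$cv$holdout_frac, seed = derive_seed(seed, 6))
  bs <- run_bench(datasets, setup$library, setup$gains, prior_kind, folds,
                  R = config$inversion$R,
                  msp_patches = config$inversion$msp_patches,
                  smooth_s = config$inversion$smooth_s,
                  seed = derive_seed(seed, 7))
  bs$delta <- delta_metrics(bs$per_mesh)
  bs
}

#' Group-level benchmark statistics
#'
#' Per-harmonic one-sample t-tests of the subjects' dCV against zero,
#' random-effects Bayesian model comparison of the subjects' dF, and the
#' highest distinguishable harmonic for each metric with its millimetre
#' conversion.
#'
#' @param benches list (one per subject) of [subject_bench()] results.
#' @param libraries list of the subjects' `mesh_library` objects.
#' @param config a `run_config`.
#' @return list with `per_harmonic` (data.frame: harmonic, mean_dcv,
#'   mean_df, t, p, exceedance), `hdh_cv`, `hdh_f`, `mm_cv`, `mm_f`,
#'   `spearman_dcv`, `spearman_df`.
#' @export
group_stats <- function(benches, libraries, config) {
  harmonics <- sort(benches[[1]]$delta$harmonic)
  dcv <- sapply(benches, function(b) b$delta$dcv[order(b$delta$harmonic)])
  df <- sapply(benches, function(b) b$delta$df[order(b$delta$harmonic)])
  tt <- apply(dcv, 1, group_ttest)
  exc <- vapply(seq_along(harmonics), function(i)
    bmc_exceedance(df[i, ], n_draws = config$stats$bmc_draws,
                   seed = derive_seed(config$seed, 100 + i))$exceedance,
    numeric(1))
  per_h <- data.frame(
    harmonic = harmonics,
    mean_dcv = rowMeans(dcv), mean_df = rowMeans(df),
    t = vapply(tt, `[[`, numeric(1), "t"),
    p = vapply(tt, `[[`, numeric(1), "p"),
    exceedance = exc)
  hdh_cv <- find_hdh(harmonics, per_h$p, per_h$mean_dcv, config$stats$alpha)
  hdh_f <- find_hdh(harmonics, per_h$exceedance, per_h$mean_df,
                    config$stats$alpha)
  list(per_harmonic = per_h,
       hdh_cv = hdh_cv, hdh_f = hdh_f,
       mm_cv = hdh_to_mm(libraries, hdh_cv$hdh),
       mm_f = hdh_to_mm(libraries, hdh_f$hdh),
       spearman_dcv = suppressWarnings(
         cor(per_h$harmonic, per_h$mean_dcv, method = "spearman")),
       spearman_df = suppressWarnings(
         cor(per_h$harmonic, per_h$mean_df, method = "spearman")))
}

#' Run the full benchmark pipeline
#'
#' Simulation (or degradation controls) -> preprocessing -> HMM state
#' partitioning -> WFS mesh library -> forward models -> empirical-Bayes
#' inversion -> cross-validation / free-energy benchmark -> group
#' statistics, for a group of synthetic subjects (one per seed). Artifacts
#' (tidy per-fold TSV, JSON summary, config manifest) are written when
#' `out_dir` is given; re-running with the same config and seeds reproduces
#' them exactly.
#'
#' @param config a `run_config`.
#' @param seeds subject seeds (default `config$seed + 0:7`).
#' @param prior_kinds prior kinds to run (default from config).
#' @param shuffle apply the sensor-label shuffling control.
#' @param snr_db SNR override applied to every subject (NULL = noiseless;
#'   missing = config value).
#' @param out_dir optional artifact directory.
#' @return a `bench_result`: per-prior list of `group` ([group_stats()]),
#'   `per_subject` tables, plus `config`, `seeds`.
#' @export
run_pipeline <- function(config = tiny_config(), seeds = config$seed + 0:7,
                         prior_kinds = config$inversion$priors,
                         shuffle = FALSE, snr_db = config$sim$snr_db,
                         out_dir = NULL) {
  subjects <- lapply(seeds, function(s) {
    setup <- subject_setup(config, s)
    rec <- subject_recording(setup, config, s, snr_db = snr_db)
    if (shuffle) rec <- shuffle_channels(rec, seed = derive_seed(s, 8))
    datasets <- subject_datasets(rec, config, s)
    list(setup = setup, datasets = datasets, seed = s)
  })
  out <- list(config = config, seeds = seeds, priors = list())
  for (kind in prior_kinds) {
    benches <- lapply(subjects, function(su)
      subject_bench(su$datasets, su$setup, config, kind, su$seed))
    libs <- lapply(subjects, function(su) su$setup$library)
    out$priors[[kind]] <- list(
      group = group_stats(benches, libs, config),
      benches = benches,
      true_cv = vapply(benches, function(b)
        b$per_mesh$mean_cv[b$per_mesh$mesh == "true"], numeric(1)))
  }
  class(out) <- "bench_result"
  if (!is.null(out_dir)) write_bench_result(out, out_dir)
  out
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("bench_result: %d subjects, priors %s\n", length(x$seeds),
              paste(names(x$priors), collapse = ", ")))
  for (kind in names(x$priors)) {
    g <- x$priors[[kind]]$group
    cat(sprintf("  %s: HDH(CV) = %s, HDH(F) = %s, mm(95%%) = %s, rho(dCV) = %.2f\n",
                kind, format(g$hdh_cv$hdh), format(g$hdh_f$hdh),
                if (is.na(g$mm_cv$mm_mean)) "NA"
                else sprintf("%.2f +- %.2f", g$mm_cv$mm_mean, g$mm_cv$mm_sem),
                g$spearman_dcv))
  }
  invisible(x)
}

write_bench_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (kind in names(res$priors)) {
    pb <- res$priors[[kind]]
    for (i in seq_along(pb$benches)) {
      tab <- pb$benches[[i]]$table
      tab$subject <- res$seeds[i]
      tab$prior <- kind
      rows[[length(rows) + 1]] <- tab
    }
  }
  tidy <- do.call(rbind, rows)
  tidy <- tidy[, c("subject", "prior", "mesh", "harmonic", "state", "fold", "cv")]
  write.table(tidy, file.path(out_dir, "fold_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- lapply(res$priors, function(pb) {
    g <- pb$group
    list(hdh_cv = g$hdh_cv$hdh, hdh_f = g$hdh_f$hdh,
         mm_mean = g$mm_cv$mm_mean, mm_sem = g$mm_cv$mm_sem,
         spearman_dcv = g$spearman_dcv, spearman_df = g$spearman_df,
         per_harmonic = g$per_harmonic, true_cv = pb$true_cv)
  })
  jsonlite::write_json(list(seeds = res$seeds, priors = summ),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(res$config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare inversion priors on the same subjects
#'
#' Per-kind absolute true-mesh cross-validation percent, paired t-tests
#' between kinds across subjects (on the true-mesh CV), and per-kind HDH
#' and millimetre estimate.
#'
#' @param result a [run_pipeline()] result covering >= 2 priors.
#' @return list with `summary` (one row per kind: true_cv_mean, true_cv_sem,
#'   hdh, mm) and `paired` (one row per kind pair: t, p, df).
#' @export
compare_priors <- function(result) {
  kinds <- names(result$priors)
  stopifnot(length(kinds) >= 2)
  tc <- sapply(kinds, function(k) result$priors[[k]]$true_cv)
  summary <- data.frame(
    prior = kinds,
    true_cv_mean = colMeans(tc),
    true_cv_sem = apply(tc, 2, sd) / sqrt(nrow(tc)),
    hdh = vapply(kinds, function(k)
      as.integer(result$priors[[k]]$group$hdh_cv$hdh), integer(1)),
    mm = vapply(kinds, function(k)
      result$priors[[k]]$group$mm_cv$mm_mean, numeric(1)))
  pairs <- utils::combn(kinds, 2)
  paired <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- tc[, a] - tc[, b]
    if (sd(d) == 0) {
      data.frame(a = a, b = b, t = 0, p = 1, df = length(d) - 1)
    } else {
      tt <- t.test(tc[, a], tc[, b], paired = TRUE)
      data.frame(a = a, b = b, t = unname(tt$statistic), p = tt$p.value,
                 df = length(d) - 1)
    }
  }))
  list(summary = summary, paired = paired)
}
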