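#' Band-pass, notch and downsample a recording
#'
#' Zero-phase 4th-order Butterworth band-pass (1-90 Hz) and band-stop
#' (48-52 Hz, line noise) filtering followed by polyphase resampling to
#' `target_fs` (250 Hz by default). The output length is exactly
#' `round(T * target_fs / fs)`. Any ground-truth statepath is carried along
#' by nearest-sample index mapping.
#'
#' @param rec a [sensor_recording()].
#' @param target_fs output sampling rate, Hz.
#' @param band band-pass edges, Hz.
#' @param notch band-stop edges, Hz.
#' @return the filtered, resampled [sensor_recording()].
#' @export
preprocess_recording <- function(rec, target_fs = 250, band = c(1, 90),
                                 notch = c(48, 52)) {
  fs <- rec$fs
  if (fs < target_fs) stop("sampling rate below resampling target")
  if (fs <= 2 * band[2]) stop("sampling rate too low for band edges")
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  bs <- signal::butter(4, notch / (fs / 2), type = "stop")
  nt_out <- round(ncol(rec$data) * target_fs / fs)
  out <- matrix(0, nrow(rec$data), nt_out)
  for (ci in seq_len(nrow(rec$data))) {
    x <- signal::filtfilt(bp, rec$data[ci, ])
    x <- signal::filtfilt(bs, x)
    out[ci, ] <- resample_fft(x, nt_out)
  }
  truth <- NULL
  if (!is.null(rec$state_truth)) {
    idx <- pmin(ncol(rec$data), floor((seq_len(nt_out) - 1) * fs / target_fs) + 1)
    truth <- rec$state_truth[idx]
  }
  sensor_recording(out, target_fs, rec$labels, truth)
}

# Fourier-domain resampling to an arbitrary target length: retains the
# frequencies representable at the new rate (unit passband gain) and is
# exact for signals already band-limited below the new Nyquist, as here
# after the 1-90 Hz band-pass.
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  kpos <- ceiling(min(n, n_out) / 2) - 1   # bins strictly below both Nyquists
  Y[1] <- X[1]
  if (kpos >= 1) {
    Y[2:(kpos + 1)] <- X[2:(kpos + 1)]
    Y[n_out - (1:kpos) + 1] <- X[n - (1:kpos) + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Principal-component reduction to standardized component time series
#'
#' Projects the channel data onto its top principal components and
#' standardizes each component score series to zero mean and unit variance.
#' Components with zero variance (beyond the data rank) are dropped with a
#' warning.
#'
#' @param rec a [sensor_recording()].
#' @param n_comp number of components requested (<= channel count).
#' @return list with `scores` (n_comp x T, standardized), `rotation`
#'   (C x n_comp), `sdev` (all singular values / sqrt(T-1)).
#' @export
pca_reduce <- function(rec, n_comp = 40) {
  X <- rec$data
  if (n_comp > nrow(X)) stop("n_comp exceeds channel count")
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / (ncol(X) - 1), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  usable <- sum(ev > max(ev) * 1e-12)
  if (n_comp > usable) {
    warning(sprintf("data rank %d < n_comp; keeping %d components", usable, usable))
    n_comp <- usable
  }
  rot <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  sc <- crossprod(rot, Xc)
  sc <- (sc - rowMeans(sc)) / apply(sc, 1, sd)
  list(scores = sc, rotation = rot, sdev = sqrt(ev))
}

# per-sample log density under each state's full-covariance Gaussian
gauss_logdens <- function(X, means, covs) {
  T <- ncol(X); K <- length(covs); D <- nrow(X)
  ld <- matrix(0, T, K)
  for (k in seq_len(K)) {
    ch <- chol(covs[[k]])
    z <- backsolve(ch, X - means[, k], transpose = TRUE)
    ld[, k] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * D * log(2 * pi)
  }
  ld
}

#' Fit a Gaussian-observation hidden Markov model and decode the statepath
#'
#' Full-covariance Gaussian HMM fit by expectation-maximization with
#' multiple seeded restarts (k-means initialized means); the restart with
#' the best log-likelihood is kept and its Viterbi decoding returned as the
#' statepath. EM stops when the relative log-likelihood improvement falls
#' below `tol`. Degenerate state covariances are ridge-regularized with a
#' warning.
#'
#' @param scores D x T component time series (e.g. from [pca_reduce()]).
#' @param K number of states.
#' @param fs sampling rate of the score series, Hz (carried in the path).
#' @param seed master RNG seed; restart seeds are derived from it.
#' @param n_restarts EM restarts (default 5).
#' @param tol relative log-likelihood tolerance (default 1e-4).
#' @param max_iter EM iteration cap per restart.
#' @return an `hmm_fit`: list with `statepath` (list: `states`, `K`, `fs`),
#'   `means`, `covs`, `transition`, `initial`, `loglik`, `loglik_trace`.
#' @export
fit_hmm <- function(scores, K, fs = 250, seed = 1, n_restarts = 5,
                    tol = 1e-4, max_iter = 100) {
  X <- as.matrix(scores)
  D <- nrow(X); T <- ncol(X)
  stopifnot(K >= 1, T > 10 * K)
  if (K == 1) {
    path <- list(states = rep(1L, T), K = 1L, fs = fs)
    return(structure(list(statepath = path, means = matrix(rowMeans(X)),
                          covs = list(cov(t(X))), transition = matrix(1, 1, 1),
                          initial = 1, loglik = NA_real_, loglik_trace = NA_real_),
                     class = "hmm_fit"))
  }
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    fit <- withr::with_seed(seed + 7919L * rs, {
      em_hmm(X, K, tol, max_iter)
    })
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ld <- gauss_logdens(X, best$means, best$covs)
  states <- hmm_viterbi(ld, log(best$initial), log(best$transition))
  best$statepath <- list(states = as.integer(states), K = as.integer(K), fs = fs)
  structure(best, class = "hmm_fit")
}

em_hmm <- function(X, K, tol, max_iter) {
  D <- nrow(X); T <- ncol(X)
  km <- suppressWarnings(kmeans(t(X), centers = K, nstart = 1, iter.max = 20))
  means <- t(km$centers)
  gcov <- cov(t(X))
  covs <- replicate(K, gcov, simplify = FALSE)
  A <- matrix(0.1 / (K - 1), K, K); diag(A) <- 0.9
  pi0 <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- gauss_logdens(X, means, covs)
    fb <- hmm_forward_backward(ld, log(pi0), log(A))
    ll_trace <- c(ll_trace, fb$loglik)
    g <- fb$gamma                       # T x K
    nk <- colSums(g)
    means <- (X %*% g) / rep(nk, each = D)
    for (k in seq_len(K)) {
      Xc <- X - means[, k]
      Ck <- (Xc * rep(g[, k], each = D)) %*% t(Xc) / nk[k]
      ev_ok <- tryCatch({ chol(Ck); TRUE }, error = function(e) FALSE)
      if (!ev_ok) {
        warning("degenerate state covariance; ridge regularized")
        Ck <- Ck + diag(1e-6 * mean(diag(Ck)) + 1e-12, D)
      }
      covs[[k]] <- Ck
    }
    A <- fb$xi / pmax(rowSums(fb$xi), .Machine$double.eps)
    A <- pmax(A, 1e-12); A <- A / rowSums(A)
    pi0 <- pmax(g[1, ], 1e-12); pi0 <- pi0 / sum(pi0)
    if (is.finite(ll_prev) &&
        (fb$loglik - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- fb$loglik
  }
  list(means = means, covs = covs, transition = A, initial = pi0,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace)
}

#' Log-likelihood of data under a fitted HMM
#'
#' Computed by the forward recursion; used e.g. to compare against
#' brute-force path enumeration on tiny problems.
#'
#' @param fit an `hmm_fit` (or list with `means`, `covs`, `transition`,
#'   `initial`).
#' @param scores D x T observation matrix.
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(fit, scores) {
  ld <- gauss_logdens(as.matrix(scores), fit$means, fit$covs)
  hmm_forward_backward(ld, log(fit$initial), log(fit$transition))$loglik
}

#' Epoch a recording and tag each epoch with its modal state
#'
#' Cuts the recording into non-overlapping consecutive epochs of
#' `round(epoch_ms * fs / 1000)` samples (the trailing partial epoch is
#' discarded) and tags each with the statistical mode of the statepath over
#' that window. Ties go to the lower state index.
#'
#' @param rec a [sensor_recording()].
#' @param path a statepath list (`states`, `K`, `fs`) aligned with `rec`.
#' @param epoch_ms epoch length in ms (default 200).
#' @return list with `epochs` (C x S x E array), `tags` (length E),
#'   `fs`, `labels`.
#' @export
epoch_modal <- function(rec, path, epoch_ms = 200) {
  stopifnot(length(path$states) == ncol(rec$data))
  S <- round(epoch_ms * rec$fs / 1000)
  if (S > ncol(rec$data)) stop("epoch longer than recording")
  E <- floor(ncol(rec$data) / S)
  epochs <- array(rec$data[, seq_len(E * S), drop = FALSE],
                  dim = c(nrow(rec$data), S, E))
  tags <- vapply(seq_len(E), function(e) {
    seg <- path$states[((e - 1) * S + 1):(e * S)]
    cnt <- tabulate(seg, nbins = path$K)
    which.max(cnt)           # ties: first (lowest) index
  }, integer(1))
  list(epochs = epochs, tags = tags, fs = rec$fs, labels = rec$labels)
}

#' Partition tagged epochs into per-state datasets
#'
#' @param tagged result of [epoch_modal()].
#' @param K number of states.
#' @return list of K `state_dataset`s (each: `epochs` C x S x E_k,
#'   `state_id`, `fs`, `labels`); empty states yield zero-epoch datasets.
#' @export
partition_states <- function(tagged, K) {
  lapply(seq_len(K), function(k) {
    idx <- which(tagged$tags == k)
    structure(list(
      epochs = tagged$epochs[, , idx, drop = FALSE],
      state_id = k, fs = tagged$fs, labels = tagged$labels
    ), class = "state_dataset")
  })
}

#' Select the dominant states by occupancy
#'
#' Returns the `n` state datasets with the most epochs (most time spent in
#' that state); ties go to the lower state index. If fewer than `n` states
#' are nonempty, all nonempty ones are returned with a warning.
#'
#' @param datasets list of `state_dataset`s from [partition_states()].
#' @param n number of datasets to keep (default 4).
#' @return list of the selected `state_dataset`s, largest first.
#' @export
dominant_states <- function(datasets, n = 4) {
  stopifnot(n <= length(datasets))
  counts <- vapply(datasets, function(d) dim(d$epochs)[3], numeric(1))
  ord <- order(-counts, seq_along(counts))
  sel <- ord[seq_len(n)]
  nonempty <- counts[sel] > 0
  if (!all(nonempty)) {
    warning("fewer nonempty state datasets than requested; returning all nonempty")
    sel <- sel[nonempty]
  }
  datasets[sel]
}

#' Sensor-space correlation map of a state
#'
#' Pearson correlation, per channel, between the binary indicator of state k
#' in the statepath and the channel's amplitude envelope (modulus of the
#' analytic signal).
#'
#' @param rec a [sensor_recording()].
#' @param path aligned statepath.
#' @param k state index.
#' @return numeric vector of per-channel correlations.
#' @export
state_sensor_map <- function(rec, path, k) {
  ind <- as.numeric(path$states == k)
  if (all(ind == 0)) stop("state never visited: map undefined")
  if (sd(ind) == 0) stop("indicator constant: correlation undefined")
  env <- t(apply(rec$data, 1, amplitude_envelope))
  drop(cor(t(env), ind))
}

# analytic-signal amplitude envelope via FFT Hilbert transform
amplitude_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}
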