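test_that("preprocessing attenuates the stop band, passes the pass band, and resamples exactly", {
  fs <- 1200
  t <- (0:(fs * 20 - 1)) / fs
  mid <- 1001:4000                            # steady-state portion at 250 Hz
  rec50 <- sensor_recording(rbind(sin(2 * pi * 50 * t)), fs, "c1")
  out50 <- preprocess_recording(rec50)
  expect_lt(sd(out50$data[, mid]) / sd(rec50$data), 0.05)
  rec10 <- sensor_recording(rbind(sin(2 * pi * 10 * t)), fs, "c1")
  out10 <- preprocess_recording(rec10)
  expect_lt(abs(sd(out10$data[, mid]) / sd(rec10$data) - 1), 0.05)
  expect_identical(ncol(out10$data), 5000L)   # 20 s at 250 Hz
  expect_error(preprocess_recording(sensor_recording(rbind(rnorm(100)), 150, "a")),
               "below resampling target")
})

test_that("a 600 s recording at 1200 Hz yields exactly 150000 samples at 250 Hz", {
  rec <- sensor_recording(rbind(rnorm(720000)), 1200, "c1")
  out <- preprocess_recording(rec)
  expect_identical(ncol(out$data), 150000L)
  expect_identical(out$fs, 250)
})

test_that("PCA components are standardized and match an eigendecomposition oracle", {
  set.seed(8)
  X <- matrix(rnorm(10 * 1000), 10) * (1:10)
  rec <- sensor_recording(X, 250, paste0("c", 1:10))
  pc <- pca_reduce(rec, 4)
  expect_equal(rowMeans(pc$scores), rep(0, 4), tolerance = 1e-8)
  expect_equal(apply(pc$scores, 1, var), rep(1, 4), tolerance = 1e-8)
  # oracle: scores proportional to eigenvector projections of the covariance
  Xc <- X - rowMeans(X)
  eg <- eigen(Xc %*% t(Xc) / (ncol(X) - 1), symmetric = TRUE)
  for (k in 1:4) {
    o <- drop(crossprod(eg$vectors[, k], Xc))
    o <- (o - mean(o)) / sd(o)
    expect_gt(abs(cor(pc$scores[k, ], o)), 1 - 1e-10)
  }
  # rank-1 data leaves a single usable component
  r1 <- sensor_recording(outer(1:5, rnorm(500)), 250, paste0("c", 1:5))
  expect_warning(pc1 <- pca_reduce(r1, 3), "rank")
  expect_identical(nrow(pc1$scores), 1L)
})

test_that("HMM log-likelihood equals brute-force path enumeration at T = 6, K = 2", {
  set.seed(3)
  X <- matrix(rnorm(2 * 6), 2, 6)
  model <- list(means = cbind(c(-1, 0), c(1, 0.5)),
                covs = list(diag(c(1, 2)), matrix(c(1.5, 0.3, 0.3, 0.8), 2)),
                transition = matrix(c(0.9, 0.2, 0.1, 0.8), 2),
                initial = c(0.6, 0.4))
  ll <- hmm_loglik(model, X)
  dens <- function(x, k)
    exp(-0.5 * drop(t(x - model$means[, k]) %*% solve(model$covs[[k]]) %*%
                    (x - model$means[, k]))) /
      (2 * pi * sqrt(det(model$covs[[k]])))
  total <- 0
  for (path_id in 0:(2^6 - 1)) {
    s <- as.integer(intToBits(path_id))[1:6] + 1L
    p <- model$initial[s[1]] * dens(X[, 1], s[1])
    for (t in 2:6) p <- p * model$transition[s[t - 1], s[t]] * dens(X[, t], s[t])
    total <- total + p
  }
  expect_lt(abs(ll - log(total)), 1e-9)
})

test_that("well-separated two-state data is decoded above 90% accuracy", {
  set.seed(21)
  fs <- 250; nt <- fs * 60
  dwell <- 0.2 * fs
  truth <- integer(nt); truth[1] <- 1L
  for (t in 2:nt)
    truth[t] <- if (runif(1) < 1 - 1 / dwell) truth[t - 1] else 3L - truth[t - 1]
  mu <- cbind(c(0, 0, 0), c(3, -3, 2))
  X <- mu[, truth] + matrix(rnorm(3 * nt), 3)
  fit <- fit_hmm(X, K = 2, fs = fs, seed = 5, n_restarts = 2)
  acc <- max(mean(fit$statepath$states == truth),
             mean(3L - fit$statepath$states == truth))
  expect_gt(acc, 0.9)
})

test_that("K = 1 yields an all-ones statepath", {
  X <- matrix(rnorm(2 * 500), 2)
  fit <- fit_hmm(X, K = 1, fs = 100)
  expect_true(all(fit$statepath$states == 1L))
})

test_that("modal epoching uses 50-sample epochs at 250 Hz and the stated tie rule", {
  fs <- 250
  rec <- sensor_recording(matrix(rnorm(2 * 500), 2), fs, c("a", "b"))
  path <- list(states = rep(1L, 500), K = 3L, fs = fs)
  em <- epoch_modal(rec, path, epoch_ms = 200)
  expect_identical(dim(em$epochs)[2], 50L)
  expect_identical(dim(em$epochs)[3], 10L)
  expect_true(all(em$tags == 1L))
  # segment of 30 state-2 then 20 state-3 -> tagged 2; 25/25 tie -> lower index
  path$states[1:50] <- c(rep(2L, 30), rep(3L, 20))
  path$states[51:100] <- c(rep(3L, 25), rep(2L, 25))
  em <- epoch_modal(rec, path, epoch_ms = 200)
  expect_identical(em$tags[1:2], c(2L, 2L))
  # losslessness up to the trailing partial epoch
  rec2 <- sensor_recording(matrix(rnorm(2 * 520), 2), fs, c("a", "b"))
  path2 <- list(states = rep(1L, 520), K = 1L, fs = fs)
  em2 <- epoch_modal(rec2, path2, 200)
  expect_identical(matrix(em2$epochs, 2), rec2$data[, 1:500])
  expect_error(epoch_modal(rec, path, epoch_ms = 5000), "longer than")
})

test_that("state partitioning conserves epochs and dominant selection follows counts", {
  tagged <- list(epochs = array(rnorm(2 * 10 * 111), c(2, 10, 111)),
                 tags = rep(1:8, c(10, 40, 30, 20, 5, 1, 2, 3)),
                 fs = 250, labels = c("a", "b"))
  ds <- partition_states(tagged, 8)
  expect_identical(sum(vapply(ds, function(d) dim(d$epochs)[3], numeric(1))),
                   111)
  dom <- dominant_states(ds, 4)
  expect_identical(vapply(dom, `[[`, integer(1), "state_id"), c(2L, 3L, 4L, 1L))
  # equal counts tie-break to the lowest state ids
  tagged$tags <- rep(1:8, length.out = 111 - 111 %% 8)[1:111]
  tagged$tags <- rep(1:8, each = 13)[1:104]
  tagged$epochs <- tagged$epochs[, , 1:104, drop = FALSE]
  dom2 <- dominant_states(partition_states(tagged, 8), 3)
  expect_identical(vapply(dom2, `[[`, integer(1), "state_id"), 1:3)
  # empty state is a dataset, not an error
  tagged$tags <- rep(1L, 104)
  ds3 <- partition_states(tagged, 2)
  expect_identical(dim(ds3[[2]]$epochs)[3], 0L)
  expect_warning(dominant_states(ds3, 2), "nonempty")
})

test_that("815 epochs of 200 ms correspond to 163 s of data", {
  expect_equal(815 * 0.2, 163)
})

test_that("state sensor maps match brute-force Pearson correlations", {
  set.seed(4)
  nt <- 2000
  states <- rep(rep(1:2, each = 100), 10)
  x1 <- rnorm(nt) * (1 + 2 * (states == 1))
  x2 <- rnorm(nt)
  rec <- sensor_recording(rbind(x1, x2), 250, c("a", "b"))
  path <- list(states = states, K = 2L, fs = 250)
  map <- state_sensor_map(rec, path, 1)
  env <- t(apply(rec$data, 1, meshbench:::amplitude_envelope))
  oracle <- apply(env, 1, function(e) cor(e, as.numeric(states == 1)))
  expect_equal(unname(map), unname(oracle), tolerance = 1e-12)
  expect_gt(map[1], 0)
  expect_error(state_sensor_map(rec, path, 5), "never visited")
  const <- list(states = rep(1L, nt), K = 1L, fs = 250)
  expect_error(state_sensor_map(rec, const, 1), "constant")
})
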