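# tiny linear-Gaussian toy shared by several oracle checks
toy_system <- function(C = 4, N = 6, seed = 2) {
  set.seed(seed)
  L <- matrix(rnorm(C * N), C, N)
  structure(list(values = L, channel_labels = paste0("c", 1:C),
                 mesh_id = "toy"), class = "gain_matrix")
}

test_that("temporal modes are orthonormal and variance fractions match an SVD oracle", {
  set.seed(1)
  ep <- array(rnorm(20 * 50 * 12), c(20, 50, 12))
  tr <- temporal_reduce(list(epochs = ep), R = 16)
  expect_equal(crossprod(tr$modes), diag(16), tolerance = 1e-9)
  expect_identical(dim(tr$reduced), c(20L, 16L * 12L))
  # oracle: eigenvalues of the summed temporal covariance
  M <- matrix(0, 50, 50)
  for (e in 1:12) M <- M + crossprod(ep[, , e])
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(tr$variance_retained, sum(ev[1:16]) / sum(ev), tolerance = 1e-10)
  # rank-1 data has one usable mode explaining everything
  ep1 <- array(outer(rnorm(3), outer(rnorm(10), rnorm(4))), c(3, 10, 4))
  expect_warning(tr1 <- temporal_reduce(list(epochs = ep1), R = 5), "rank")
  expect_identical(tr1$R, 1L)
  expect_equal(tr1$variance_retained, 1, tolerance = 1e-12)
})

test_that("the minimum-norm prior reproduces the closed-form ridge solution", {
  g <- toy_system(4, 6)
  set.seed(3)
  Y <- matrix(rnorm(4 * 10), 4)
  pr <- prior_mmn(6)
  w <- c(0.3, 1.7)   # fixed noise and source weights
  fit <- reml_fit(g, Y, pr, fixed_weights = w)
  J <- map_sources(fit, g, Y, pr)
  # oracle: J = Q L' (L Q L' + mu I)^-1 Y with Q = w2 I, mu = w1
  L <- g$values
  J_oracle <- w[2] * t(L) %*% solve(w[2] * L %*% t(L) + w[1] * diag(4), Y)
  expect_lt(max(abs(J - J_oracle)), 1e-8)
  expect_identical(map_sources(fit, g, 0 * Y, pr), 0 * J)
})

test_that("free-energy differences at fixed weights equal analytic Gaussian log-evidence differences", {
  set.seed(9)
  L <- matrix(rnorm(2 * 5), 2, 5)
  g <- structure(list(values = L, channel_labels = c("a", "b"), mesh_id = "t"),
                 class = "gain_matrix")
  Y <- matrix(rnorm(2 * 30), 2)
  pr <- prior_mmn(5)
  f1 <- reml_fit(g, Y, pr, fixed_weights = c(1, 0.5))$F
  f2 <- reml_fit(g, Y, pr, fixed_weights = c(0.2, 2))$F
  logev <- function(w) {
    S <- w[1] * diag(2) + w[2] * L %*% t(L)
    n <- ncol(Y)
    Cy <- Y %*% t(Y) / n
    -n / 2 * (sum(diag(solve(S) %*% Cy)) + log(det(S)) + 2 * log(2 * pi))
  }
  expect_lt(abs((f1 - f2) - (logev(c(1, 0.5)) - logev(c(0.2, 2)))), 1e-6)
})

test_that("ReML recovers a known noise level and ascends monotonically", {
  set.seed(12)
  C <- 8; n <- 600
  Y <- matrix(rnorm(C * n, sd = sqrt(2)), C)      # true Sigma = 2 I
  g <- structure(list(values = matrix(0, C, 0), channel_labels = paste0("c", 1:C),
                      mesh_id = "t"), class = "gain_matrix")
  fit <- reml_fit(g, Y, NULL)                     # noise-only model
  expect_lt(abs(fit$weights[1] - 2) / 2, 0.10)
  expect_true(all(diff(fit$F_trace) >= -1e-10))
})

test_that("ReML ascent holds for data-driven priors too", {
  set.seed(5)
  m <- fix_sphere_mesh(42)
  sa <- fix_sensors(8)
  g <- gain_matrix(fix_folded_mesh(42), sa)
  Y <- g$values %*% matrix(rnorm(42 * 80), 42) + matrix(rnorm(8 * 80), 8)
  for (pr in list(prior_mmn(42), prior_ebb(g, Y))) {
    fit <- reml_fit(g, Y, pr)
    expect_true(all(diff(fit$F_trace) >= -1e-10))
    expect_true(all(eigen(fit$Sigma_y, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("LOR Green's kernel matches a dense matrix-exponential oracle", {
  m <- fix_sphere_mesh(12)       # icosahedron, 12 vertices
  G <- greens_kernel(m, 0.6)
  A <- as.matrix(meshbench:::row_norm_adjacency(m))
  expect_lt(max(abs(G - pracma::expm(0.6 * A))), 1e-6)
  expect_identical(greens_kernel(m, 0), diag(12))
  Q <- tcrossprod(G)
  expect_equal(Q, t(Q), tolerance = 1e-12)
  expect_true(all(eigen(Q, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("EBB variances reduce to inverse column norms under white data and are unit trace", {
  g <- toy_system(6, 10, seed = 4)
  # sensor covariance exactly I: use data whose sample covariance is I
  set.seed(6)
  Z <- matrix(rnorm(6 * 2000), 6)
  W <- t(chol(tcrossprod(Z) / 2000))
  Y <- solve(W, Z)                 # sample covariance exactly I
  pr <- prior_ebb(g, Y)
  v <- pr$components[[1]]$value
  expect_equal(sum(v), 1, tolerance = 1e-12)
  v_oracle <- 1 / colSums(g$values^2)
  expect_equal(v / max(v), v_oracle / max(v_oracle), tolerance = 1e-6)
})

test_that("EBB localizes a single strong source to its graph neighbourhood", {
  m <- fix_folded_mesh(162, amp = 4, freq = 6, seed = 8)
  sa <- fix_sensors(32)
  g <- gain_matrix(m, sa)
  src <- 57
  set.seed(7)
  Y <- g$values[, src, drop = FALSE] %*% rnorm(200) * 20
  Y <- Y + matrix(rnorm(length(Y), sd = 0.01 * sd(Y)), nrow(Y))
  pr <- prior_ebb(g, Y)
  peak <- which.max(pr$components[[1]]$value)
  e <- meshbench:::mesh_edges(m$faces)
  nbh <- c(src, e[e[, 1] == src, 2], e[e[, 2] == src, 1])
  expect_true(peak %in% nbh)
  # and the MAP source under the EBB prior peaks there as well
  fit <- reml_fit(g, Y, pr)
  J <- map_sources(fit, g, Y, pr)
  expect_true(which.max(rowSums(J^2)) %in% nbh)
})

test_that("MSP components are rank-1 patches placed quasi-uniformly", {
  m <- fix_sphere_mesh(162)
  pr <- prior_msp(m, n_patches = 16, seed = 3)
  expect_length(pr$components, 16)
  expect_true(all(vapply(pr$components, function(c) ncol(c$value) == 1,
                         logical(1))))
  seeds <- attr(pr, "seed_vertices")
  gph <- igraph::graph_from_edgelist(meshbench:::mesh_edges(m$faces),
                                     directed = FALSE)
  D <- igraph::distances(gph, v = seeds, to = seeds)
  mine <- min(D[upper.tri(D)])
  # exhaustive check over every possible starting vertex of the
  # farthest-point procedure
  best <- max(vapply(1:162, function(s0) {
    sel <- s0
    mind <- drop(igraph::distances(gph, v = s0))
    for (k in 2:16) {
      sel <- c(sel, which.max(mind))
      mind <- pmin(mind, drop(igraph::distances(gph, v = sel[k])))
    }
    Ds <- igraph::distances(gph, v = sel, to = sel)
    min(Ds[upper.tri(Ds)])
  }, numeric(1)))
  expect_gte(mine, 0.5 * best)
  expect_warning(prior_msp(fix_sphere_mesh(12), n_patches = 50), "capped")
})

test_that("MSP pruning keeps the fit usable on a sparse-source toy", {
  m <- fix_sphere_mesh(42)
  sa <- fix_sensors(12)
  g <- gain_matrix(fix_folded_mesh(42), sa)
  set.seed(10)
  Y <- g$values[, 11, drop = FALSE] %*% rnorm(100) * 10 +
       matrix(rnorm(12 * 100, sd = 0.05), 12)
  pr <- prior_msp(fix_folded_mesh(42), n_patches = 20, seed = 2)
  fit <- reml_fit(g, Y, pr)
  expect_lt(length(fit$active), 21)
  expect_true(all(diff(fit$F_trace) >= -1e-10))
  J <- map_sources(fit, g, Y, pr)
  expect_identical(dim(J), c(42L, 100L))
})

test_that("held-out prediction is linear, zero for zero sources, and accurate noiselessly", {
  m <- fix_folded_mesh(162, amp = 4, freq = 6, seed = 13)
  sa <- fix_sensors(32)
  g <- gain_matrix(m, sa)
  set.seed(14)
  ep <- array(0, c(32, 40, 3))
  src <- matrix(rnorm(2 * 120), 2)
  for (e in 1:3)
    ep[, , e] <- g$values[, c(40, 90)] %*% (src[, (e - 1) * 40 + 1:40] * 15)
  tr <- suppressWarnings(temporal_reduce(list(epochs = ep[-1, , , drop = FALSE]),
                                         R = 8))   # noiseless data is rank 6
  g_fit <- meshbench:::subset_gain(g, 2:32)
  g_out <- meshbench:::subset_gain(g, 1)
  pr <- prior_mmn(162)
  fit <- reml_fit(g_fit, tr$reduced, pr)
  J <- map_sources(fit, g_fit, tr$reduced, pr)
  pred <- predict_heldout(J, g_out, tr$modes)
  truth <- matrix(ep[1, , ], nrow = 1)
  expect_gt(cor(drop(pred), drop(truth)), 0.99)
  expect_identical(predict_heldout(0 * J, g_out, tr$modes),
                   matrix(0, 1, 120))
  expect_equal(predict_heldout(2 * J, g_out, tr$modes), 2 * pred,
               tolerance = 1e-12)
  expect_error(predict_heldout(J, g_out, tr$modes,
                               fit_labels = g$channel_labels), "overlap")
})
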