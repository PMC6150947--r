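#' Temporal reduction of a state dataset to orthonormal modes
#'
#' Computes the dominant temporal subspace of an epoched dataset: the
#' S x S temporal covariance summed over epochs and channels is
#' eigendecomposed and the top R eigenvectors retained as an orthonormal
#' temporal basis. Each epoch is projected onto the modes and the
#' projections concatenated, so the reduced data is C x (R*E).
#'
#' @param dataset a `state_dataset` (or any list with `epochs` C x S x E).
#' @param R number of temporal modes (default 16).
#' @return list with `modes` (S x R, orthonormal), `reduced` (C x (R*E)),
#'   `variance_retained`, `R` (effective), `n_epochs`.
#' @export
temporal_reduce <- function(dataset, R = 16) {
  ep <- dataset$epochs
  stopifnot(length(dim(ep)) == 3, dim(ep)[3] >= 1)
  S <- dim(ep)[2]; E <- dim(ep)[3]
  if (R > S) stop("more temporal modes requested than samples per epoch")
  X <- matrix(aperm(ep, c(1, 3, 2)), dim(ep)[1] * E, S)  # (C*E) x S
  M <- crossprod(X)                                      # sum_e Y_e' Y_e
  eg <- eigen(M, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  R_eff <- R
  if (R > rank) {
    warning(sprintf("temporal rank %d < R; keeping %d modes", rank, rank))
    R_eff <- rank
  }
  modes <- eg$vectors[, seq_len(R_eff), drop = FALSE]
  P <- array(X %*% modes, c(dim(ep)[1], E, R_eff))       # (C,E,R)
  red <- matrix(aperm(P, c(1, 3, 2)), dim(ep)[1], R_eff * E)
  list(modes = modes, reduced = red,
       variance_retained = sum(ev[seq_len(R_eff)]) / sum(ev),
       R = R_eff, n_epochs = E)
}

# ---- source-covariance prior sets --------------------------------------
# Components are stored symbolically to bound memory:
#   identity : C_k = I_N                      (value = N)
#   diag     : C_k = diag(value)              (value = length-N variances)
#   factor   : C_k = V V'                     (value = N x r matrix V)

new_prior_set <- function(kind, components) {
  structure(list(kind = kind, components = components), class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("prior_set %s: %d component(s)\n", x$kind, length(x$components)))
  invisible(x)
}

#' Minimum-norm (IID) source-covariance prior
#'
#' A single identity component: every source has equal, independent prior
#' variance. With this prior the MAP estimate is the classical (unweighted)
#' minimum-norm / Tikhonov solution.
#'
#' @param N number of sources.
#' @return a `prior_set` of kind `"MMN"`.
#' @export
prior_mmn <- function(N) {
  stopifnot(N >= 1)
  new_prior_set("MMN", list(list(type = "identity", value = N)))
}

# row-normalized vertex adjacency of a mesh
row_norm_adjacency <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  A / Matrix::rowSums(A)
}

#' Surface Green's-function smoothing kernel
#'
#' The graph heat kernel `G = exp(s A)` on the row-normalized vertex
#' adjacency A, computed by a truncated Taylor series (terms added until the
#' next term's maximum entry falls below 1e-12; since the row-normalized A
#' has spectral radius <= 1 the series converges rapidly for moderate s).
#'
#' @param mesh a [cortical_mesh()].
#' @param s smoothing parameter (default 0.6); `s = 0` gives the identity.
#' @return dense N x N matrix G.
#' @export
greens_kernel <- function(mesh, s = 0.6) {
  n <- nrow(mesh$vertices)
  if (s == 0) return(diag(n))
  A <- row_norm_adjacency(mesh)
  G <- Matrix::Diagonal(n)
  term <- Matrix::Diagonal(n)
  for (k in 1:60) {
    term <- (s / k) * (A %*% term)
    G <- G + term
    if (max(abs(term)) < 1e-12) break
  }
  as.matrix(G)
}

#' LORETA-like smooth source-covariance prior
#'
#' A single smooth component `Q = G G'` built from surface Green's-function
#' smoothing of the mesh graph (no depth weighting): neighbouring sources
#' are a priori correlated, favouring spatially smooth current
#' distributions.
#'
#' @param mesh a [cortical_mesh()].
#' @param smooth_s Green's-function smoothing parameter (default 0.6).
#' @return a `prior_set` of kind `"LOR"`.
#' @export
prior_lor <- function(mesh, smooth_s = 0.6) {
  G <- greens_kernel(mesh, smooth_s)
  new_prior_set("LOR", list(list(type = "factor", value = G)))
}

#' Empirical Bayesian beamformer source-variance prior
#'
#' Estimates each source's prior variance directly from the sensor data as
#' the classical beamformer power `1 / (l_i' C_y^{-1} l_i)` (with zero
#' regularization of the sensor covariance), normalized to unit trace, and
#' uses the resulting diagonal matrix as a single covariance component.
#'
#' @param gain a `gain_matrix` (rows must match the channels of
#'   `reduced_data`).
#' @param reduced_data C x n matrix (e.g. `$reduced` from
#'   [temporal_reduce()]).
#' @return a `prior_set` of kind `"EBB"`.
#' @export
prior_ebb <- function(gain, reduced_data) {
  L <- gain$values
  stopifnot(nrow(L) == nrow(reduced_data))
  Cy <- tcrossprod(reduced_data) / ncol(reduced_data)
  Cyi <- tryCatch(solve(Cy), error = function(e) {
    warning("singular sensor covariance; using pseudo-inverse")
    pinv_sym(Cy)
  })
  denom <- colSums(L * (Cyi %*% L))
  v <- numeric(ncol(L))
  ok <- denom > 0
  if (!all(ok)) warning("zero-norm lead-field column(s); variance set to 0")
  v[ok] <- 1 / denom[ok]
  v <- v / sum(v)
  new_prior_set("EBB", list(list(type = "diag", value = v)))
}

pinv_sym <- function(M, tol = 1e-10) {
  eg <- eigen(M, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * tol
  eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
}

#' Multiple sparse priors: patch covariance components
#'
#' Builds `n_patches` rank-1 covariance components, one per cortical patch:
#' component k is `g_k g_k'` where `g_k` is the Green's-function column at a
#' seed vertex. Seeds are placed quasi-uniformly by farthest-point sampling
#' on the mesh graph (geodesic hop distance), starting from a seeded random
#' vertex.
#'
#' @param mesh a [cortical_mesh()].
#' @param n_patches number of patches (default 512; capped at N with a
#'   warning).
#' @param smooth_s Green's-function smoothing parameter.
#' @param seed RNG seed for the starting vertex.
#' @return a `prior_set` of kind `"MSP"`; attribute `seed_vertices` records
#'   the patch centres.
#' @export
prior_msp <- function(mesh, n_patches = 512, smooth_s = 0.6, seed = 1) {
  n <- nrow(mesh$vertices)
  if (n_patches > n) {
    warning("n_patches exceeds vertex count; capped")
    n_patches <- n
  }
  e <- mesh_edges(mesh$faces)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  seeds <- integer(n_patches)
  seeds[1] <- withr::with_seed(seed, sample.int(n, 1))
  mind <- drop(igraph::distances(g, v = seeds[1]))
  for (k in seq_len(n_patches)[-1]) {
    seeds[k] <- which.max(mind)
    mind <- pmin(mind, drop(igraph::distances(g, v = seeds[k])))
  }
  G <- greens_kernel(mesh, smooth_s)
  comps <- lapply(seeds, function(v)
    list(type = "factor", value = G[, v, drop = FALSE]))
  ps <- new_prior_set("MSP", comps)
  attr(ps, "seed_vertices") <- seeds
  ps
}

# sensor-space factor F_k with L C_k L' = F_k F_k'
sensor_factor <- function(comp, L) {
  switch(comp$type,
         identity = L,
         diag = sweep(L, 2, sqrt(comp$value), "*"),
         factor = L %*% comp$value,
         stop("unknown component type"))
}

# Q_s L' accumulation for MAP estimation (N x C), weights on original scale
source_times_gain_t <- function(priors, weights, L) {
  A <- matrix(0, ncol(L), nrow(L))
  for (k in seq_along(priors$components)) {
    comp <- priors$components[[k]]
    w <- weights[k]
    if (w == 0) next
    A <- A + switch(comp$type,
      identity = w * t(L),
      diag = w * (comp$value * t(L)),
      factor = comp$value %*% (w * crossprod(comp$value, t(L))))
  }
  A
}

#' Restricted-maximum-likelihood fit of covariance hyperparameters
#'
#' Fits the linear-Gaussian observation model
#' \deqn{\Sigma_y = e^{\lambda_0} Q_\epsilon + \sum_k e^{\lambda_k}
#'   L C_k L',}
#' maximizing the variational (Laplace) free energy over the log-scale
#' hyperparameters by Fisher scoring with step halving, under weak Gaussian
#' hyperpriors `N(hE, hC)` per hyperparameter. The reported free energy is
#' \deqn{F = -\tfrac n2\left[tr(\Sigma_y^{-1} C_y) + \log|\Sigma_y| +
#'   C\log 2\pi\right] - \tfrac12 (\lambda-hE)' hC^{-1} (\lambda-hE)
#'   + \tfrac12 \log|hC^{-1} H^{-1}|,}
#' with `C_y` the sample covariance of the n reduced data columns and H the
#' posterior precision of the hyperparameters; F is non-decreasing across
#' iterations by construction of the step-halving line search. Components
#' and data are trace-normalized internally; reported `weights` are on the
#' original data scale. For sets with many components (MSP) components whose
#' log-weights collapse below the pruning threshold are removed from the
#' active set (automatic relevance determination).
#'
#' Passing `fixed_weights` (original-scale, noise first) skips optimization
#' and returns the plain Gaussian log evidence of the fixed model as `F`
#' (no hyperprior or Laplace terms): the closed-form
#' \eqn{-\tfrac n2 [tr(\Sigma^{-1}C_y) + \log|\Sigma| + C\log 2\pi]}.
#'
#' @param gain a `gain_matrix` for the fitted channels.
#' @param Y C x n reduced data matrix.
#' @param priors a `prior_set`.
#' @param noise_cov per-channel noise variances (default rep(1, C): white).
#' @param hE,hC hyperprior mean and variance on the log hyperparameters.
#' @param max_iter,tol optimization controls.
#' @param prune_threshold log-weight (relative scale) below which a
#'   component of a many-component set is pruned.
#' @param fixed_weights optional original-scale weights `c(w_noise, w_1..)`.
#' @return an `inversion_result`: `lambda`, `weights` (original scale, noise
#'   first), `F`, `accuracy`, `Sigma_y` (original scale), `converged`,
#'   `active`, `prior_kind`, `mesh_id`, `channel_labels`, `n`.
#' @export
reml_fit <- function(gain, Y, priors, noise_cov = NULL, hE = -32, hC = 256,
                     max_iter = 256, tol = 1e-7, prune_threshold = -16,
                     fixed_weights = NULL) {
  L <- gain$values
  C <- nrow(L)
  if (is.null(priors)) priors <- new_prior_set("NOISE", list())
  stopifnot(nrow(Y) == C)
  n <- ncol(Y)
  if (is.null(noise_cov)) noise_cov <- rep(1, C)
  Cy <- tcrossprod(Y) / n
  sy <- mean(diag(Cy))
  if (sy <= 0) stop("zero data: covariance fit undefined")

  facs <- c(list(sqrt(noise_cov) * diag(C)),
            lapply(priors$components, sensor_factor, L = L))
  # factors wider than C carry a rank <= C component; compress to an exact
  # C x r eigenfactor so the hyperparameter algebra stays O(C) per component
  facs <- lapply(facs, function(f) {
    if (ncol(f) <= C) return(f)
    eg <- eigen(tcrossprod(f), symmetric = TRUE)
    keep <- eg$values > max(eg$values, 0) * 1e-14
    eg$vectors[, keep, drop = FALSE] *
      rep(sqrt(eg$values[keep]), each = C)
  })
  K <- length(facs)
  s_k <- vapply(facs, function(f) sum(f^2) / C, numeric(1))
  if (any(s_k <= 0)) stop("degenerate (zero) covariance component")

  if (!is.null(fixed_weights)) {
    stopifnot(length(fixed_weights) == K)
    Sig <- matrix(0, C, C)
    for (k in seq_len(K)) Sig <- Sig + fixed_weights[k] * tcrossprod(facs[[k]])
    acc <- gauss_evidence(Sig, Cy, n)
    return(structure(list(lambda = log(fixed_weights), weights = fixed_weights,
                          F = acc, accuracy = acc, Sigma_y = Sig,
                          converged = TRUE, active = seq_len(K),
                          prior_kind = priors$kind, mesh_id = gain$mesh_id,
                          channel_labels = gain$channel_labels, n = n),
                     class = "inversion_result"))
  }

  facs_s <- lapply(seq_len(K), function(k) facs[[k]] / sqrt(s_k[k]))
  Cys <- Cy / sy
  Fall <- do.call(cbind, facs_s)
  grp <- rep(seq_len(K), vapply(facs_s, ncol, numeric(1)))
  active <- rep(TRUE, K)
  lam <- rep(log(1 / K), K)
  many <- K > 8

  sigma_of <- function(lam) {
    w_col <- exp(lam[grp[grp_active()]])
    Fa <- Fall[, grp_active(), drop = FALSE]
    Fa %*% (w_col * t(Fa))
  }
  grp_active <- function() which(active[grp])
  fobj <- function(lam) {
    Sig <- sigma_of(lam)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(F = -Inf))
    ldet <- 2 * sum(log(diag(ch)))
    Si <- chol2inv(ch)
    acc <- -n / 2 * (sum(Si * Cys) + ldet + C * log(2 * pi))
    pen <- -0.5 * sum((lam[active] - hE)^2) / hC
    list(F = acc + pen, Si = Si, Sig = Sig)
  }

  cur <- fobj(lam)
  f_trace <- cur$F
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ia <- which(active)
    cols <- grp_active()
    Fa <- Fall[, cols, drop = FALSE]
    SiF <- cur$Si %*% Fa
    t1 <- colSums(Fa * SiF)                   # tr(Si U_k) pieces
    Bm <- Cys %*% SiF
    t2 <- colSums(SiF * Bm)                   # tr(Si U_k Si Cy) pieces
    gk <- match(grp[cols], ia)
    g1 <- rowsum_vec(t1, gk, length(ia))
    g2 <- rowsum_vec(t2, gk, length(ia))
    ew <- exp(lam[ia])
    grad <- n / 2 * ew * (g2 - g1) - (lam[ia] - hE) / hC
    M <- crossprod(Fa, SiF)^2
    Hm <- rowsum(t(rowsum(M, gk)), gk)        # group-summed squared cross-traces
    H <- n / 2 * (ew %o% ew) * Hm + diag(1 / hC, length(ia))
    step <- drop(solve(H, grad))
    # line search: F must not decrease
    improved <- FALSE
    for (h in 0:8) {
      lam_try <- lam
      lam_try[ia] <- lam[ia] + step / 2^h
      cand <- fobj(lam_try)
      if (cand$F >= cur$F - 1e-10) {
        dF <- cand$F - cur$F
        lam <- lam_try
        cur <- cand
        improved <- TRUE
        break
      }
    }
    f_trace <- c(f_trace, cur$F)
    if (!improved) { converged <- TRUE; break }
    if (many && it >= 3) {
      drop_k <- ia[-1][lam[ia[-1]] < prune_threshold]  # never prune noise
      if (length(drop_k)) {
        active[drop_k] <- FALSE
        lam[drop_k] <- -Inf
        cur <- fobj(lam)
      }
    }
    if (dF < tol * max(1, abs(cur$F))) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ReML did not converge within max_iter; returning best iterate")

  # Laplace term at the optimum
  ia <- which(active)
  cols <- grp_active()
  Fa <- Fall[, cols, drop = FALSE]
  SiF <- cur$Si %*% Fa
  gk <- match(grp[cols], ia)
  M <- crossprod(Fa, SiF)^2
  Hm <- rowsum(t(rowsum(M, gk)), gk)
  ew <- exp(lam[ia])
  H <- n / 2 * (ew %o% ew) * Hm + diag(1 / hC, length(ia))
  lap <- 0.5 * (length(ia) * log(1 / hC) - determinant(H)$modulus[1])

  w <- exp(lam) * sy / s_k
  w[!active] <- 0
  Sig_orig <- sy * cur$Sig
  acc_orig <- gauss_evidence(Sig_orig, Cy, n)
  pen <- -0.5 * sum((lam[active] - hE)^2) / hC
  structure(list(lambda = lam, weights = w, F = acc_orig + pen + lap,
                 accuracy = acc_orig, Sigma_y = Sig_orig,
                 converged = converged, active = ia,
                 F_trace = f_trace, prior_kind = priors$kind,
                 mesh_id = gain$mesh_id, channel_labels = gain$channel_labels,
                 n = n),
            class = "inversion_result")
}

rowsum_vec <- function(x, g, ng) {
  out <- numeric(ng)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

# Gaussian log evidence of n iid columns with covariance Sig
gauss_evidence <- function(Sig, Cy, n) {
  ch <- chol(Sig)
  -n / 2 * (sum(chol2inv(ch) * Cy) + 2 * sum(log(diag(ch))) +
            nrow(Sig) * log(2 * pi))
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("inversion_result [%s on %s]: F = %.2f, %d/%d active components%s\n",
              x$prior_kind, x$mesh_id, x$F, length(x$active), length(x$lambda),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Maximum a posteriori source estimate
#'
#' `J = Q_s L' \Sigma_y^{-1} Y` with `Q_s` the fitted mixture of prior
#' covariance components.
#'
#' @param result an [reml_fit()] result.
#' @param gain the `gain_matrix` used in the fit.
#' @param reduced_data the C x n data that was fitted.
#' @param priors the `prior_set` used in the fit.
#' @return N x n matrix of source coefficients.
#' @export
map_sources <- function(result, gain, reduced_data, priors) {
  w_src <- result$weights[-1]
  A <- source_times_gain_t(priors, w_src, gain$values)
  ch <- tryCatch(chol(result$Sigma_y),
                 error = function(e) stop("model covariance not positive definite"))
  A %*% (chol2inv(ch) %*% reduced_data)
}

#' Predict held-out sensor data from source estimates
#'
#' Maps the source estimate through the held-out channels' lead fields and
#' back through the temporal modes to sample space:
#' `Yhat = L_out J` per mode, then `block %*% t(modes)` per epoch.
#'
#' @param J_hat N x (R*E) source coefficients from [map_sources()].
#' @param gain_heldout `gain_matrix` rows for the held-out channels.
#' @param modes S x R orthonormal temporal modes used in the reduction.
#' @param fit_labels optional channel labels used in fitting; if both label
#'   sets are present they must be disjoint.
#' @return C_out x (S*E) predicted sample-space data.
#' @export
predict_heldout <- function(J_hat, gain_heldout, modes, fit_labels = NULL) {
  if (!is.null(fit_labels) &&
      length(intersect(fit_labels, gain_heldout$channel_labels)) > 0)
    stop("held-out channels overlap the fitted channels")
  R <- ncol(modes)
  stopifnot(ncol(J_hat) %% R == 0)
  E <- ncol(J_hat) / R
  Ym <- gain_heldout$values %*% J_hat          # C_out x (R*E)
  S <- nrow(modes)
  out <- matrix(0, nrow(Ym), S * E)
  for (e in seq_len(E))
    out[, ((e - 1) * S + 1):(e * S)] <-
      Ym[, ((e - 1) * R + 1):(e * R), drop = FALSE] %*% t(modes)
  out
}
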