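#' Real spherical-harmonic basis on unit-sphere points
#'
#' Evaluates the orthonormal real spherical harmonics \eqn{S_{lm}} of degree
#' \eqn{l = 0..L} and order \eqn{m = -l..l} at a set of unit vectors. The
#' basis is fully normalized so that \eqn{\int S_{lm}^2 d\Omega = 1} over the
#' sphere, without the Condon-Shortley phase: for \eqn{m > 0} the functions
#' are \eqn{\sqrt 2\, \bar P_{lm}(\cos\theta)\cos(m\phi)} and for
#' \eqn{m < 0} \eqn{\sqrt 2\, \bar P_{l|m|}(\cos\theta)\sin(|m|\phi)}.
#' Normalized associated Legendre functions are computed by the standard
#' three-term recurrence, which is numerically stable to high degree.
#'
#' @param u numeric matrix, n x 3 unit vectors.
#' @param L_max maximum harmonic degree (>= 0).
#' @return n x (L_max+1)^2 matrix; column `l^2 + l + m + 1` holds degree `l`,
#'   order `m`.
#' @export
real_sph_harm <- function(u, L_max) {
  stopifnot(is.matrix(u), ncol(u) == 3, L_max >= 0)
  n <- nrow(u)
  nrm <- sqrt(rowSums(u^2))
  if (any(abs(nrm - 1) > 1e-6)) u <- u / nrm
  x <- u[, 3]                       # cos(theta)
  st <- sqrt(pmax(0, 1 - x^2))      # sin(theta)
  phi <- atan2(u[, 2], u[, 1])

  K <- (L_max + 1)^2
  B <- matrix(0, n, K)
  # Pbar[l, m]: fully normalized assoc. Legendre incl. the 1/sqrt(4*pi)
  # solid-angle factor; stored only for the current two degrees.
  cosm <- lapply(0:L_max, function(m) cos(m * phi))
  sinm <- lapply(0:L_max, function(m) sin(m * phi))
  col_of <- function(l, m) l^2 + l + m + 1

  # sectoral seeds P(m, m)
  pmm <- vector("list", L_max + 1)
  pmm[[1]] <- rep(sqrt(1 / (4 * pi)), n)
  if (L_max >= 1) {
    for (m in 1:L_max) {
      pmm[[m + 1]] <- sqrt((2 * m + 1) / (2 * m)) * st * pmm[[m]]
    }
  }
  for (m in 0:L_max) {
    p_prev <- pmm[[m + 1]]                       # P(m, m)
    for (l in m:L_max) {
      if (l == m) {
        p <- p_prev
        p_last2 <- NULL
      } else if (l == m + 1) {
        p_last2 <- p_prev
        p <- sqrt(2 * m + 3) * x * p_prev
      } else {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((2 * l + 1) * ((l - 1)^2 - m^2)) / ((2 * l - 3) * (l^2 - m^2)))
        p_new <- a * x * p - b * p_last2
        p_last2 <- p
        p <- p_new
      }
      if (m == 0) {
        B[, col_of(l, 0)] <- p
      } else {
        B[, col_of(l, m)] <- sqrt(2) * p * cosm[[m + 1]]
        B[, col_of(l, -m)] <- sqrt(2) * p * sinm[[m + 1]]
      }
    }
  }
  B
}

#' Degree index for each spherical-harmonic basis column
#'
#' @param L_max maximum degree.
#' @return integer vector of length (L_max+1)^2 giving the degree l of each
#'   column of [real_sph_harm()].
#' @export
sph_degree_index <- function(L_max) {
  rep.int(0:L_max, times = 2 * (0:L_max) + 1)
}
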