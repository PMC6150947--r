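#' Magnetic field of a current dipole in a conducting sphere (Sarvas)
#'
#' Closed-form field of a current dipole inside a homogeneous spherical
#' conductor, projected onto a sensor's pickup orientation. With r the sensor
#' position and r0 the dipole position (both relative to the sphere centre),
#' a = r - r0:
#' \deqn{B(r) = \frac{\mu_0}{4\pi F^2}\left(F\, Q\times r_0 -
#'   (Q\times r_0 \cdot r)\, \nabla F\right)}
#' where \eqn{F = a(ra + r^2 - r_0\cdot r)} and
#' \eqn{\nabla F = (a^2/r + (a\cdot r)/a + 2a + 2r)\,r - (a + 2r + (a\cdot r)/a)\,r_0.}
#' Radial dipole moments produce exactly zero external field (the spherical
#' conductor's silent sources); a dipole at the centre likewise gives 0.
#'
#' @param dipole_pos 3-vector, mm.
#' @param dipole_moment 3-vector, nAm.
#' @param sensor_pos 3-vector, mm (strictly outside the conductor).
#' @param sensor_ori unit 3-vector pickup direction.
#' @param center conductor centre, mm.
#' @param conductor_radius conductor radius, mm (for geometry checks; NULL
#'   skips them).
#' @return field in fT along `sensor_ori`.
#' @export
sarvas_leadfield <- function(dipole_pos, dipole_moment, sensor_pos, sensor_ori,
                             center = c(0, 0, 0), conductor_radius = NULL) {
  if (!is.null(conductor_radius)) {
    if (sqrt(sum((sensor_pos - center)^2)) <= conductor_radius)
      stop("sensor inside conductor sphere")
    if (sqrt(sum((dipole_pos - center)^2)) >= conductor_radius)
      stop("dipole outside conductor sphere")
  }
  # SI units: mm -> m, nAm -> Am, output T -> fT
  r <- (sensor_pos - center) * 1e-3
  r0 <- (dipole_pos - center) * 1e-3
  q <- dipole_moment * 1e-9
  a <- r - r0
  an <- sqrt(sum(a^2)); rn <- sqrt(sum(r^2))
  f <- an * (rn * an + rn^2 - sum(r0 * r))
  if (f == 0) return(0)
  gf <- (an^2 / rn + sum(a * r) / an + 2 * an + 2 * rn) * r -
        (an + 2 * rn + sum(a * r) / an) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  b <- 1e-7 / f^2 * (f * qxr0 - sum(qxr0 * r) * gf)
  sum(b * sensor_ori) * 1e15
}

#' Lead-field (gain) matrix for surface-normal unit dipoles
#'
#' Column i is the Sarvas field of a unit (1 nAm) dipole at vertex i,
#' oriented along the vertex's outward surface normal, evaluated at every
#' sensor. Units fT/nAm.
#'
#' @param mesh a [cortical_mesh()] strictly inside the conductor.
#' @param sensors a `sensor_array` from [gen_sensor_array()].
#' @param mesh_id optional identifier stored with the matrix.
#' @return a `gain_matrix`: list with `values` (C x N), `channel_labels`,
#'   `mesh_id`.
#' @export
gain_matrix <- function(mesh, sensors, mesh_id = "mesh") {
  ctr <- sensors$conductor_center
  v <- sweep(mesh$vertices, 2, ctr) * 1e-3          # N x 3, metres
  q <- mesh$normals * 1e-9                          # unit nAm moments
  rv <- sqrt(rowSums(v^2))
  if (any(rv * 1e3 >= sensors$conductor_radius)) {
    bad <- which(rv * 1e3 >= sensors$conductor_radius)
    stop(sprintf("%d vertices outside conductor sphere (e.g. %s)",
                 length(bad), paste(head(bad, 5), collapse = ", ")))
  }
  qxr0 <- cbind(q[, 2] * v[, 3] - q[, 3] * v[, 2],
                q[, 3] * v[, 1] - q[, 1] * v[, 3],
                q[, 1] * v[, 2] - q[, 2] * v[, 1])
  C <- nrow(sensors$positions)
  G <- matrix(0, C, nrow(v))
  for (ci in seq_len(C)) {
    r <- (sensors$positions[ci, ] - ctr) * 1e-3
    rn <- sqrt(sum(r^2))
    if (rn * 1e3 <= sensors$conductor_radius)
      stop(sprintf("sensor %d inside conductor sphere", ci))
    a <- matrix(r, nrow(v), 3, byrow = TRUE) - v
    an <- sqrt(rowSums(a^2))
    r0dr <- drop(v %*% r)
    adr <- drop(a %*% r)
    f <- an * (rn * an + rn^2 - r0dr)
    gf_r <- an^2 / rn + adr / an + 2 * an + 2 * rn   # coefficient of r
    gf_v <- -(an + 2 * rn + adr / an)                # coefficient of r0
    qxr0_dot_r <- drop(qxr0 %*% r)
    # b . ori = 1/f^2 * ( f * (qxr0 . ori) - (qxr0 . r) * (gradF . ori) )
    ori <- sensors$orientations[ci, ]
    gf_dot_ori <- gf_r * sum(r * ori) + gf_v * drop(v %*% ori)
    G[ci, ] <- 1e-7 / f^2 * (f * drop(qxr0 %*% ori) - qxr0_dot_r * gf_dot_ori) * 1e15
  }
  structure(list(values = G, channel_labels = sensors$labels, mesh_id = mesh_id),
            class = "gain_matrix")
}
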