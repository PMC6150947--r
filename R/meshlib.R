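#' Spherical parameterization of a closed genus-0 mesh
#'
#' Maps every vertex bijectively onto the unit sphere. Meshes from
#' [gen_mesh()] carry their generating sphere coordinates and are projected
#' radially; external meshes are iteratively inflated (Laplacian smoothing
#' toward neighbour centroids with renormalization) until radial projection
#' from the centroid produces no flipped spherical triangles.
#'
#' @param mesh a [cortical_mesh()], closed and genus 0.
#' @param max_iter maximum inflation iterations for external meshes.
#' @return N x 3 matrix of unit vectors, attribute `flipped` = 0.
#' @export
parameterize_sphere <- function(mesh, max_iter = 2000) {
  if (euler_characteristic(mesh) != 2)
    stop("mesh is not genus 0; spherical parameterization undefined")
  sc <- attr(mesh, "sphere_coords")
  if (!is.null(sc)) {
    u <- sc
  } else {
    v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
    u <- v / sqrt(rowSums(v^2))
    if (count_flipped(u, mesh$faces) > 0) {
      nb <- adjacency_list(mesh$faces, nrow(v))
      for (it in seq_len(max_iter)) {
        cen <- t(vapply(nb, function(j) colMeans(u[j, , drop = FALSE]),
                        numeric(3)))
        u <- 0.5 * u + 0.5 * cen
        u <- u / sqrt(rowSums(u^2))
        if (count_flipped(u, mesh$faces) == 0) break
      }
    }
  }
  nf <- count_flipped(u, mesh$faces)
  if (nf > 0) stop(sprintf("parameterization failed: %d flipped triangles", nf))
  attr(u, "flipped") <- nf
  u
}

# number of spherical triangles whose orientation disagrees with outward
# winding (negative determinant of the vertex triple)
count_flipped <- function(u, faces) {
  d <- u[faces[, 1], 1] * (u[faces[, 2], 2] * u[faces[, 3], 3] -
                           u[faces[, 2], 3] * u[faces[, 3], 2]) -
       u[faces[, 1], 2] * (u[faces[, 2], 1] * u[faces[, 3], 3] -
                           u[faces[, 2], 3] * u[faces[, 3], 1]) +
       u[faces[, 1], 3] * (u[faces[, 2], 1] * u[faces[, 3], 2] -
                           u[faces[, 2], 2] * u[faces[, 3], 1])
  sum(d <= 0)
}

adjacency_list <- function(faces, n) {
  e <- mesh_edges(faces)
  nb <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    nb[[e[i, 1]]] <- c(nb[[e[i, 1]]], e[i, 2])
    nb[[e[i, 2]]] <- c(nb[[e[i, 2]]], e[i, 1])
  }
  nb
}

#' Weighted Fourier series basis for a parameterized mesh
#'
#' Real spherical harmonics up to degree `L_max`, evaluated at each vertex's
#' unit-sphere coordinate, together with the smoothing bandwidth sigma used
#' by the exponential reconstruction weights `exp(-l(l+1) sigma)`.
#'
#' @param mesh a [cortical_mesh()].
#' @param L_max maximum harmonic degree; needs (L_max+1)^2 <= N vertices.
#' @param sigma smoothing-kernel bandwidth (dimensionless; default 1e-4).
#' @return a `wfs_basis`: list with `B` (N x (L_max+1)^2), `sphere_coords`,
#'   `degree` (per column), `L_max`, `sigma`, `faces` (topology of the mesh
#'   the basis was built on).
#' @export
wfs_basis <- function(mesh, L_max, sigma = 1e-4) {
  stopifnot(L_max >= 0)
  if ((L_max + 1)^2 > nrow(mesh$vertices))
    stop("too few vertices for requested L_max: system would be rank deficient")
  u <- parameterize_sphere(mesh)
  structure(list(B = real_sph_harm(u, L_max), sphere_coords = u,
                 degree = sph_degree_index(L_max), L_max = L_max,
                 sigma = sigma, faces = mesh$faces),
            class = "wfs_basis")
}

#' Fit weighted Fourier series coefficients to a mesh
#'
#' Solves the least-squares system B f = v for each coordinate (x, y, z)
#' over the spherical-harmonic design matrix B, i.e. the Fourier
#' coefficients `f_lm = <f, S_lm>` obtained by solving a system of linear
#' equations on the (generally non-uniform) vertex sampling.
#'
#' @param mesh the [cortical_mesh()] to decompose (same vertex order as the
#'   basis).
#' @param basis a [wfs_basis()].
#' @return a `wfs_coefficients`: list with `f_lm` ((L_max+1)^2 x 3 matrix),
#'   `L_max`, `sigma`.
#' @export
fit_wfs <- function(mesh, basis) {
  stopifnot(inherits(basis, "wfs_basis"),
            nrow(mesh$vertices) == nrow(basis$B))
  qrB <- qr(basis$B)
  if (qrB$rank < ncol(basis$B))
    stop("rank-deficient harmonic design: reduce L_max")
  f <- qr.coef(qrB, mesh$vertices)
  structure(list(f_lm = f, L_max = basis$L_max, sigma = basis$sigma),
            class = "wfs_coefficients")
}

#' Reconstruct a mesh at harmonic order L
#'
#' Vertex positions are the exponentially weighted partial sum
#' \deqn{\hat v(\omega) = \sum_{l=0}^{L}\sum_{m=-l}^{l} e^{-l(l+1)\sigma}
#'   f_{lm} S_{lm}(\omega),}
#' so order 1 is a smooth ovoid and increasing L restores progressively
#' finer surface detail. Topology (faces) is copied from the basis mesh and
#' normals are recomputed.
#'
#' @param coeffs a [fit_wfs()] result.
#' @param basis the matching [wfs_basis()].
#' @param L harmonic order, 0 <= L <= L_max.
#' @return a [cortical_mesh()] in vertex correspondence with the original.
#' @export
reconstruct_mesh <- function(coeffs, basis, L) {
  if (L < 0 || L > basis$L_max) stop("L outside 0..L_max")
  keep <- basis$degree <= L
  w <- exp(-basis$degree[keep] * (basis$degree[keep] + 1) * basis$sigma)
  v <- basis$B[, keep, drop = FALSE] %*% (w * coeffs$f_lm[keep, , drop = FALSE])
  m <- cortical_mesh(v, basis$faces, validate = FALSE)
  attr(m, "sphere_coords") <- basis$sphere_coords
  m
}

#' Build a library of progressively distorted meshes
#'
#' Decomposes the mesh into its weighted Fourier series and reconstructs it
#' at every harmonic order 1..L_max, yielding a library that runs from a
#' completely smooth ovoid (order 1) up to a near copy of the input, plus
#' the true mesh itself. All meshes share the face array and vertex
#' correspondence.
#'
#' @param mesh the true [cortical_mesh()].
#' @param L_max highest harmonic order (>= 1; 50 at full scale).
#' @param sigma smoothing bandwidth, default 1e-4.
#' @param subject_id identifier carried in the library.
#' @return a `mesh_library`: list with `meshes` (named list, orders 1..L_max),
#'   `true_mesh`, `harmonic_orders`, `sigma`, `subject_id`.
#' @export
build_library <- function(mesh, L_max, sigma = 1e-4, subject_id = "subject") {
  stopifnot(L_max >= 1)
  basis <- wfs_basis(mesh, L_max, sigma)
  coeffs <- fit_wfs(mesh, basis)
  meshes <- lapply(seq_len(L_max), function(L) reconstruct_mesh(coeffs, basis, L))
  names(meshes) <- as.character(seq_len(L_max))
  structure(list(meshes = meshes, true_mesh = mesh,
                 harmonic_orders = seq_len(L_max), sigma = sigma,
                 subject_id = subject_id),
            class = "mesh_library")
}

#' @export
print.mesh_library <- function(x, ...) {
  cat(sprintf("mesh_library '%s': orders %d..%d + true mesh (%d vertices, sigma %g)\n",
              x$subject_id, min(x$harmonic_orders), max(x$harmonic_orders),
              nrow(x$true_mesh$vertices), x$sigma))
  invisible(x)
}
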