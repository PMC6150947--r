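#' Construct a cortical mesh object
#'
#' A `cortical_mesh` is a closed triangulated surface: vertex positions in
#' mm, triangular faces (1-based vertex indices, consistently wound so that
#' face normals point outward), and unit outward vertex normals. Normals are
#' recomputed from the geometry unless supplied.
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param normals optional N x 3 matrix of unit outward normals.
#' @param validate check closedness, Euler characteristic and normal
#'   orientation (default TRUE).
#' @return an object of class `cortical_mesh`.
#' @export
cortical_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, all(is.finite(vertices)))
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (is.null(normals)) normals <- vertex_normals(vertices, faces)
  m <- structure(list(vertices = vertices, faces = faces, normals = normals),
                 class = "cortical_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices, %d faces, Euler characteristic %d\n",
              nrow(x$vertices), nrow(x$faces), euler_characteristic(x)))
  invisible(x)
}

# undirected edge list (2-column, each edge once)
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic V - E + F of a triangulated mesh
#' @param mesh a `cortical_mesh`.
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh$faces)) + nrow(mesh$faces)
}

#' Validate mesh invariants
#'
#' Checks that the surface is a closed 2-manifold of genus 0 (every edge
#' shared by exactly two faces; Euler characteristic 2), that vertex normals
#' are unit length, and that normals point outward from the centroid.
#'
#' @param mesh a `cortical_mesh`.
#' @return invisibly TRUE; otherwise an error.
#' @export
validate_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2)) stop("mesh is not a closed 2-manifold")
  if (euler_characteristic(mesh) != 2)
    stop("mesh is not genus 0 (Euler characteristic != 2)")
  nn <- sqrt(rowSums(mesh$normals^2))
  if (any(abs(nn - 1) > 1e-9)) stop("vertex normals are not unit length")
  ctr <- colMeans(mesh$vertices)
  out <- rowSums(mesh$normals * sweep(mesh$vertices, 2, ctr))
  if (any(out <= 0)) stop("normals are not consistently outward")
  invisible(TRUE)
}

#' Area-weighted outward vertex normals
#'
#' Face normals (from the winding order) are accumulated onto their vertices
#' weighted by face area and normalized to unit length.
#'
#' @param vertices N x 3 matrix.
#' @param faces M x 3 integer matrix.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3], , drop = FALSE] - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted already
  n <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], faces[, j])
      idx <- as.integer(rownames(acc))
      n[idx, k] <- n[idx, k] + acc
    }
  }
  n / sqrt(rowSums(n^2))
}

# icosahedron with unit-norm vertices
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# Loop-style midpoint subdivision of a unit sphere triangulation
subdivide_sphere <- function(vertices, faces) {
  n <- nrow(vertices)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- mesh_edges(faces)
  mid <- (vertices[e[, 1], , drop = FALSE] + vertices[e[, 2], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  midx <- setNames(n + seq_len(nrow(e)), edge_key(e[, 1], e[, 2]))
  v <- rbind(vertices, mid)
  f <- matrix(0L, nrow(faces) * 4, 3)
  for (i in seq_len(nrow(faces))) {
    a <- faces[i, 1]; b <- faces[i, 2]; c <- faces[i, 3]
    ab <- midx[[edge_key(a, b)]]
    bc <- midx[[edge_key(b, c)]]
    ca <- midx[[edge_key(c, a)]]
    f[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                    c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = v, faces = f)
}

# smallest icosphere with at least n_vertices vertices (12, 42, 162, 642, ...)
icosphere <- function(n_vertices) {
  s <- icosahedron()
  while (nrow(s$vertices) < n_vertices) s <- subdivide_sphere(s$vertices, s$faces)
  s
}

#' Per-vertex Euclidean distances between corresponding vertices
#'
#' @param a,b `cortical_mesh` objects with identical vertex correspondence.
#' @return numeric vector of length N (mm).
#' @export
vertex_distances <- function(a, b) {
  if (nrow(a$vertices) != nrow(b$vertices))
    stop("meshes have different vertex counts; no correspondence")
  sqrt(rowSums((a$vertices - b$vertices)^2))
}

#' Percentile of a vertex-distance distribution
#'
#' Uses the linear-interpolation convention of [stats::quantile()] type 7
#' (the R default): the q-th percentile of sorted values x_(1..n) is obtained
#' by linear interpolation at rank 1 + (n-1) q/100.
#'
#' @param distances numeric vector (mm), nonempty.
#' @param q percentile in \[0, 100\].
#' @return scalar (mm).
#' @export
distance_percentile <- function(distances, q = 95) {
  if (length(distances) == 0) stop("empty distance vector")
  stopifnot(q >= 0, q <= 100)
  unname(quantile(distances, q / 100, type = 7))
}

#' Mean distance to the nearest edge-connected neighbour vertex
#'
#' @param mesh a `cortical_mesh`.
#' @return scalar (mm).
#' @export
mean_vertex_spacing <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  nn <- rep(Inf, nrow(mesh$vertices))
  for (i in seq_len(nrow(e))) {
    nn[e[i, 1]] <- min(nn[e[i, 1]], d[i])
    nn[e[i, 2]] <- min(nn[e[i, 2]], d[i])
  }
  mean(nn)
}
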