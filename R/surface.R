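# Radial basis function interpolation for surface reconstruction: morphing a
# template shell mesh onto predicted landmarks, interpolating thickness
# fields over the mesh, and mirroring the half head across the mid-sagittal
# plane.

.rbf_kernel <- function(r, kernel, eps) {
  switch(kernel,
    polyharmonic = r^3,
    thinplate = ifelse(r > 0, r^2 * log(r), 0),
    gaussian = exp(-(r / eps)^2),
    stop("unknown kernel: ", kernel)
  )
}

.pairwise_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Fit a radial basis function interpolant
#'
#' Solves the augmented linear system (kernel matrix plus affine polynomial
#' block) so the interpolant passes exactly through the training values and
#' reproduces affine functions exactly.  The default kernel is the
#' polyharmonic cubic `r^3`; thin-plate (`r^2 log r`) and Gaussian kernels
#' are offered.
#'
#' @param centers n x 3 matrix of interpolation nodes (>= 4, not coplanar
#'   for a full-rank affine block).
#' @param values Length-n vector or n x m matrix of values at the nodes.
#' @param kernel `"polyharmonic"`, `"thinplate"` or `"gaussian"`.
#' @param eps Gaussian kernel length scale, in units of the mean inter-node
#'   distance (default 1).
#' @return An `rbf_interpolant`; evaluate with `predict(fit, x)`.
#' @export
rbf_fit <- function(centers, values,
                    kernel = c("polyharmonic", "thinplate", "gaussian"),
                    eps = NULL) {
  kernel <- match.arg(kernel)
  centers <- as.matrix(centers)
  values <- as.matrix(values)
  n <- nrow(centers)
  if (n < 4) stop("conditioning error: need at least 4 centers")
  if (nrow(values) != n)
    stop("dimension error: values must have one row per center")
  d <- .pairwise_dist(centers, centers)
  if (any(d[upper.tri(d)] < 1e-12))
    stop("conditioning error: duplicate centers")
  # work in units of the mean inter-node distance: the polyharmonic kernel
  # grows as r^3, so unscaled mm coordinates make the system ill conditioned
  scale <- mean(d[upper.tri(d)])
  if (!is.finite(scale) || scale <= 0) scale <- 1
  if (is.null(eps)) eps <- 1
  K <- .rbf_kernel(d / scale, kernel, eps)
  P <- cbind(1, centers / scale)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(values, matrix(0, 4, ncol(values)))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e)
                    stop("conditioning error: singular RBF system (",
                         conditionMessage(e), ")"))
  sol <- sol + solve(A, rhs - A %*% sol)  # one step of iterative refinement
  structure(list(kernel = kernel, eps = eps, scale = scale,
                 centers = centers,
                 weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:4, , drop = FALSE]),
            class = "rbf_interpolant")
}

#' @rdname rbf_fit
#' @param object An `rbf_interpolant`.
#' @param x m x 3 matrix (or length-3 vector) of evaluation points.
#' @param ... Unused.
#' @return `predict()`: m x k matrix of interpolated values (a vector when
#'   the training values were a vector).
#' @export
predict.rbf_interpolant <- function(object, x, ...) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  s <- object$scale
  K <- .rbf_kernel(.pairwise_dist(x, object$centers) / s, object$kernel,
                   object$eps)
  out <- K %*% object$weights + cbind(1, x / s) %*% object$affine
  if (ncol(out) == 1L) as.vector(out) else out
}

#' Triangulated half-head template mesh
#'
#' A half-ellipsoid shell triangulation in the same aligned frame as the
#' landmark template, for morphing onto predicted geometries.  The mesh
#' boundary at the mid-sagittal plane lies on `y = 0`, so a mirrored mesh is
#' watertight along the seam.
#'
#' @param n_theta,n_phi Grid resolution (front-to-back, bottom-to-top).
#' @param schema A [skull_schema()].
#' @return A `skull_mesh`: list with `vertices` (V x 3, mm) and `faces`
#'   (F x 3 integer, counter-clockwise outward).
#' @export
template_mesh <- function(n_theta = 24, n_phi = 14, schema = skull_schema()) {
  tpl <- .template_default(schema)
  theta <- seq(0, pi, length.out = n_theta + 1)
  phi <- seq(-20 * .deg, 85 * .deg, length.out = n_phi + 1)
  g <- expand.grid(theta = theta, phi = phi)
  v <- .ell_point(g$theta, g$phi)
  v <- apply_transform(tpl$transform, v)
  idx <- function(it, ip) (ip - 1L) * (n_theta + 1L) + it
  faces <- NULL
  for (ip in seq_len(n_phi)) {
    for (it in seq_len(n_theta)) {
      a <- idx(it, ip); b <- idx(it + 1L, ip)
      c2 <- idx(it + 1L, ip + 1L); d2 <- idx(it, ip + 1L)
      faces <- rbind(faces, c(a, b, c2), c(a, c2, d2))
    }
  }
  colnames(v) <- c("x", "y", "z")
  structure(list(vertices = v, faces = faces), class = "skull_mesh")
}

#' Morph a template mesh onto target landmarks
#'
#' Fits a 3D-to-3D RBF mapping on corresponding landmark pairs and applies
#' it to every mesh vertex.  Template landmarks map exactly onto their
#' targets, and affine changes (e.g. uniform scaling) are reproduced exactly.
#'
#' @param mesh A `skull_mesh` template.
#' @param from n x 3 landmark positions in template space.
#' @param to n x 3 corresponding target positions (same row order).
#' @param kernel RBF kernel (see [rbf_fit()]).
#' @return The morphed `skull_mesh`.
#' @export
morph_mesh <- function(mesh, from, to, kernel = "polyharmonic") {
  from <- as.matrix(from)
  to <- as.matrix(to)
  if (!all(dim(from) == dim(to)))
    stop("correspondence error: landmark counts differ")
  fit <- rbf_fit(from, to, kernel = kernel)
  out <- mesh
  v <- predict(fit, mesh$vertices)
  dimnames(v) <- dimnames(mesh$vertices)
  out$vertices <- v
  out
}

#' Interpolate a thickness field over a mesh
#'
#' Scalar RBF interpolation of landmark thickness values to every mesh
#' vertex, floored at 0.
#'
#' @param mesh A `skull_mesh`.
#' @param landmarks m x 3 landmark positions (m >= 4).
#' @param thickness Length-m thickness values (mm).
#' @param kernel RBF kernel.
#' @return Numeric vector of per-vertex thickness (mm).
#' @export
thickness_field <- function(mesh, landmarks, thickness,
                            kernel = "polyharmonic") {
  fit <- rbf_fit(as.matrix(landmarks), as.numeric(thickness), kernel = kernel)
  pmax(predict(fit, mesh$vertices), 0)
}

#' Mirror a half head across the mid-sagittal plane
#'
#' Reflects coordinates across `y = 0`.  Points within `tol` of the plane
#' are kept once (not duplicated); mirrored landmarks get a `_m` label
#' suffix, and mirrored mesh faces are re-oriented so the full mesh stays
#' consistently wound and watertight along the seam.
#'
#' @param x A `predicted_geometry`, `processed_geometry`, labelled
#'   coordinate matrix, or `skull_mesh`.
#' @param tol Midline tolerance in mm.
#' @return For geometries/matrices: the full-head labelled coordinate
#'   matrix.  For meshes: the full-head `skull_mesh`.
#' @export
mirror_full_head <- function(x, tol = 1e-6) {
  if (inherits(x, "skull_mesh")) {
    v <- x$vertices
    off <- which(abs(v[, 2]) > tol)
    map <- seq_len(nrow(v))
    map[off] <- nrow(v) + seq_along(off)
    mv <- v[off, , drop = FALSE]
    mv[, 2] <- -mv[, 2]
    faces_m <- matrix(map[x$faces], ncol = 3)[, c(1, 3, 2), drop = FALSE]
    keep <- rowSums(matrix(faces_m > nrow(v), ncol = 3)) > 0
    structure(list(vertices = rbind(v, mv),
                   faces = rbind(x$faces, faces_m[keep, , drop = FALSE])),
              class = "skull_mesh")
  } else {
    coords <- if (is.matrix(x)) x else x$coords
    if (is.null(coords)) stop("state error: no coordinates to mirror")
    off <- which(abs(coords[, 2]) > tol)
    m <- coords[off, , drop = FALSE]
    m[, 2] <- -m[, 2]
    rownames(m) <- paste0(rownames(coords)[off], "_m")
    rbind(coords, m)
  }
}

#' Write a mesh to Wavefront OBJ
#'
#' @param mesh A `skull_mesh`.
#' @param path OBJ file path.
#' @param scalar Optional per-vertex scalar (e.g. thickness); written to a
#'   sidecar CSV next to `path`.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, scalar = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9f %.9f %.9f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  if (!is.null(scalar)) {
    side <- paste0(tools::file_path_sans_ext(path), "_scalar.csv")
    utils::write.csv(data.frame(vertex = seq_len(nrow(mesh$vertices)),
                                value = scalar),
                     side, row.names = FALSE)
  }
  invisible(path)
}
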