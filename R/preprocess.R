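# Reprocessing of raw suture-pair landmarks into the homologous 60-landmark
# representation, and rigid registration of all subjects into the anatomical
# frame (S01 at the origin, mid-sagittal plane y = 0, C01 on the +x axis).

#' Rigid transforms
#'
#' A rigid (rotation + translation) map `x -> R x + t` in mm.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return `rigid_transform()` returns a `rigid_transform` object;
#'   `apply_transform()` returns the transformed n x 3 coordinate matrix;
#'   `compose_transform()` the composition (first `a`, then `b`);
#'   `invert_transform()` the inverse map.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (determinant +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform,a,b `rigid_transform` objects.
#' @param coords n x 3 coordinate matrix.
#' @export
apply_transform <- function(transform, coords) {
  out <- coords %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  dimnames(out) <- dimnames(coords)
  out
}

#' @rdname rigid_transform
#' @export
compose_transform <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.vector(b$rotation %*% a$translation) + b$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*% transform$translation))
}

# Anatomical frame from labelled coordinates: origin at S01, x axis along
# S01 -> C01, y axis the component of the least-squares mid-sagittal plane
# normal orthogonal to x, z = x cross y, with the sign chosen so the landmark
# centroid (the head interior, superior to the S01-C01 line) has positive z.
.rigid_from_landmarks <- function(coords, schema) {
  mid_lab <- intersect(schema_midline_labels(schema), rownames(coords))
  if (!all(c("S01", "C01") %in% rownames(coords)))
    stop("integrity error: S01 and C01 are required for alignment")
  if (length(mid_lab) < 3L)
    stop("integrity error: need at least 3 midline landmarks for alignment")
  s01 <- coords["S01", ]
  c01 <- coords["C01", ]

  mid <- coords[mid_lab, , drop = FALSE]
  cen <- sweep(mid, 2, colMeans(mid))
  sv <- svd(cen)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate-plane error: midline landmarks are collinear")
  normal <- sv$v[, 3]

  xhat <- c01 - s01
  nx <- sqrt(sum(xhat^2))
  if (nx < 1e-9) stop("degenerate-plane error: S01 and C01 coincide")
  xhat <- xhat / nx

  yhat <- normal - sum(normal * xhat) * xhat
  ny <- sqrt(sum(yhat^2))
  if (ny < 1e-9)
    stop("degenerate-plane error: mid-sagittal normal parallel to S01-C01")
  yhat <- yhat / ny
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])

  centroid <- colMeans(coords) - s01
  if (sum(centroid * zhat) < 0) {
    yhat <- -yhat
    zhat <- -zhat
  }
  rot <- rbind(xhat, yhat, zhat)
  dimnames(rot) <- NULL
  rigid_transform(rot, as.vector(-rot %*% s01))
}

#' Convert suture landmark pairs to centerline landmarks and widths
#'
#' Replaces each open boundary pair by its midpoint (the suture centerline
#' landmark) and the Euclidean distance between the pair members (the suture
#' width in mm).  Closed sutures, digitized as a single centerline landmark,
#' receive width 0.  Widths below 0.5 mm are set to 0 (the minimum width
#' representable by downstream finite-element meshing).  The result is the
#' homologous 60-landmark representation with 32 widths.
#'
#' @param raw A `raw_landmark_set` (e.g. from [read_landmark_table()] or
#'   [sample_subject()]), or an already-processed `processed_geometry`
#'   (returned unchanged, making the operation idempotent).
#' @param schema A [skull_schema()].
#' @return A `processed_geometry`: list with `subject_id`, `age`, `coords`
#'   (60 x 3 labelled matrix, mm), `widths` (named length-32, mm),
#'   `thickness` (named length-25, mm, `NA` where unrecorded) and
#'   `transform_applied` (`NULL` until [align_geometry()] is applied).
#' @examples
#' geom <- pair_to_midline(newborn_template())
#' length(geom$widths)
#' @export
pair_to_midline <- function(raw, schema = skull_schema()) {
  if (inherits(raw, "processed_geometry")) return(raw)
  pm <- schema$pair_map
  have <- rownames(raw$coords)

  coords <- matrix(NA_real_, 60, 3,
                   dimnames = list(schema_labels(schema), c("x", "y", "z")))
  widths <- stats::setNames(numeric(32), pm$mid)
  for (i in seq_len(nrow(pm))) {
    m <- pm$mid[i]
    has_a <- pm$a[i] %in% have
    has_b <- pm$b[i] %in% have
    if (has_a && has_b) {
      pa <- raw$coords[pm$a[i], ]
      pb <- raw$coords[pm$b[i], ]
      coords[m, ] <- (pa + pb) / 2
      w <- sqrt(sum((pa - pb)^2))
      # zero rule with a 1e-9 numeric guard: a separation constructed to be
      # exactly 0.5 mm must survive floating-point distance recomputation
      widths[m] <- if (w < 0.5 - 1e-9) 0 else w
    } else if (!has_a && !has_b && m %in% have) {
      coords[m, ] <- raw$coords[m, ]
      widths[m] <- 0
    } else {
      stop("integrity error: suture ", m,
           " has one pair member missing in subject ", raw$subject_id)
    }
  }
  other <- schema$labels$label[schema$labels$role != "suture"]
  missing <- setdiff(other, have)
  if (length(missing))
    stop("integrity error: missing landmarks ", paste(missing, collapse = ", "),
         " in subject ", raw$subject_id)
  coords[other, ] <- raw$coords[other, ]

  th <- stats::setNames(rep(NA_real_, 25), schema$thickness_subset)
  if (!is.null(raw$thickness)) {
    keep <- intersect(names(raw$thickness), schema$thickness_subset)
    th[keep] <- raw$thickness[keep]
  }

  structure(list(subject_id = raw$subject_id, age = raw$age,
                 circumference = raw$circumference,
                 coords = coords, widths = widths, thickness = th,
                 transform_applied = NULL,
                 schema_signature = .schema_signature(schema)),
            class = "processed_geometry")
}

#' Rigidly align a processed geometry into the anatomical frame
#'
#' Translates S01 to the origin, takes the x axis along S01 to C01 (so C01
#' lands on the +x axis with `y = z = 0`), the y axis as the total
#' least-squares mid-sagittal plane normal (fitted through all
#' midline-flagged landmarks) orthogonalized against x, and z completing a
#' right-handed frame with the landmark centroid at positive z.
#'
#' @param geom A `processed_geometry` from [pair_to_midline()].
#' @param schema A [skull_schema()].
#' @return A list with components `geometry` (the aligned
#'   `processed_geometry`, `transform_applied` set) and `transform` (the
#'   [rigid_transform()] that was applied).
#' @export
align_geometry <- function(geom, schema = skull_schema()) {
  tr <- .rigid_from_landmarks(geom$coords, schema)
  geom$coords <- apply_transform(tr, geom$coords)
  geom$transform_applied <-
    if (is.null(geom$transform_applied)) tr
    else compose_transform(geom$transform_applied, tr)
  list(geometry = geom, transform = tr)
}

#' Assemble per-block geometry matrices
#'
#' Stacks aligned processed geometries into the three analysis matrices: an
#' n x 180 coordinate block (x, y, z per landmark in schema order), an
#' n x 25 thickness block and an n x 32 suture-width block, together with the
#' per-subject feature table.
#'
#' @param geoms List of aligned `processed_geometry` objects.
#' @param features Data frame with one row per geometry (same order),
#'   typically from [feature_table()]; must contain `age` and `cir_offset`.
#' @param schema A [skull_schema()].
#' @return A `geometry_matrices` object: list with `coords` (n x 180),
#'   `thickness` (n x 25), `widths` (n x 32), `subject_ids`, `features`.
#' @export
assemble_matrices <- function(geoms, features, schema = skull_schema()) {
  if (!length(geoms)) stop("insufficient-data error: no geometries")
  sig <- .schema_signature(schema)
  for (g in geoms) {
    if (!identical(g$schema_signature, sig))
      stop("schema error: geometry from a different schema")
    if (is.null(g$transform_applied))
      stop("state error: geometries must be aligned before assembly")
    if (anyNA(g$thickness))
      stop("integrity error: missing thickness entry for subject ",
           g$subject_id)
  }
  if (!is.null(features) && nrow(features) != length(geoms))
    stop("integrity error: feature rows must match geometries")

  labs <- schema_labels(schema)
  coord_cols <- as.vector(t(outer(labs, c("x", "y", "z"), paste, sep = ".")))
  coords <- t(vapply(geoms, function(g) as.vector(t(g$coords[labs, ])),
                     numeric(180)))
  colnames(coords) <- coord_cols
  thickness <- t(vapply(geoms,
                        function(g) g$thickness[schema$thickness_subset],
                        numeric(25)))
  widths <- t(vapply(geoms, function(g) g$widths[schema$pair_map$mid],
                     numeric(32)))
  ids <- vapply(geoms, function(g) as.character(g$subject_id), character(1))
  rownames(coords) <- rownames(thickness) <- rownames(widths) <- ids

  structure(list(coords = coords, thickness = thickness, widths = widths,
                 subject_ids = ids, features = features,
                 schema_signature = sig),
            class = "geometry_matrices")
}

# Split a 180-vector back into a 60 x 3 labelled coordinate matrix.
.vec_to_coords <- function(v, schema) {
  m <- matrix(v, ncol = 3, byrow = TRUE,
              dimnames = list(schema_labels(schema), c("x", "y", "z")))
  m
}
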