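# Newborn template geometry: landmarks laid out on a half-ellipsoidal skull
# shell, with suture curves for the metopic, sagittal, coronal, lambdoid and
# squamosal sutures.  All positions are in mm in the aligned anatomical frame
# (S01 at the origin, mid-sagittal plane y = 0, C01 on the +x axis).

.deg <- pi / 180

# Semi-axes of the newborn shell (mm): anterior-posterior, lateral, vertical.
.ell_axes <- c(58, 47, 47)

.ell_point <- function(theta, phi, ax = .ell_axes) {
  cbind(ax[1] * cos(phi) * cos(theta),
        ax[2] * cos(phi) * sin(theta),
        ax[3] * sin(phi))
}

# Project a point radially (from the shell centre) onto the ellipsoid.
.ell_project <- function(p, ax = .ell_axes) {
  k <- 1 / sqrt(sum((p / ax)^2))
  p * k
}

# Outward surface normal of the ellipsoid at a point on it.
.ell_normal <- function(p, ax = .ell_axes) {
  n <- p / ax^2
  n / sqrt(sum(n^2))
}

# (theta, phi) waypoints of the lateral suture curves, parameterized on [0,1].
.suture_param <- function(suture, t) {
  switch(suture,
    coronal   = cbind(55 * t, 75 - 80 * t),
    lambdoid  = cbind(180 - 55 * t, 38 - 48 * t),
    squamosal = cbind(55 + 70 * t, -5 - 5 * t + 14 * sin(pi * t)),
    stop("unknown suture curve: ", suture)
  )
}

# Internal rich template: landmark positions, suture-pair unit directions and
# the template circumference, all in the aligned frame.
.template_geometry <- function(schema = skull_schema()) {
  ax <- .ell_axes
  midline_curve <- function(alpha) {
    cbind(ax[1] * cos(alpha * .deg), 0, ax[3] * sin(alpha * .deg))
  }

  s_lab <- schema$pair_map$mid
  s_pos <- matrix(NA_real_, 32, 3, dimnames = list(s_lab, c("x", "y", "z")))
  s_dir <- matrix(NA_real_, 32, 3, dimnames = list(s_lab, c("x", "y", "z")))

  # Midline sutures (metopic S01-S06, sagittal S07-S14): pairs straddle the
  # mid-sagittal plane, so the pair direction is +/- y exactly.
  mid_alpha <- c(10, 21, 32, 43, 54, 65, 85, 92, 99, 106, 113, 120, 127, 134)
  s_pos[1:14, ] <- midline_curve(mid_alpha)
  s_dir[1:14, ] <- matrix(c(0, 1, 0), 14, 3, byrow = TRUE)

  lateral <- list(coronal = 15:20, lambdoid = 21:26, squamosal = 27:32)
  for (su in names(lateral)) {
    idx <- lateral[[su]]
    t <- seq_along(idx) / (length(idx) + 1)
    tp <- .suture_param(su, t)
    p <- .ell_point(tp[, 1] * .deg, tp[, 2] * .deg, ax)
    s_pos[idx, ] <- p
    # tangent by finite difference along the curve parameter
    h <- 1e-5
    tp2 <- .suture_param(su, t + h)
    p2 <- .ell_point(tp2[, 1] * .deg, tp2[, 2] * .deg, ax)
    for (k in seq_along(idx)) {
      tg <- p2[k, ] - p[k, ]
      tg <- tg / sqrt(sum(tg^2))
      nr <- .ell_normal(p[k, ], ax)
      d <- c(tg[2] * nr[3] - tg[3] * nr[2],
             tg[3] * nr[1] - tg[1] * nr[3],
             tg[1] * nr[2] - tg[2] * nr[1])
      d <- d / sqrt(sum(d^2))
      if (abs(d[3]) > 1e-6) {
        if (d[3] < 0) d <- -d
      } else if (d[1] < 0) d <- -d
      s_dir[idx[k], ] <- d
    }
  }

  c_pos <- rbind(
    C01 = midline_curve(75)[1, ],
    C02 = midline_curve(142)[1, ],
    C03 = .ell_point(55 * .deg, -5 * .deg, ax)[1, ],
    C04 = .ell_point(125 * .deg, -10 * .deg, ax)[1, ]
  )
  colnames(c_pos) <- c("x", "y", "z")

  # Surface landmarks from the relative-position rules (anchors may be
  # earlier surface landmarks, so apply rules in order).
  known <- rbind(s_pos, c_pos)
  sr <- schema$surface_rules
  b_pos <- matrix(NA_real_, nrow(sr), 3,
                  dimnames = list(sr$label, c("x", "y", "z")))
  for (i in seq_len(nrow(sr))) {
    p1 <- known[sr$anchor1[i], ]
    p2 <- known[sr$anchor2[i], ]
    b_pos[i, ] <- .ell_project((p1 + p2) / 2, ax)
    known <- rbind(known, b_pos[i, , drop = FALSE])
  }

  coords <- rbind(s_pos, b_pos, c_pos)[schema_labels(schema), ]

  # Rigidly map the natural construction frame into the anatomical frame.
  tr <- .rigid_from_landmarks(coords, schema)
  coords <- apply_transform(tr, coords)
  mid <- schema_midline_labels(schema)
  coords[mid, "y"] <- 0  # exact by construction
  s_dir <- s_dir %*% t(tr$rotation)
  s_dir[1:14, ] <- matrix(c(0, 1, 0), 14, 3, byrow = TRUE)

  circ0 <- .polygon_circumference(coords, schema)

  list(schema = schema, coords = coords, pair_dir = s_dir,
       transform = tr, circumference = circ0)
}

.template_cache <- new.env(parent = emptyenv())

.template_default <- function(schema = skull_schema()) {
  key <- .schema_signature(schema)
  if (is.null(.template_cache[[key]]))
    .template_cache[[key]] <- .template_geometry(schema)
  .template_cache[[key]]
}

#' Newborn template landmark set
#'
#' Builds the 92-landmark newborn half-head template: 64 suture-boundary
#' landmarks (32 pairs straddling the suture curves at the requested widths),
#' 24 surface landmarks placed by the schema's relative-position rules and 4
#' suture-convergence landmarks, on a half-ellipsoidal skull shell in the
#' aligned anatomical frame.
#'
#' @param schema A [skull_schema()].
#' @param widths Named or unnamed numeric vector of 32 suture widths (mm),
#'   one per centerline label, used to separate each boundary pair.  Defaults
#'   to the generator's newborn widths.  A width of 0 emits the single
#'   centerline landmark instead of a pair.
#' @param thickness Optional numeric vector of 25 thickness values (mm) for
#'   the schema thickness subset; defaults to the generator's newborn
#'   thickness.
#' @return A `raw_landmark_set` (see [read_landmark_table()]) with
#'   `subject_id = "template"` and `age = 0`.
#' @examples
#' tpl <- newborn_template()
#' nrow(tpl$coords)  # 92
#' @export
newborn_template <- function(schema = skull_schema(), widths = NULL,
                             thickness = NULL) {
  tpl <- .template_default(schema)
  if (is.null(widths)) widths <- default_initial_widths(schema)
  if (is.null(thickness))
    thickness <- .thickness_at_age(default_thickness_params(schema), 0)
  widths <- .as_named32(widths, schema)
  .raw_from_template(tpl, scale = 1, widths = widths, thickness = thickness,
                     subject_id = "template", age = 0)
}

.as_named32 <- function(widths, schema) {
  s_lab <- schema$pair_map$mid
  if (is.null(names(widths))) {
    stopifnot(length(widths) == 32L)
    names(widths) <- s_lab
  }
  widths[s_lab]
}

# Emit a raw landmark set from the template: scaled midline/surface points,
# boundary pairs separated by the given widths (0 => centerline singleton).
.raw_from_template <- function(tpl, scale, widths, thickness, subject_id,
                               age, coord_noise_sd = 0) {
  schema <- tpl$schema
  pm <- schema$pair_map
  base <- tpl$coords * scale

  lab_list <- character(0)
  pts <- NULL
  for (i in seq_len(nrow(pm))) {
    m <- pm$mid[i]
    w <- widths[[m]]
    if (w > 0) {
      d <- tpl$pair_dir[m, ]
      pts <- rbind(pts, base[m, ] + (w / 2) * d, base[m, ] - (w / 2) * d)
      lab_list <- c(lab_list, pm$a[i], pm$b[i])
    } else {
      pts <- rbind(pts, base[m, , drop = FALSE])
      lab_list <- c(lab_list, m)
    }
  }
  other <- schema$labels$label[schema$labels$role != "suture"]
  pts <- rbind(pts, base[other, ])
  lab_list <- c(lab_list, other)
  rownames(pts) <- lab_list
  colnames(pts) <- c("x", "y", "z")

  if (coord_noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, coord_noise_sd),
                        nrow(pts), 3)

  th <- thickness
  names(th) <- schema$thickness_subset

  structure(list(subject_id = subject_id, age = age, circumference = NA_real_,
                 coords = pts, thickness = th),
            class = "raw_landmark_set")
}

#' Reference median head circumference curve
#'
#' Bundled parametric median head-circumference curve, a saturating growth
#' law \eqn{c(a) = c_0 (1 + g (1 - e^{-a/\tau}))} rising from about 35 cm at
#' birth to about 49 cm at 36 months.  It stands in for a population growth
#' reference; the same curve is used by the synthetic generator and by
#' [cir_offset()], so offsets are self-consistent.
#'
#' @param age Age in months; must lie in \[0, 36\].
#' @param params Curve parameters `c(c0, gain, tau)`: newborn circumference
#'   (cm), fractional asymptotic gain, and time constant (months).
#' @return Median circumference in cm (vectorized over `age`).
#' @examples
#' reference_circumference(c(0, 12, 36))
#' @export
reference_circumference <- function(age,
                                    params = c(c0 = 35, gain = 0.411,
                                               tau = 8.2)) {
  if (any(!is.finite(age)) || any(age < 0) || any(age > 36))
    stop("domain error: age must lie in [0, 36] months")
  params[[1]] * (1 + params[[2]] * (1 - exp(-age / params[[3]])))
}
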