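# Head circumference measurement and the CirOffset predictor.  Circumference
# is strongly correlated with age, which destabilizes regression
# coefficients; CirOffset (circumference minus the reference median at the
# subject's age) is the decorrelated size predictor used in the model.

# Perimeter (cm) of the closed polygon through the schema circumference loop,
# mirrored across y = 0 to close the loop on the full head.
.polygon_circumference <- function(coords, schema) {
  loop <- schema$circumference_loop
  missing <- setdiff(loop, rownames(coords))
  if (length(missing))
    stop("integrity error: circumference loop landmarks missing: ",
         paste(missing, collapse = ", "))
  p <- coords[loop, , drop = FALSE]
  m <- nrow(p)
  back <- p[(m - 1):2, , drop = FALSE]
  back[, 2] <- -back[, 2]
  poly <- rbind(p, back)
  edges <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(edges^2))) / 10
}

#' Measure head circumference from an aligned geometry
#'
#' Perimeter of the closed 3D polygon through a fixed, schema-defined loop of
#' landmarks near the maximal axial contour, mirrored across the mid-sagittal
#' plane to close the loop on the full head.  An inscribed polygon slightly
#' underestimates the true contour, but the same loop is used for every
#' subject (and by the synthetic generator's calibration), so the measure is
#' homologous across subjects.
#'
#' @param geom An aligned `processed_geometry`.
#' @param schema A [skull_schema()].
#' @return Circumference in cm.
#' @export
measure_circumference <- function(geom, schema = skull_schema()) {
  .polygon_circumference(geom$coords, schema)
}

#' Circumference offset from the reference median curve
#'
#' `CirOffset = circumference - reference_median(age)`: the subject's head
#' circumference relative to the bundled median growth curve at the same age.
#'
#' @param circumference Head circumference in cm.
#' @param age Age in months, in \[0, 36\].
#' @param params Reference curve parameters (see
#'   [reference_circumference()]).
#' @return Offset in cm (vectorized).
#' @examples
#' cir_offset(reference_circumference(12), 12)  # 0
#' @export
cir_offset <- function(circumference, age,
                       params = c(c0 = 35, gain = 0.411, tau = 8.2)) {
  circumference - reference_circumference(age, params)
}

#' Per-subject feature table
#'
#' Measures circumference for each aligned geometry and derives the
#' regression features (age, CirOffset).
#'
#' @param geoms List of aligned `processed_geometry` objects.
#' @param schema A [skull_schema()].
#' @param curve_params Reference curve parameters.
#' @return Data frame: `subject_id`, `age_months`, `circumference_cm`,
#'   `cir_offset_cm`.
#' @export
feature_table <- function(geoms, schema = skull_schema(),
                          curve_params = c(c0 = 35, gain = 0.411, tau = 8.2)) {
  circ <- vapply(geoms, measure_circumference, numeric(1), schema = schema)
  age <- vapply(geoms, function(g) g$age, numeric(1))
  data.frame(
    subject_id = vapply(geoms, function(g) as.character(g$subject_id),
                        character(1)),
    age_months = age,
    circumference_cm = circ,
    cir_offset_cm = cir_offset(circ, age, curve_params),
    stringsAsFactors = FALSE
  )
}

# Design matrix [1, age, cir_offset] from a feature table.
.feature_design <- function(features) {
  stopifnot(all(c("age_months", "cir_offset_cm") %in% names(features)))
  cbind(intercept = 1, age = features$age_months,
        cir_offset = features$cir_offset_cm)
}
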