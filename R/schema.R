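#' Default half-head landmark schema
#'
#' The homologous landmark layout used throughout the package: 32 suture
#' centerline landmarks (`S01`--`S32`), 24 skull-surface landmarks
#' (`B01`--`B24`) and 4 suture-convergence landmarks (`C01`--`C04`) on one
#' half of the head.  In raw (as-digitized) data each open suture location is
#' represented by a *pair* of boundary landmarks flanking the suture
#' (`S01A`/`S01B`, ...), giving the 92-landmark newborn layout
#' (64 boundary + 24 surface + 4 convergence); a closed suture location is
#' represented by the single centerline label.
#'
#' Midline-flagged labels (the metopic/sagittal centerline `S01`--`S14` and
#' the midline convergences `C01`, `C02`) lie on the mid-sagittal plane and
#' define the `y = 0` plane of the aligned anatomical frame.
#'
#' @return An object of class `landmark_schema`: a list with components
#'   `labels` (data frame: `label`, `role`, `midline`, `region`, `suture`),
#'   `pair_map` (data frame: `mid`, `a`, `b` giving the boundary pair
#'   flanking each centerline label), `surface_rules` (data frame: `label`,
#'   `anchor1`, `anchor2`; each surface landmark sits midway between its two
#'   anchors, projected onto the skull shell), `thickness_subset` (the 25
#'   labels at which skull thickness is recorded) and `circumference_loop`
#'   (the ordered half-loop of labels through which head circumference is
#'   measured).
#' @examples
#' sch <- skull_schema()
#' table(sch$labels$role)
#' @export
skull_schema <- function() {
  s_lab <- sprintf("S%02d", 1:32)
  b_lab <- sprintf("B%02d", 1:24)
  c_lab <- sprintf("C%02d", 1:4)

  suture <- c(
    rep("metopic", 6),    # S01-S06
    rep("sagittal", 8),   # S07-S14
    rep("coronal", 6),    # S15-S20
    rep("lambdoid", 6),   # S21-S26
    rep("squamosal", 6)   # S27-S32
  )
  names(suture) <- s_lab

  b_region <- c(rep("frontal", 6), rep("parietal", 10),
                rep("occipital", 4), rep("temporal", 4))
  s_region <- c(rep("frontal", 6), rep("parietal", 8),
                rep("frontal", 6), rep("occipital", 6), rep("temporal", 6))
  c_region <- c("frontal", "occipital", "temporal", "temporal")

  labels <- data.frame(
    label = c(s_lab, b_lab, c_lab),
    role = c(rep("suture", 32), rep("surface", 24), rep("convergence", 4)),
    midline = c(rep(TRUE, 14), rep(FALSE, 18), rep(FALSE, 24),
                TRUE, TRUE, FALSE, FALSE),
    region = c(s_region, b_region, c_region),
    suture = c(suture, rep(NA_character_, 28)),
    stringsAsFactors = FALSE
  )

  pair_map <- data.frame(
    mid = s_lab,
    a = paste0(s_lab, "A"),
    b = paste0(s_lab, "B"),
    stringsAsFactors = FALSE
  )

  # Each surface landmark lies midway between its two anchors (projected to
  # the skull shell); B12 and B14 follow the layout's worked definitions.
  surface_rules <- data.frame(
    label = b_lab,
    anchor1 = c("S02", "S03", "S04", "S06", "S01", "S05",
                "S08", "S09", "S10", "S11", "S13", "S27",
                "S12", "B12", "S22", "S07",
                "S22", "S23", "S24", "C02",
                "C03", "S29", "S28", "S30"),
    anchor2 = c("S16", "S17", "S18", "S15", "C03", "S20",
                "S16", "S17", "S28", "S29", "S30", "S14",
                "S21", "S14", "S30", "S15",
                "C04", "C04", "S26", "C04",
                "S28", "S31", "S31", "C04"),
    stringsAsFactors = FALSE
  )

  out <- list(
    labels = labels,
    pair_map = pair_map,
    surface_rules = surface_rules,
    thickness_subset = c(b_lab, "C04"),
    circumference_loop = c("S01", "B05", "C03", "B21", "S28", "S30",
                           "B24", "C04", "B18", "B20", "C02")
  )
  class(out) <- "landmark_schema"
  validate_schema(out)
  out
}

#' Validate a landmark schema
#'
#' Checks the structural invariants of a [skull_schema()]-style schema:
#' unique labels, 32 centerline / 24 surface / 4 convergence labels, every
#' centerline label paired with exactly one boundary pair, a 25-label
#' thickness subset, and circumference-loop labels that exist with midline
#' endpoints.
#'
#' @param schema A `landmark_schema` object.
#' @return `schema`, invisibly; stops on violation.
#' @export
validate_schema <- function(schema) {
  lab <- schema$labels
  if (anyDuplicated(lab$label))
    stop("schema error: duplicated labels")
  if (sum(lab$role == "suture") != 32L)
    stop("schema error: expected 32 suture centerline labels")
  if (sum(lab$role == "surface") != 24L)
    stop("schema error: expected 24 surface labels")
  if (sum(lab$role == "convergence") != 4L)
    stop("schema error: expected 4 convergence labels")
  pm <- schema$pair_map
  if (!setequal(pm$mid, lab$label[lab$role == "suture"]))
    stop("schema error: pair map must cover every centerline label")
  bound <- c(pm$a, pm$b)
  if (anyDuplicated(bound))
    stop("schema error: a boundary label occurs in more than one pair")
  if (length(schema$thickness_subset) != 25L)
    stop("schema error: thickness subset must have 25 labels")
  if (!all(schema$thickness_subset %in% lab$label))
    stop("schema error: unknown label in thickness subset")
  loop <- schema$circumference_loop
  if (!all(loop %in% lab$label))
    stop("schema error: unknown label in circumference loop")
  mid <- schema_midline_labels(schema)
  if (!(loop[1] %in% mid && loop[length(loop)] %in% mid))
    stop("schema error: circumference loop must start and end on the midline")
  invisible(schema)
}

#' @rdname skull_schema
#' @param schema A `landmark_schema` object.
#' @return `schema_labels()`: character vector of the 60 processed
#'   (homologous) labels in canonical order; `schema_raw_labels()`: the 92
#'   newborn raw labels; `schema_midline_labels()`: the midline-flagged
#'   labels.
#' @export
schema_labels <- function(schema = skull_schema()) {
  lab <- schema$labels
  c(lab$label[lab$role == "suture"],
    lab$label[lab$role == "surface"],
    lab$label[lab$role == "convergence"])
}

#' @rdname skull_schema
#' @export
schema_raw_labels <- function(schema = skull_schema()) {
  lab <- schema$labels
  c(as.vector(rbind(schema$pair_map$a, schema$pair_map$b)),
    lab$label[lab$role == "surface"],
    lab$label[lab$role == "convergence"])
}

#' @rdname skull_schema
#' @export
schema_midline_labels <- function(schema = skull_schema()) {
  schema$labels$label[schema$labels$midline]
}

# All labels that may legally appear in a raw landmark file: boundary pairs,
# centerline singletons (closed sutures), surface and convergence labels.
.schema_legal_raw <- function(schema) {
  c(schema_raw_labels(schema), schema$pair_map$mid)
}

# Signature used to detect mixed-schema inputs.
.schema_signature <- function(schema) {
  paste(schema_labels(schema), collapse = "|")
}
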