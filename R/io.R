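# Readers/writers for the pipeline's file formats: long-format landmark CSV,
# per-block geometry tables, and the LM3 dialect of the TPS landmark format
# (coordinates only; widths and thickness travel in sidecar CSV tables, since
# TPS has no scalar channels).

#' Read a long-format landmark table
#'
#' Expects columns `subject_id`, `landmark`, `x_mm`, `y_mm`, `z_mm`,
#' `age_months`, and optionally `thickness_mm` and `circumference_cm`.  Each
#' subject becomes one `raw_landmark_set`; open sutures appear as boundary
#' pairs (e.g. `S05A`/`S05B`), closed sutures as the single centerline label.
#'
#' @param path CSV file path.
#' @param schema A [skull_schema()].
#' @return List of `raw_landmark_set` objects (one per subject, in file
#'   order), each a list with `subject_id`, `age`, `circumference`, `coords`
#'   (labelled n x 3 matrix, mm) and `thickness` (named vector, mm).
#' @export
read_landmark_table <- function(path, schema = skull_schema()) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "landmark", "x_mm", "y_mm", "z_mm", "age_months")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("format error: missing required columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("subject_id", "landmark")]))
    stop("integrity error: duplicated (subject, landmark) rows")
  bad <- setdiff(unique(df$landmark), .schema_legal_raw(schema))
  if (length(bad))
    stop("schema error: unknown landmark labels: ",
         paste(bad, collapse = ", "))
  if (!all(is.finite(as.matrix(df[c("x_mm", "y_mm", "z_mm")]))))
    stop("integrity error: non-finite coordinates")

  lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
         function(d) {
           coords <- as.matrix(d[c("x_mm", "y_mm", "z_mm")])
           dimnames(coords) <- list(d$landmark, c("x", "y", "z"))
           th <- NULL
           if ("thickness_mm" %in% names(d)) {
             keep <- !is.na(d$thickness_mm)
             if (any(d$thickness_mm[keep] <= 0))
               stop("integrity error: thickness values must be > 0")
             th <- stats::setNames(d$thickness_mm[keep], d$landmark[keep])
           }
           circ <- if ("circumference_cm" %in% names(d))
             d$circumference_cm[1] else NA_real_
           structure(list(subject_id = d$subject_id[1],
                          age = d$age_months[1],
                          circumference = circ,
                          coords = coords, thickness = th),
                     class = "raw_landmark_set")
         })
}

#' Write raw landmark sets to a long-format CSV
#'
#' Inverse of [read_landmark_table()].
#'
#' @param raws List of `raw_landmark_set` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(raws, path) {
  rows <- lapply(raws, function(r) {
    th <- rep(NA_real_, nrow(r$coords))
    if (!is.null(r$thickness)) {
      idx <- match(names(r$thickness), rownames(r$coords))
      th[idx[!is.na(idx)]] <- r$thickness[!is.na(idx)]
    }
    data.frame(subject_id = r$subject_id, landmark = rownames(r$coords),
               x_mm = r$coords[, 1], y_mm = r$coords[, 2],
               z_mm = r$coords[, 3], age_months = r$age,
               circumference_cm = r$circumference, thickness_mm = th,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write processed geometry tables
#'
#' Emits three CSV tables mirroring the supplementary layout of the study
#' format: landmark coordinates (with age), suture widths and thickness,
#' with a deterministic row and column order.  [read_geometry_tables()]
#' re-reads them.
#'
#' @param geoms List of `processed_geometry` objects sharing one schema.
#' @param dir Output directory (created if needed).
#' @param schema A [skull_schema()].
#' @return Named character vector of the three file paths.
#' @export
write_geometry_tables <- function(geoms, dir, schema = skull_schema()) {
  sig <- .schema_signature(schema)
  for (g in geoms)
    if (!identical(g$schema_signature, sig))
      stop("schema error: geometries use mismatched schemas")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                        cols))
    df
  }
  if (length(geoms)) {
    coords <- do.call(rbind, lapply(geoms, function(g)
      data.frame(subject_id = g$subject_id, age_months = g$age,
                 landmark = rownames(g$coords),
                 x_mm = g$coords[, 1], y_mm = g$coords[, 2],
                 z_mm = g$coords[, 3], stringsAsFactors = FALSE)))
    widths <- do.call(rbind, lapply(geoms, function(g)
      data.frame(subject_id = g$subject_id, landmark = names(g$widths),
                 width_mm = unname(g$widths), stringsAsFactors = FALSE)))
    thick <- do.call(rbind, lapply(geoms, function(g)
      data.frame(subject_id = g$subject_id, landmark = names(g$thickness),
                 thickness_mm = unname(g$thickness),
                 stringsAsFactors = FALSE)))
    rownames(coords) <- rownames(widths) <- rownames(thick) <- NULL
  } else {
    coords <- empty(c("subject_id", "age_months", "landmark", "x_mm", "y_mm",
                      "z_mm"))
    widths <- empty(c("subject_id", "landmark", "width_mm"))
    thick <- empty(c("subject_id", "landmark", "thickness_mm"))
  }
  paths <- c(coordinates = file.path(dir, "landmark_coordinates.csv"),
             widths = file.path(dir, "suture_widths.csv"),
             thickness = file.path(dir, "skull_thickness.csv"))
  utils::write.csv(coords, paths["coordinates"], row.names = FALSE)
  utils::write.csv(widths, paths["widths"], row.names = FALSE)
  utils::write.csv(thick, paths["thickness"], row.names = FALSE)
  paths
}

#' @rdname write_geometry_tables
#' @return `read_geometry_tables()`: list of `processed_geometry` objects.
#'   Geometries read back are marked with an identity transform (the tables
#'   store aligned coordinates).
#' @export
read_geometry_tables <- function(dir, schema = skull_schema()) {
  coords <- utils::read.csv(file.path(dir, "landmark_coordinates.csv"))
  widths <- utils::read.csv(file.path(dir, "suture_widths.csv"))
  thick <- utils::read.csv(file.path(dir, "skull_thickness.csv"))
  ids <- unique(coords$subject_id)
  labs <- schema_labels(schema)
  lapply(ids, function(id) {
    dc <- coords[coords$subject_id == id, ]
    m <- as.matrix(dc[match(labs, dc$landmark), c("x_mm", "y_mm", "z_mm")])
    dimnames(m) <- list(labs, c("x", "y", "z"))
    dw <- widths[widths$subject_id == id, ]
    w <- stats::setNames(dw$width_mm[match(schema$pair_map$mid, dw$landmark)],
                         schema$pair_map$mid)
    dt <- thick[thick$subject_id == id, ]
    th <- stats::setNames(
      dt$thickness_mm[match(schema$thickness_subset, dt$landmark)],
      schema$thickness_subset)
    structure(list(subject_id = id, age = dc$age_months[1],
                   circumference = NA_real_, coords = m, widths = w,
                   thickness = th, transform_applied = rigid_transform(),
                   schema_signature = .schema_signature(schema)),
              class = "processed_geometry")
  })
}

#' TPS (LM3 dialect) reader and writer
#'
#' Interoperability with morphometrics tooling.  Each specimen is a block
#' `LM3=<n>` followed by one `x y z` line per landmark and an `ID=` line.
#' Coordinates only: labels are assigned by schema order (the 60-landmark
#' processed layout), and suture widths/thickness travel in sidecar CSV
#' tables instead.
#'
#' @param geoms List of `processed_geometry` objects (or anything with a
#'   labelled 60 x 3 `coords` matrix).
#' @param path TPS file path.
#' @param schema A [skull_schema()].
#' @return `write_tps()`: `path`, invisibly.  `read_tps()`: list of
#'   specimens, each a list with `subject_id` and `coords` (labelled 60 x 3
#'   matrix).
#' @export
write_tps <- function(geoms, path, schema = skull_schema()) {
  labs <- schema_labels(schema)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geoms) {
    m <- g$coords[labs, , drop = FALSE]
    writeLines(sprintf("LM3=%d", nrow(m)), con)
    writeLines(sprintf("%.9f %.9f %.9f", m[, 1], m[, 2], m[, 3]), con)
    writeLines(paste0("ID=", g$subject_id), con)
  }
  invisible(path)
}

#' @rdname write_tps
#' @export
read_tps <- function(path, schema = skull_schema()) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  labs <- schema_labels(schema)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM3=", lines[i]))
      stop("format error: expected LM3= line at line ", i)
    n <- as.integer(sub("^LM3=", "", lines[i]))
    if (is.na(n)) stop("format error: unparseable LM3 count")
    if (n != length(labs))
      stop("format error: LM3=", n, " but schema defines ", length(labs),
           " landmarks")
    body <- lines[seq(i + 1L, length.out = min(n, length(lines) - i))]
    if (length(body) < n || any(grepl("^(ID=|LM3=)", body)))
      stop("format error: LM3 count disagrees with coordinate rows")
    vals <- do.call(rbind, lapply(strsplit(body, "[ \t]+"), as.numeric))
    if (ncol(vals) != 3L || anyNA(vals))
      stop("format error: expected three numeric coordinates per line")
    i <- i + n + 1L
    id <- if (i <= length(lines) && grepl("^ID=", lines[i])) {
      id0 <- sub("^ID=", "", lines[i]); i <- i + 1L; id0
    } else stop("format error: missing ID= line after coordinates")
    dimnames(vals) <- list(labs, c("x", "y", "z"))
    out[[length(out) + 1L]] <- list(subject_id = id, coords = vals)
  }
  out
}
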