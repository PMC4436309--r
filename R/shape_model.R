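# Statistical skull geometry model: per-block PCA (coordinates, thickness,
# suture widths) retaining 95% of variance, with a multivariate least-squares
# regression of the PC scores on the feature design [1, age, CirOffset].
# Prediction reconstructs each block from the regressed scores and clamps
# negative widths to zero.

#' Fit a PCA block
#'
#' Mean-centered PCA via the singular value decomposition.  Retains the
#' smallest number of components whose cumulative variance reaches
#' `threshold`, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive).  A constant matrix yields `k = 0`
#' with a warning.
#'
#' @param x n x d numeric matrix (n >= 3).
#' @param threshold Fraction of variance to retain, in (0, 1\].
#' @param max_k Optional cap on the number of retained components.
#' @return A `pca_block`: list with `mean` (length d), `basis` (k x d,
#'   orthonormal rows), `eigenvalues` (k component variances),
#'   `variance_fraction_retained`, `total_variance`.
#' @export
fit_pca <- function(x, threshold = 0.95, max_k = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("insufficient-data error: need at least 3 rows")
  if (threshold <= 0 || threshold > 1)
    stop("domain error: threshold must be in (0, 1]")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (total < 1e-24) {
    warning("constant matrix: retaining 0 components")
    return(structure(list(mean = mu, basis = matrix(0, 0, ncol(x)),
                          eigenvalues = numeric(0),
                          variance_fraction_retained = 1, total_variance = 0),
                     class = "pca_block"))
  }
  keep <- ev > 1e-12 * ev[1]
  ev <- ev[keep]
  cum <- cumsum(ev) / total
  k <- which(cum >= threshold)[1]
  if (is.na(k)) k <- length(ev)
  if (!is.null(max_k)) k <- min(k, max_k)
  basis <- t(sv$v[, seq_len(k), drop = FALSE])
  for (j in seq_len(k)) {
    i <- which.max(abs(basis[j, ]))
    if (basis[j, i] < 0) basis[j, ] <- -basis[j, ]
  }
  structure(list(mean = mu, basis = basis, eigenvalues = ev[seq_len(k)],
                 variance_fraction_retained = if (k) cum[k] else 0,
                 total_variance = total),
            class = "pca_block")
}

#' Project to and reconstruct from a PCA block
#'
#' `pca_project()` maps rows into score space (`basis (x - mean)`);
#' `pca_reconstruct()` maps scores back (`mean + t(basis) s`).
#'
#' @param block A `pca_block` from [fit_pca()].
#' @param x Vector of length d, or an n x d matrix.
#' @param scores Vector of length k, or an n x k matrix.
#' @return Scores (length k / n x k) or reconstructed rows (length d /
#'   n x d).
#' @export
pca_project <- function(block, x) {
  d <- length(block$mean)
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("dimension error: expected ", d, " columns")
    sweep(x, 2, block$mean) %*% t(block$basis)
  } else {
    if (length(x) != d) stop("dimension error: expected length ", d)
    as.vector(block$basis %*% (x - block$mean))
  }
}

#' @rdname pca_project
#' @export
pca_reconstruct <- function(block, scores) {
  k <- nrow(block$basis)
  if (is.matrix(scores)) {
    if (ncol(scores) != k) stop("dimension error: expected ", k, " columns")
    sweep(scores %*% block$basis, 2, block$mean, "+")
  } else {
    if (length(scores) != k) stop("dimension error: expected length ", k)
    block$mean + as.vector(t(block$basis) %*% scores)
  }
}

#' Regress PC scores on the feature design
#'
#' Column-wise ordinary least squares of the n x k score matrix on the n x p
#' design (intercept, age, CirOffset), yielding the k x p coefficient matrix
#' and per-component residual SDs.  A rank-deficient design (e.g. using raw
#' circumference together with age, which are strongly collinear) is an
#' error naming the offending columns.
#'
#' @param scores n x k PC score matrix.
#' @param design n x p design matrix (should include an intercept column).
#' @return A `regression_block`: list with `C` (k x p), `residual_sd`
#'   (length k), `df_residual`.
#' @export
fit_score_regression <- function(scores, design) {
  scores <- as.matrix(scores)
  design <- as.matrix(design)
  n <- nrow(design)
  p <- ncol(design)
  if (nrow(scores) != n) stop("dimension error: rows of scores and design differ")
  if (n <= p) stop("insufficient-data error: need n > p")
  qx <- qr(design)
  if (qx$rank < p) {
    bad <- colnames(design)[qx$pivot[seq(qx$rank + 1L, p)]]
    if (is.null(bad)) bad <- paste0("column ", qx$pivot[seq(qx$rank + 1L, p)])
    stop("collinearity error: design is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, scores)
  res <- scores - design %*% coef
  rsd <- sqrt(colSums(res^2) / (n - p))
  structure(list(C = t(coef), residual_sd = unname(rsd),
                 df_residual = n - p),
            class = "regression_block")
}

#' Fit the statistical skull geometry model
#'
#' Fits three independent (PCA, regression) block pairs -- landmark
#' coordinates (n x 180), skull thickness (n x 25) and suture widths
#' (n x 32) -- each retaining at least `threshold` of the variance, and
#' regresses the PC scores of each block on \[1, age, CirOffset\].  The
#' number of retained components is capped at `n - p - 1` so every
#' regression stays overdetermined.
#'
#' @param mats A `geometry_matrices` object from [assemble_matrices()] (or
#'   [preprocess_cohort()]).
#' @param threshold PCA variance-retention fraction (default 0.95).
#' @param curve_params Reference circumference curve parameters, stored with
#'   the model so predictions at percentile offsets stay self-consistent.
#' @param schema A [skull_schema()].
#' @return A `skull_geometry_model`: list with `blocks` (named list
#'   `coords`/`thickness`/`widths`, each `list(pca, regression)`),
#'   `curve_params`, `fit` metadata (`n`, `threshold`, `age_range`).
#' @export
fit_skull_model <- function(mats, threshold = 0.95,
                            curve_params = c(c0 = 35, gain = 0.411,
                                             tau = 8.2),
                            schema = skull_schema()) {
  design <- .feature_design(mats$features)
  n <- nrow(design)
  p <- ncol(design)
  if (n < p + 2) stop("insufficient-data error: need at least p + 2 subjects")
  max_k <- n - p - 1
  fit_block <- function(x) {
    pca <- fit_pca(x, threshold, max_k = max_k)
    scores <- pca_project(pca, x)
    reg <- if (ncol(scores))
      fit_score_regression(scores, design)
    else structure(list(C = matrix(0, 0, p), residual_sd = numeric(0),
                        df_residual = n - p), class = "regression_block")
    list(pca = pca, regression = reg)
  }
  structure(list(
    blocks = list(coords = fit_block(mats$coords),
                  thickness = fit_block(mats$thickness),
                  widths = fit_block(mats$widths)),
    curve_params = curve_params,
    fit = list(n = n, threshold = threshold,
               age_range = range(mats$features$age_months)),
    schema_signature = .schema_signature(schema)),
    class = "skull_geometry_model")
}

#' Predict skull geometry for given age and circumference offset
#'
#' Evaluates `scores = C f` with `f = (1, age, cir_offset)` for each block
#' and reconstructs landmark coordinates, thickness and suture widths.
#' Negative predicted widths are amended to 0; thickness is floored at
#' 0.1 mm (it must stay positive for downstream meshing).  Ages outside the
#' fitted range trigger a warning, not an error.
#'
#' @param object A `skull_geometry_model`.
#' @param age Age in months.
#' @param cir_offset Circumference offset in cm (default 0, the median
#'   head).
#' @param thickness_floor Lower clamp for predicted thickness (mm).
#' @param schema A [skull_schema()].
#' @param ... Unused.
#' @return A `predicted_geometry`: list with `coords` (60 x 3 labelled
#'   matrix), `widths` (named, >= 0), `thickness` (named), `features`.
#' @export
predict.skull_geometry_model <- function(object, age, cir_offset = 0,
                                         thickness_floor = 0.1,
                                         schema = skull_schema(), ...) {
  if (!is.finite(age) || !is.finite(cir_offset))
    stop("domain error: non-finite features")
  rng <- object$fit$age_range
  if (age < rng[1] - 1e-9 || age > rng[2] + 1e-9)
    warning("extrapolating outside the fitted age range [",
            signif(rng[1], 3), ", ", signif(rng[2], 3), "] months")
  f <- c(1, age, cir_offset)
  recon <- function(blk) {
    pca_reconstruct(blk$pca, as.vector(blk$regression$C %*% f))
  }
  coords <- .vec_to_coords(recon(object$blocks$coords), schema)
  widths <- pmax(recon(object$blocks$widths), 0)
  names(widths) <- schema$pair_map$mid
  thickness <- pmax(recon(object$blocks$thickness), thickness_floor)
  names(thickness) <- schema$thickness_subset
  structure(list(coords = coords, widths = widths, thickness = thickness,
                 features = c(age = age, cir_offset = cir_offset)),
            class = "predicted_geometry")
}

#' Validate a model against held-out subjects
#'
#' Predicts each held-out subject from its age and measured circumference
#' offset and summarizes the signed landmark coordinate errors
#' (predicted - observed) per axis, pooled over landmarks and subjects.
#'
#' @param model A `skull_geometry_model`.
#' @param geoms List of aligned `processed_geometry` holdout subjects
#'   (aligned with the same procedure as the training set).
#' @param schema A [skull_schema()].
#' @return A `geometry_error_summary`: list with `per_axis` (data frame
#'   `axis`, `mean`, `sd` in mm) and `per_subject` (data frame of subject
#'   mean errors per axis).
#' @export
validate_model <- function(model, geoms, schema = skull_schema()) {
  if (!length(geoms)) stop("domain error: empty holdout set")
  feats <- feature_table(geoms, schema, model$curve_params)
  errs <- vector("list", length(geoms))
  for (i in seq_along(geoms)) {
    pred <- suppressWarnings(
      predict(model, feats$age_months[i], feats$cir_offset_cm[i],
              schema = schema))
    errs[[i]] <- pred$coords - geoms[[i]]$coords[rownames(pred$coords), ]
  }
  pooled <- do.call(rbind, errs)
  per_axis <- data.frame(axis = c("x", "y", "z"),
                         mean = colMeans(pooled),
                         sd = apply(pooled, 2, stats::sd),
                         row.names = NULL)
  per_subject <- data.frame(subject_id = feats$subject_id,
                            t(vapply(errs, colMeans, numeric(3))),
                            row.names = NULL)
  names(per_subject)[2:4] <- c("mean_x", "mean_y", "mean_z")
  structure(list(per_axis = per_axis, per_subject = per_subject),
            class = "geometry_error_summary")
}

# ---- serialization -------------------------------------------------------

# Doubles are stored as %.17g decimal strings so the JSON round trip
# reproduces every value bit for bit (15-digit JSON numbers would not).
.num_out <- function(x) sprintf("%.17g", as.numeric(x))
.num_in <- function(x) as.numeric(x)
.mat_to_list <- function(m) list(dim = dim(m), data = .num_out(as.vector(m)))
.list_to_mat <- function(l) matrix(.num_in(l$data), l$dim[1], l$dim[2])

#' Save / load a fitted skull geometry model
#'
#' Versioned JSON serialization (full double precision); the round trip
#' preserves predictions exactly.
#'
#' @param model A `skull_geometry_model`.
#' @param path JSON file path.
#' @return `save_skull_model()`: `path`, invisibly; `load_skull_model()`:
#'   the model.
#' @export
save_skull_model <- function(model, path) {
  blk <- function(b) list(
    pca = list(mean = .num_out(b$pca$mean), basis = .mat_to_list(b$pca$basis),
               eigenvalues = .num_out(b$pca$eigenvalues),
               variance_fraction_retained =
                 .num_out(b$pca$variance_fraction_retained),
               total_variance = .num_out(b$pca$total_variance)),
    regression = list(C = .mat_to_list(b$regression$C),
                      residual_sd = .num_out(b$regression$residual_sd),
                      df_residual = b$regression$df_residual))
  payload <- list(format = "skullgeom-model", version = 1L,
                  blocks = lapply(model$blocks, blk),
                  curve_params = as.list(stats::setNames(
                    .num_out(model$curve_params), names(model$curve_params))),
                  fit = list(n = model$fit$n,
                             threshold = .num_out(model$fit$threshold),
                             age_range = .num_out(model$fit$age_range)),
                  schema_signature = model$schema_signature)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_skull_model
#' @export
load_skull_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "skullgeom-model"))
    stop("format error: not a skullgeom model file")
  blk <- function(b) list(
    pca = structure(list(mean = .num_in(b$pca$mean),
                         basis = .list_to_mat(b$pca$basis),
                         eigenvalues = .num_in(b$pca$eigenvalues),
                         variance_fraction_retained =
                           .num_in(b$pca$variance_fraction_retained),
                         total_variance = .num_in(b$pca$total_variance)),
                    class = "pca_block"),
    regression = structure(list(C = .list_to_mat(b$regression$C),
                                residual_sd =
                                  .num_in(b$regression$residual_sd),
                                df_residual = b$regression$df_residual),
                           class = "regression_block"))
  cp <- vapply(p$curve_params, .num_in, numeric(1))
  structure(list(blocks = lapply(p$blocks, blk),
                 curve_params = cp,
                 fit = list(n = p$fit$n, threshold = .num_in(p$fit$threshold),
                            age_range = .num_in(p$fit$age_range)),
                 schema_signature = p$schema_signature),
            class = "skull_geometry_model")
}
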