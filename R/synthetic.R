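# Synthetic cohort generator.  Emulates the statistical structure the
# analysis assumes: ages 0-36 months, circumference tracking the reference
# median curve plus a subject offset, location-dependent suture closure (all
# sutures closed by 24 months) and location-dependent thickness growth
# (occipital thicker than frontal/parietal).

#' Default suture closure ages, newborn widths and thickness growth
#'
#' Closure ages (months at which the pre-noise width reaches 0) follow the
#' closure sequence seen clinically and radiologically: the squamosal suture
#' closes first (~7 months), the inferior coronal and lambdoid and the
#' metopic next (~12), the remaining coronal/lambdoid and mid-sagittal
#' (~14-18), and the sagittal segment behind the anterior fontanel last
#' (22-24 months).  Newborn widths are a few mm, widest next to the
#' fontanels.  Thickness grows linearly with age, with larger intercepts and
#' slopes in the occipital region than frontally/parietally.
#'
#' @param schema A [skull_schema()].
#' @return `default_closure_ages()`: named length-32 vector (months);
#'   `default_initial_widths()`: named length-32 vector (mm);
#'   `default_thickness_params()`: data frame `label`, `intercept` (mm),
#'   `slope` (mm/month) for the 25 thickness labels.
#' @export
default_closure_ages <- function(schema = skull_schema()) {
  s_lab <- schema$pair_map$mid
  cl <- c(
    rep(12, 6),                      # metopic S01-S06
    24, 22, 18, 18, 18, 14, 14, 14,  # sagittal S07-S14 (S07 last to close)
    18, 18, 18, 18, 12, 12,          # coronal S15-S20 (inferior earlier)
    18, 18, 18, 18, 12, 12,          # lambdoid S21-S26
    rep(7, 6)                        # squamosal S27-S32
  )
  stats::setNames(cl, s_lab)
}

#' @rdname default_closure_ages
#' @export
default_initial_widths <- function(schema = skull_schema()) {
  s_lab <- schema$pair_map$mid
  w0 <- c(
    3.5, 3.0, 2.5, 2.5, 3.0, 4.0,            # metopic
    5.0, 4.0, 3.0, 3.0, 3.0, 3.0, 3.5, 4.0,  # sagittal
    4.0, 3.0, 3.0, 3.0, 3.0, 3.0,            # coronal
    3.0, 3.0, 3.0, 3.0, 3.0, 3.0,            # lambdoid
    rep(2.0, 6)                              # squamosal
  )
  stats::setNames(w0, s_lab)
}

#' @rdname default_closure_ages
#' @export
default_thickness_params <- function(schema = skull_schema()) {
  labs <- schema$thickness_subset
  region <- schema$labels$region[match(labs, schema$labels$label)]
  intercept <- c(frontal = 1.2, parietal = 1.3, occipital = 1.9,
                 temporal = 1.1)[region]
  slope <- c(frontal = 0.055, parietal = 0.060, occipital = 0.075,
             temporal = 0.050)[region]
  data.frame(label = labs, region = region,
             intercept = unname(intercept), slope = unname(slope),
             stringsAsFactors = FALSE)
}

.thickness_at_age <- function(params, age) {
  stats::setNames(params$intercept + params$slope * age, params$label)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_subjects Number of subjects (default 56, the study-sized cohort).
#' @param age_sampler Function of `n` returning ages in months; default
#'   uniform on \[0, 36\].
#' @param cir_offset_sd SD (cm) of the Normal circumference offsets around
#'   the reference median curve.
#' @param growth_params Reference curve parameters
#'   (see [reference_circumference()]); the skull is scaled so its measured
#'   circumference equals the curve value at the subject's age plus the
#'   subject's offset.
#' @param closure_ages,initial_widths,thickness_params Suture closure and
#'   thickness growth laws (see [default_closure_ages()]).
#' @param noise_sd Length-3 vector `c(coord, width, thickness)` of Gaussian
#'   measurement-noise SDs (mm).  In `"model_based"` mode the first entry is
#'   the residual SD of the PC scores.
#' @param seed Integer seed controlling all randomness in [sample_cohort()].
#' @param mode `"mechanistic"` (growth/closure laws above) or `"model_based"`
#'   (geometries drawn exactly from a known linear-Gaussian shape model, for
#'   sharp parameter-recovery tests).
#' @param schema A [skull_schema()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 56,
                        age_sampler = function(n) stats::runif(n, 0, 36),
                        cir_offset_sd = 1.2,
                        growth_params = c(c0 = 35, gain = 0.411, tau = 8.2),
                        closure_ages = default_closure_ages(schema),
                        initial_widths = default_initial_widths(schema),
                        thickness_params = default_thickness_params(schema),
                        noise_sd = c(coord = 0.5, width = 0.15,
                                     thickness = 0.08),
                        seed = 1L,
                        mode = c("mechanistic", "model_based"),
                        schema = skull_schema()) {
  mode <- match.arg(mode)
  if (any(noise_sd < 0) || cir_offset_sd < 0)
    stop("invalid spec: standard deviations must be >= 0")
  if (any(closure_ages > 24))
    stop("invalid spec: all closure ages must be <= 24 months")
  if (any(closure_ages <= 0) || any(initial_widths <= 0))
    stop("invalid spec: closure ages and initial widths must be positive")
  tp <- thickness_params
  occ <- mean(tp$intercept[tp$region == "occipital"])
  if (occ <= mean(tp$intercept[tp$region == "frontal"]) ||
      occ <= mean(tp$intercept[tp$region == "parietal"]))
    stop("invalid spec: occipital thickness intercept must exceed frontal and parietal")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_sampler = age_sampler,
                 cir_offset_sd = cir_offset_sd,
                 growth_params = growth_params,
                 closure_ages = closure_ages,
                 initial_widths = initial_widths,
                 thickness_params = thickness_params,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 mode = mode, schema = schema),
            class = "cohort_spec")
}

# Pre-noise width law: linear decline to zero at the closure age.
.width_at_age <- function(spec, age) {
  w <- pmax(0, spec$initial_widths * (1 - age / spec$closure_ages))
  stats::setNames(as.numeric(w), names(spec$initial_widths))
}

#' Sample one synthetic subject
#'
#' Mechanistic mode: the newborn template is scaled so its measured
#' circumference equals `reference_median(age) + cir_offset` (a saturating
#' growth law, since the reference curve saturates); suture pairs are
#' separated by the width law `max(0, w0 (1 - age/closure))` plus noise, with
#' fully closed sutures emitted as single centerline landmarks; thickness is
#' `intercept + slope * age` plus noise.  Uses the current RNG state (callers
#' seed it; [sample_cohort()] does so from `spec$seed`).
#'
#' @param spec A [cohort_spec()].
#' @param age Age in months (>= 0).
#' @param cir_offset Circumference offset in cm.
#' @param subject_id Identifier for the emitted set.
#' @return A `raw_landmark_set`, with a `truth` attribute recording the true
#'   scale, widths and thickness.
#' @export
sample_subject <- function(spec, age, cir_offset = 0,
                           subject_id = "synthetic") {
  if (!is.finite(age) || age < 0)
    stop("domain error: age must be a non-negative number of months")
  tpl <- .template_default(spec$schema)
  target <- reference_circumference(min(age, 36), spec$growth_params) +
    cir_offset
  s <- target / tpl$circumference

  w_true <- .width_at_age(spec, age)
  w <- w_true
  open <- w_true > 0
  if (any(open) && spec$noise_sd[[2]] > 0)
    w[open] <- pmax(w_true[open] +
                      stats::rnorm(sum(open), 0, spec$noise_sd[[2]]), 0.05)

  th_true <- .thickness_at_age(spec$thickness_params, age)
  th <- pmax(th_true + stats::rnorm(length(th_true), 0, spec$noise_sd[[3]]),
             0.05)

  raw <- .raw_from_template(tpl, scale = s, widths = w, thickness = th,
                            subject_id = subject_id, age = age,
                            coord_noise_sd = spec$noise_sd[[1]])
  attr(raw, "truth") <- list(scale = s, circumference = target,
                             widths = w, thickness = th)
  raw
}

# Linear-Gaussian truth model for "model_based" cohorts: orthonormal modes
# with known coefficient matrices, chosen so that every generated geometry
# already satisfies the alignment frame constraints exactly and widths stay
# well above the 0.5 mm zeroing threshold.
.true_linear_model <- function(spec) {
  tpl <- .template_default(spec$schema)
  labs <- schema_labels(spec$schema)
  mean_c <- as.vector(t(tpl$coords[labs, ]))
  d <- length(mean_c)

  v1 <- mean_c
  v2 <- numeric(d); v2[seq(1, d, 3)] <- mean_c[seq(1, d, 3)]  # x stretch
  v3 <- numeric(d); v3[seq(3, d, 3)] <- mean_c[seq(3, d, 3)]  # z stretch
  basis_c <- qr.Q(qr(cbind(v1, v2, v3)))
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:3) if (basis_c[which.max(abs(basis_c[, j])), j] < 0)
    basis_c[, j] <- -basis_c[, j]
  nrmc <- sqrt(sum(mean_c^2))
  C_c <- rbind(c(0, 0.010 * nrmc, 0.028 * nrmc),
               c(0, 0.0020 * nrmc, 0.004 * nrmc),
               c(0, 0.0015 * nrmc, 0.003 * nrmc))

  mean_w <- 1.5 + spec$initial_widths / 2
  basis_w <- cbind(rep(1, 32) / sqrt(32),
                   qr.Q(qr(cbind(rep(1, 32), seq_len(32))))[, 2])
  C_w <- rbind(c(0, -0.030, 0.15), c(0, -0.008, 0.03))

  mean_t <- .thickness_at_age(spec$thickness_params, 0) + 1
  basis_t <- matrix(rep(1, 25) / 5, ncol = 1)
  C_t <- rbind(c(0, 0.30, 0.25))

  list(template = tpl,
       coords = list(mean = mean_c, basis = t(basis_c), C = C_c),
       widths = list(mean = unname(mean_w), basis = t(basis_w), C = C_w),
       thickness = list(mean = unname(mean_t), basis = t(basis_t), C = C_t))
}

.sample_model_based <- function(spec, age, cir_offset, subject_id, truth_model,
                                score_sd) {
  f <- c(1, age, cir_offset)
  blk <- function(b) {
    k <- nrow(b$C)
    sc <- as.vector(b$C %*% f)
    if (score_sd > 0) sc <- sc + stats::rnorm(k, 0, score_sd)
    list(value = b$mean + as.vector(t(b$basis) %*% sc), scores = sc)
  }
  co <- blk(truth_model$coords)
  wi <- blk(truth_model$widths)
  th <- blk(truth_model$thickness)
  widths <- pmax(wi$value, 0)
  names(widths) <- spec$schema$pair_map$mid
  coords60 <- .vec_to_coords(co$value, spec$schema)

  tpl <- truth_model$template
  tpl_mb <- tpl
  tpl_mb$coords <- coords60
  raw <- .raw_from_template(tpl_mb, scale = 1, widths = widths,
                            thickness = th$value, subject_id = subject_id,
                            age = age, coord_noise_sd = 0)
  attr(raw, "truth") <- list(scores = list(coords = co$scores,
                                           widths = wi$scores,
                                           thickness = th$scores),
                             coords = co$value, widths = widths,
                             thickness = th$value)
  raw
}

#' Sample a synthetic cohort
#'
#' Draws `n_subjects` ages from the spec's age sampler and circumference
#' offsets from Normal(0, `cir_offset_sd`), then generates each subject with
#' [sample_subject()] (mechanistic mode) or from the known linear-Gaussian
#' shape model (model_based mode).  All randomness derives from `spec$seed`;
#' the caller's RNG state is restored afterwards.
#'
#' @param spec A [cohort_spec()].
#' @param id_prefix Prefix for subject identifiers.
#' @return A `skull_cohort`: list with `subjects` (list of
#'   `raw_landmark_set`), `truth` (data frame of true ages, offsets, scales
#'   plus per-subject truth records as the attribute `records`; in
#'   model_based mode also the `model` truth object) and `spec`.
#' @export
sample_cohort <- function(spec, id_prefix = "subj") {
  if (spec$n_subjects < 3)
    stop("insufficient-data error: need at least 3 subjects")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_subjects
  ages <- spec$age_sampler(n)
  offsets <- if (spec$cir_offset_sd > 0)
    stats::rnorm(n, 0, spec$cir_offset_sd) else rep(0, n)
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))

  truth_model <- if (spec$mode == "model_based") .true_linear_model(spec)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- if (spec$mode == "mechanistic")
      sample_subject(spec, ages[i], offsets[i], ids[i])
    else
      .sample_model_based(spec, ages[i], offsets[i], ids[i], truth_model,
                          score_sd = spec$noise_sd[[1]])
  }

  truth <- data.frame(subject_id = ids, age = ages, cir_offset = offsets,
                      stringsAsFactors = FALSE)
  attr(truth, "records") <- lapply(subjects, attr, "truth")
  structure(list(subjects = subjects, truth = truth, spec = spec,
                 model = truth_model),
            class = "skull_cohort")
}

#' Preprocess a whole cohort
#'
#' Convenience wrapper: reprocesses pairs to centerline + width, aligns every
#' subject, and computes the feature table.
#'
#' @param cohort A `skull_cohort` (or plain list of `raw_landmark_set`).
#' @param schema A [skull_schema()].
#' @param curve_params Reference curve parameters for [cir_offset()].
#' @return List with `geometries` (aligned `processed_geometry` list),
#'   `features` (see [feature_table()]) and `matrices`
#'   (see [assemble_matrices()]).
#' @export
preprocess_cohort <- function(cohort, schema = skull_schema(),
                              curve_params = c(c0 = 35, gain = 0.411,
                                               tau = 8.2)) {
  raws <- if (inherits(cohort, "skull_cohort")) cohort$subjects else cohort
  geoms <- lapply(raws, function(r) {
    align_geometry(pair_to_midline(r, schema), schema)$geometry
  })
  features <- feature_table(geoms, schema, curve_params)
  # In model_based cohorts the covariates ARE the generator's features: the
  # scores are exactly linear in (age, offset), whereas an offset re-derived
  # from the measured circumference relates to them through the nonlinear
  # reference curve and would break the exact linear-Gaussian structure.
  if (inherits(cohort, "skull_cohort") &&
      identical(cohort$spec$mode, "model_based"))
    features$cir_offset_cm <- cohort$truth$cir_offset
  list(geometries = geoms, features = features,
       matrices = assemble_matrices(geoms, features, schema))
}
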