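# Shared fixture builders (everything is generated in code at test time).

default_schema <- skull_schema()

# Small preprocessed mechanistic cohort, cached per (n, seed) within a run.
.cohort_cache <- new.env(parent = emptyenv())
fixture_cohort <- function(n = 20, seed = 7, mode = "mechanistic",
                           noise_sd = c(coord = 0.5, width = 0.15,
                                        thickness = 0.08)) {
  key <- paste(n, seed, mode, paste(noise_sd, collapse = ","), sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    spec <- cohort_spec(n_subjects = n, seed = seed, mode = mode,
                        noise_sd = noise_sd)
    co <- sample_cohort(spec)
    .cohort_cache[[key]] <- list(cohort = co, pp = preprocess_cohort(co))
  }
  .cohort_cache[[key]]
}

# Balanced long table: n_sub subjects x landmark levels, subject-level age
# and circumference covariates, random-intercept + noise response plus an
# optional fixed age effect.
balanced_long_table <- function(n_sub, landmarks, age_beta = 0,
                                subject_sd = 1, resid_sd = 1,
                                landmark_effects = NULL) {
  ids <- sprintf("s%03d", seq_len(n_sub))
  d <- expand.grid(subject_id = ids, landmark = factor(landmarks),
                   stringsAsFactors = FALSE)
  ages <- stats::setNames(stats::runif(n_sub, 0, 36), ids)
  circ <- stats::setNames(reference_circumference(ages) +
                            stats::rnorm(n_sub, 0, 1.2), ids)
  u <- stats::setNames(stats::rnorm(n_sub, 0, subject_sd), ids)
  d$age <- ages[as.character(d$subject_id)]
  d$circumference <- circ[as.character(d$subject_id)]
  lm_eff <- if (is.null(landmark_effects)) rep(0, length(landmarks))
            else landmark_effects
  names(lm_eff) <- landmarks
  d$y <- 3 + age_beta * d$age + lm_eff[as.character(d$landmark)] +
    u[as.character(d$subject_id)] + stats::rnorm(nrow(d), 0, resid_sd)
  d
}
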