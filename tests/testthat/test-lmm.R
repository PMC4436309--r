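test_that("the profiled REML fit matches lme4 on an unbalanced design", {
  skip_if_not_installed("lme4")
  set.seed(5)
  d <- balanced_long_table(20, sprintf("L%d", 1:6), age_beta = 0.1,
                           subject_sd = 1.5, resid_sd = 0.7,
                           landmark_effects = seq(0, 2.5, length.out = 6))
  d <- d[-c(3, 40, 77), ]  # unbalance it
  f <- fit_lmm(y ~ landmark + age, d)
  lf <- lme4::lmer(y ~ landmark + age + (1 | subject_id), d, REML = TRUE,
                   contrasts = list(landmark = "contr.sum"))
  expect_equal(unname(f$coefficients), unname(lme4::fixef(lf)),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$sigma2_subject, vc$vcov[1], tolerance = 1e-3)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(f$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)

  fm <- fit_lmm(y ~ landmark + age, d, reml = FALSE)
  lfm <- lme4::lmer(y ~ landmark + age + (1 | subject_id), d, REML = FALSE,
                    contrasts = list(landmark = "contr.sum"))
  expect_equal(fm$logLik, as.numeric(stats::logLik(lfm)), tolerance = 1e-6)
  expect_equal(fm$AIC, stats::AIC(lfm), tolerance = 1e-5)
})

test_that("balanced designs reproduce the subject-means GLS closed form", {
  set.seed(12)
  d <- balanced_long_table(24, sprintf("L%d", 1:5), age_beta = 0.05)
  f <- fit_lmm(y ~ landmark + age + circumference, d)
  # closed form for between-subject effects: OLS on subject means
  ym <- tapply(d$y, d$subject_id, mean)
  ages <- tapply(d$age, d$subject_id, mean)[names(ym)]
  circ <- tapply(d$circumference, d$subject_id, mean)[names(ym)]
  sm <- stats::lm(ym ~ ages + circ)
  expect_equal(unname(f$coefficients["age"]), unname(coef(sm)[2]),
               tolerance = 1e-8)
  expect_equal(unname(f$coefficients["circumference"]), unname(coef(sm)[3]),
               tolerance = 1e-8)
  # the between-subject F matches the subject-means F exactly
  at <- anova(f)
  expect_equal(at$F_value[at$effect == "age"],
               unname(summary(sm)$coefficients[2, 3]^2), tolerance = 1e-6)
})

test_that("noise-free fixed effects are recovered and null variance shrinks", {
  set.seed(3)
  d <- balanced_long_table(12, sprintf("L%d", 1:4), age_beta = 0.2,
                           subject_sd = 0, resid_sd = 0,
                           landmark_effects = c(0, 1, 2, 3))
  f <- fit_lmm(y ~ landmark + age, d)
  expect_equal(unname(f$coefficients["age"]), 0.2, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["(Intercept)"]), 3 + 1.5,
               tolerance = 1e-6)

  # zero between-subject variance in truth: the REML estimate is zero or
  # within sampling noise of zero.  Under the null sigma2_subject is
  # max(0, (MS_B - MS_W) / m) with sd(MS_B) ~ sigma_e^2 sqrt(2 / n_sub), so
  # a 3-sigma bound at n_sub = 50, m = 32 landmarks is 3 * sqrt(2/50)/32.
  set.seed(14)
  d0 <- balanced_long_table(50, sprintf("L%02d", 1:32), subject_sd = 0,
                            resid_sd = 1)
  f0 <- fit_lmm(y ~ landmark + age, d0)
  expect_lt(f0$sigma2_subject, 3 * sqrt(2 / 50) / 32)

  expect_error(fit_lmm(y ~ age, d[d$subject_id == "s001", ]), "design error")
})

test_that("containment DF reproduces the study design degrees of freedom", {
  sch <- default_schema
  set.seed(1)
  ds <- balanced_long_table(56, sch$pair_map$mid)
  names(ds)[names(ds) == "y"] <- "width"
  fs <- fit_lmm(width ~ landmark + age + circumference + age:landmark +
                  circumference:landmark + age:circumference, ds)
  at <- anova(fs)
  get <- function(eff, col) at[[col]][at$effect == eff]
  expect_identical(get("age", "den_df"), 52L)
  expect_identical(get("circumference", "den_df"), 52L)
  expect_identical(get("age:circumference", "den_df"), 52L)
  expect_identical(get("landmark", "den_df"), 1643L)
  expect_identical(get("landmark:age", "den_df"), 1643L)
  expect_identical(get("landmark:circumference", "den_df"), 1643L)
  expect_identical(get("landmark", "num_df"), 31L)

  b_lab <- sch$labels$label[sch$labels$role == "surface"]
  set.seed(2)
  dt <- balanced_long_table(56, b_lab)
  names(dt)[names(dt) == "y"] <- "thickness"
  ft <- fit_lmm(thickness ~ landmark + age + circumference + age:landmark +
                  circumference:landmark, dt)
  att <- anova(ft)
  gett <- function(eff, col) att[[col]][att$effect == eff]
  expect_identical(gett("age", "den_df"), 53L)
  expect_identical(gett("circumference", "den_df"), 53L)
  expect_identical(gett("landmark", "den_df"), 1219L)
  expect_identical(gett("landmark:age", "den_df"), 1219L)
  expect_identical(gett("landmark", "num_df"), 23L)
})

test_that("with zero subject variance the F values reduce to fixed-model ANOVA", {
  skip_if_not_installed("car")
  set.seed(23)
  d <- balanced_long_table(15, sprintf("L%d", 1:4), age_beta = 0.05,
                           subject_sd = 0, resid_sd = 1,
                           landmark_effects = c(0, 0.5, 1, 1.5))
  f <- fit_lmm(y ~ landmark + age, d)
  if (f$lambda == 0) {
    lmfit <- stats::lm(y ~ landmark + age, d,
                       contrasts = list(landmark = "contr.sum"))
    ca <- car::Anova(lmfit, type = 3)
    at <- anova(f)
    expect_equal(at$F_value[at$effect == "landmark"], ca["landmark", "F value"],
                 tolerance = 1e-6)
    expect_equal(at$F_value[at$effect == "age"], ca["age", "F value"],
                 tolerance = 1e-6)
  } else {
    succeed("variance ratio not truncated at zero for this draw")
  }
})

test_that("REML estimates are invariant to response mean shifts", {
  set.seed(8)
  d <- balanced_long_table(15, sprintf("L%d", 1:4), age_beta = 0.1)
  f1 <- fit_lmm(y ~ landmark + age, d)
  d$y <- d$y + 100
  f2 <- fit_lmm(y ~ landmark + age, d)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-8)
  expect_equal(f1$sigma2_subject, f2$sigma2_subject, tolerance = 1e-6)
  expect_equal(unname(f1$coefficients["age"]), unname(f2$coefficients["age"]),
               tolerance = 1e-8)
})

test_that("the age F-test is calibrated under the null", {
  set.seed(1)
  ps <- replicate(500, {
    d <- balanced_long_table(30, sprintf("L%d", 1:8))
    at <- anova(fit_lmm(y ~ landmark + age + circumference, d))
    at$p_value[at$effect == "age"]
  })
  rate <- mean(ps < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

test_that("stepwise selection finds real effects and respects hierarchy", {
  # power: a real age effect is selected nearly always
  set.seed(101)
  hits <- replicate(200, {
    d <- balanced_long_table(15, sprintf("L%d", 1:5), age_beta = 0.12,
                             subject_sd = 0.5)
    "age" %in% stepwise_lmm(d, "y", c("age", "circumference", "landmark"))$terms
  })
  expect_gte(mean(hits), 0.9)

  # hierarchy: interactions appear only after both parent mains
  set.seed(7)
  d <- balanced_long_table(20, sprintf("L%d", 1:4), age_beta = 0.15,
                           subject_sd = 0.3,
                           landmark_effects = c(0, 2, 4, 6))
  d$y <- d$y + 0.1 * d$age * (as.integer(d$landmark) - 2.5)
  sel <- stepwise_lmm(d, "y", c("age", "circumference", "landmark"))
  inter <- grep(":", sel$terms, value = TRUE)
  for (tm in inter) {
    parents <- strsplit(tm, ":")[[1]]
    expect_true(all(parents %in% sel$terms))
    expect_true(all(match(parents, sel$terms) < match(tm, sel$terms)))
  }
  expect_true("age:landmark" %in% sel$terms || "landmark:age" %in% sel$terms)
  # trace records the accepted path
  expect_true(all(c("step", "candidate", "AIC", "accepted") %in%
                    names(sel$trace)))
})

test_that("stepwise over-selection under the null stays near the AIC bound", {
  # A 1-df term enters by AIC when its deviance drop exceeds 2, which under
  # the null happens with probability P(chisq_1 > 2) ~ 0.157; allow binomial
  # slack around that oracle.
  set.seed(202)
  hits <- replicate(500, {
    d <- balanced_long_table(15, sprintf("L%d", 1:5), subject_sd = 0.5)
    "age" %in% stepwise_lmm(d, "y", c("age", "circumference", "landmark"))$terms
  })
  bound <- stats::pchisq(2, 1, lower.tail = FALSE)  # ~0.157
  expect_lt(mean(hits), bound + 3 * sqrt(bound * (1 - bound) / 500))
})

test_that("long tables carry widths (zeros kept) and thickness per landmark", {
  fx <- fixture_cohort(n = 10, seed = 29)
  st <- suture_long_table(fx$pp$geometries, fx$pp$features)
  expect_equal(nrow(st), 10 * 32)
  expect_true(any(st$width == 0))   # older subjects have closed sutures
  expect_true(all(st$width >= 0))
  tt <- thickness_long_table(fx$pp$geometries, fx$pp$features)
  expect_equal(nrow(tt), 10 * 24)
  expect_true(all(tt$thickness > 0))
  expect_equal(nlevels(tt$landmark), 24)
})
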