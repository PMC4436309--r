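test_that("reference curve is monotone, decelerating, and matches its formula", {
  ages <- seq(0, 36, by = 0.5)
  v <- reference_circumference(ages)
  expect_true(all(diff(v) > 0))
  expect_true(all(diff(diff(v)) < 0))  # growth decelerates
  expect_equal(reference_circumference(0), 35)
  expect_lt(reference_circumference(12), reference_circumference(24))
  # brute-force formula oracle
  p <- c(35, 0.411, 8.2)
  expect_equal(v, p[1] * (1 + p[2] * (1 - exp(-ages / p[3]))),
               tolerance = 1e-12)
  expect_error(reference_circumference(-1), "domain error")
  expect_error(reference_circumference(37), "domain error")
})

test_that("newborn template has the 92-landmark layout with exact structure", {
  tpl <- newborn_template()
  expect_equal(nrow(tpl$coords), 92)
  sch <- default_schema
  # boundary pairs straddle their suture point: midpoint on the curve
  g <- pair_to_midline(tpl, sch)
  mid <- skullgeom:::.template_default(sch)$coords
  expect_equal(g$coords[sch$pair_map$mid, ], mid[sch$pair_map$mid, ],
               tolerance = 1e-9)
  # midline-flagged labels at y = 0 exactly in the processed template
  expect_true(all(g$coords[schema_midline_labels(sch), "y"] == 0))
  # midline suture pairs are symmetric across the plane
  expect_equal(tpl$coords["S05A", "y"], -tpl$coords["S05B", "y"])
})

test_that("subject sampling follows the growth, closure and noise laws", {
  spec0 <- cohort_spec(noise_sd = c(0, 0, 0))
  # age 36: all sutures closed -> no pair labels, 60 landmarks
  set.seed(1)
  old <- sample_subject(spec0, 36, 0)
  expect_equal(nrow(old$coords), 60)
  expect_true(all(spec0$schema$pair_map$mid %in% rownames(old$coords)))

  # age 0, zero noise, zero offset: circumference calibrated to the curve
  set.seed(1)
  baby <- sample_subject(spec0, 0, 0)
  g <- align_geometry(pair_to_midline(baby))$geometry
  expect_equal(measure_circumference(g), reference_circumference(0),
               tolerance = 0.01 * reference_circumference(0))

  # determinism: same RNG state twice gives identical output
  spec <- cohort_spec()
  set.seed(42); a <- sample_subject(spec, 9, 1)
  set.seed(42); b <- sample_subject(spec, 9, 1)
  expect_identical(a, b)

  expect_error(sample_subject(spec, -1, 0), "domain error")
})

test_that("width trajectories decline and closure follows the suture sequence", {
  spec <- cohort_spec()
  ages <- seq(0, 36, by = 2)
  w <- sapply(ages, function(a) skullgeom:::.width_at_age(spec, a))
  expect_true(all(apply(w, 1, function(r) all(diff(r) <= 1e-12))))
  closure <- spec$closure_ages
  sch <- spec$schema
  su <- sch$labels$suture[match(names(closure), sch$labels$label)]
  expect_lt(max(closure[su == "squamosal"]),
            min(closure[su %in% c("lambdoid", "coronal")]))
  expect_lt(max(closure[su %in% c("lambdoid", "coronal")]),
            max(closure[su == "sagittal"]))  # anterior sagittal closes last
  expect_true(all(closure <= 24))
})

test_that("occipital thickness exceeds parietal at every age, noise free", {
  tp <- default_thickness_params()
  for (a in c(0, 6, 18, 36)) {
    th <- skullgeom:::.thickness_at_age(tp, a)
    expect_gt(mean(th[tp$region == "occipital"]),
              mean(th[tp$region == "parietal"]))
    expect_gt(mean(th[tp$region == "occipital"]),
              mean(th[tp$region == "frontal"]))
  }
})

test_that("cohorts reproduce the age-circumference correlation structure", {
  fx <- fixture_cohort(n = 56, seed = 7)
  r <- cor(fx$pp$features$age_months, fx$pp$features$circumference_cm)
  expect_gt(r, 0.8)

  # zero offset SD and zero noise: all subjects on the median curve
  spec0 <- cohort_spec(n_subjects = 6, cir_offset_sd = 0,
                       noise_sd = c(0, 0, 0), seed = 2)
  pp0 <- preprocess_cohort(sample_cohort(spec0))
  expect_equal(pp0$features$circumference_cm,
               reference_circumference(pp0$features$age_months),
               tolerance = 1e-9)

  expect_error(sample_cohort(cohort_spec(n_subjects = 2)),
               "insufficient-data")
})

test_that("cohort generation is deterministic in the seed", {
  spec <- cohort_spec(n_subjects = 5, seed = 123)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth$age, b$truth$age)
})

test_that("model_based cohorts reproduce the linear-Gaussian construction exactly", {
  spec <- cohort_spec(n_subjects = 10, seed = 3, mode = "model_based",
                      noise_sd = c(0, 0, 0))
  co <- sample_cohort(spec)
  recs <- attr(co$truth, "records")
  tm <- co$model
  for (i in c(1, 5, 10)) {
    f <- c(1, co$truth$age[i], co$truth$cir_offset[i])
    expected <- tm$coords$mean +
      as.vector(t(tm$coords$basis) %*% (tm$coords$C %*% f))
    expect_equal(recs[[i]]$coords, expected, tolerance = 1e-12)
    g <- pair_to_midline(co$subjects[[i]])
    expect_equal(as.vector(t(g$coords)), expected, tolerance = 1e-9)
  }
})

test_that("cohort spec validation enforces the stated constraints", {
  expect_error(cohort_spec(cir_offset_sd = -1), "invalid spec")
  expect_error(cohort_spec(closure_ages =
    stats::setNames(rep(30, 32), names(default_closure_ages()))),
    "24 months")
  tp <- default_thickness_params()
  tp$intercept[tp$region == "occipital"] <- 0.5
  expect_error(cohort_spec(thickness_params = tp), "occipital")
})
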