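test_that("default config reproduces the study's group sizes and passes invariants", {
  cohort <- generate_cohort(generator_config(seed = 11))
  expect_s3_class(cohort, "cohort_table")
  expect_identical(sum(cohort$sex == "M"), 303L)
  expect_identical(sum(cohort$sex == "F"), 587L)
  expect_identical(nrow(cohort), 890L)
  expect_silent(validate_cohort(cohort))
  expect_false(anyDuplicated(cohort$subject_id) > 0)
  expect_true(all(cohort$education %in% 0:3))
  expect_true(all(cohort$apoe %in% 0:2))
})

test_that("identical seed and config give byte-identical cohorts and fixtures", {
  cfg <- generator_config(seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_freesurfer_fixtures(a[1:4, ], cfg, d1)
  m2 <- write_freesurfer_fixtures(a[1:4, ], cfg, d2)
  expect_identical(readLines(m1$path[1]), readLines(m2$path[1]))
  expect_identical(m1$etiv, m2$etiv)
})

test_that("degenerate noise config collapses brain2icv onto the group means", {
  cfg <- generator_config(
    n_male = 20, n_female = 30,
    age_sd_by_sex = c(male = 0, female = 0),
    b2icv_sd_by_sex = c(male = 0, female = 0),
    cog_sd = 0,
    age_effect_on_b2icv = 0,
    seed = 3
  )
  cohort <- generate_cohort(cfg)
  expect_identical(unique(cohort$brain2icv[cohort$sex == "M"]), 0.697)
  expect_identical(unique(cohort$brain2icv[cohort$sex == "F"]), 0.708)
  expect_identical(unique(cohort$age[cohort$sex == "M"]), 74.64)
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(generator_config(apoe_probs = c(0.5, 0.4, 0.2)), "apoe_probs")
  expect_error(generator_config(education_probs = c(0.5, 0.5, 0.2, -0.2)),
               "education_probs")
  expect_error(generator_config(famad_prob = 1.2), "famad_prob")
  expect_error(generator_config(b2icv_sd_by_sex = c(male = -0.01, female = 0.028)),
               "b2icv_sd_by_sex")
  expect_error(generator_config(n_male = 0), "n_male")
  expect_error(generator_config(b2icv_mean_by_sex = c(male = 1.4, female = 0.708)),
               "b2icv_mean_by_sex")
  expect_error(generator_config(age_effect_on_b2icv = -0.02),
               "age_effect_on_b2icv")
})

test_that("replicate male means match the configured mean at the analytic standard error", {
  # oracle: the sample mean of n iid N(mu, sd) values lies within
  # 3 * sd / sqrt(n) of mu with probability 0.997
  mu <- 0.697
  bound <- 3 * 0.026 / sqrt(303)
  within <- vapply(seq_len(200), function(s) {
    cohort <- generate_cohort(generator_config(seed = 1000 + s))
    abs(mean(cohort$brain2icv[cohort$sex == "M"]) - mu) < bound
  }, logical(1))
  expect_gte(mean(within), 0.99)
})

test_that("generator respects the DAG: age independent of sex, both driving brain2icv", {
  rs <- t(vapply(1:40, function(s) {
    cohort <- generate_cohort(generator_config(seed = 2000 + s))
    sex01 <- as.integer(cohort$sex == "F")
    c(age_sex = cor(cohort$age, sex01),
      age_b = cor(cohort$age, cohort$brain2icv),
      sex_b = cor(sex01, cohort$brain2icv))
  }, numeric(3)))
  # the configured sex-specific age means differ by 0.15 years, implying a
  # tiny corr(age, sex) of ~0.018 -- statistically null at any single cohort
  expect_lt(abs(mean(rs[, "age_sex"])), 0.035)
  expect_lt(mean(rs[, "age_b"]), -0.25)   # calibrated near -0.33
  expect_gt(mean(rs[, "age_b"]), -0.41)
  expect_gt(mean(rs[, "sex_b"]), 0.1)     # women retain more volume
})

test_that("marginal moments and class frequencies converge to the configuration", {
  cfg <- generator_config(seed = 1)
  pooled <- do.call(rbind, lapply(1:30, function(s)
    generate_cohort(generator_config(seed = 3000 + s))))
  male <- pooled[pooled$sex == "M", ]
  expect_equal(mean(male$brain2icv), 0.697, tolerance = 2e-3)
  expect_equal(sd(male$brain2icv), 0.026, tolerance = 0.05)
  expect_equal(mean(male$age), 74.64, tolerance = 0.1)
  expect_equal(mean(pooled$cog_score), 9.41, tolerance = 0.05)
  expect_equal(sd(pooled$cog_score), 2.66, tolerance = 0.05)
  expect_equal(as.numeric(prop.table(table(pooled$education))),
               unname(cfg$education_probs), tolerance = 0.02)
  expect_equal(as.numeric(prop.table(table(pooled$apoe))),
               unname(cfg$apoe_probs), tolerance = 0.02)
  expect_equal(mean(pooled$famad), cfg$famad_prob, tolerance = 0.02)
})

test_that("fixture files round-trip the cohort's brain2icv through the parser", {
  cfg <- generator_config(seed = 9)
  cohort <- generate_cohort(cfg)[1:12, ]
  dir <- withr::local_tempdir()
  manifest <- write_freesurfer_fixtures(cohort, cfg, dir)
  expect_identical(manifest$subject_id, cohort$subject_id)
  expect_true(all(file.exists(manifest$path)))
  recovered <- vapply(manifest$path, function(p) {
    m <- parse_aseg_stats(p)
    compute_brain2icv(m$tbv, m$etiv)
  }, numeric(1))
  expect_equal(unname(recovered), cohort$brain2icv, tolerance = 1e-9)
  # written volumes reproduce the ratio to at least 6 significant digits
  expect_true(all(abs(manifest$tbv / manifest$etiv - cohort$brain2icv) <
                    1e-6 * cohort$brain2icv))
})

test_that("fixture writer refuses to overwrite unless forced, and handles empty cohorts", {
  cfg <- generator_config(seed = 9)
  cohort <- generate_cohort(cfg)[1:3, ]
  dir <- withr::local_tempdir()
  write_freesurfer_fixtures(cohort, cfg, dir)
  expect_error(write_freesurfer_fixtures(cohort, cfg, dir), "overwrite")
  expect_silent(write_freesurfer_fixtures(cohort, cfg, dir, force = TRUE))

  empty <- cohort[0, ]
  manifest <- write_freesurfer_fixtures(empty, cfg, withr::local_tempdir())
  expect_identical(nrow(manifest), 0L)
})

test_that("cohort CSV round-trips unchanged", {
  cohort <- generate_cohort(generator_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back$brain2icv, cohort$brain2icv, tolerance = 1e-12)
  expect_identical(back$subject_id, cohort$subject_id)
  expect_identical(back$sex, cohort$sex)
})
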