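test_that("cohort summary reports the expected class percentages and moments", {
  cohort <- generate_cohort(generator_config(seed = 4))
  s <- summarize_cohort(cohort)
  cat_tbl <- s$categorical
  female <- cat_tbl[cat_tbl$variable == "sex" & cat_tbl$class == "F", ]
  expect_identical(female$n, 587L)
  expect_identical(female$pct, 65.96)
  male <- cat_tbl[cat_tbl$variable == "sex" & cat_tbl$class == "M", ]
  expect_identical(male$pct, 34.04)
  expect_identical(sum(cat_tbl$n[cat_tbl$variable == "apoe"]), 890L)
  cont <- s$continuous
  expect_equal(cont$mean[cont$variable == "brain2icv"], 0.704, tolerance = 0.01)
})

test_that("degenerate cohorts are summarized without division errors", {
  cohort <- generate_cohort(generator_config(seed = 4))
  single <- cohort[1, ]
  s1 <- summarize_cohort(single)
  expect_true(all(is.na(s1$continuous$sd)))
  expect_false(any(is.nan(s1$categorical$pct)))

  flat <- cohort
  flat$brain2icv <- 0.7
  s2 <- summarize_cohort(flat)
  expect_identical(s2$continuous$sd[s2$continuous$variable == "brain2icv"], 0)
  expect_error(summarize_cohort(cohort[0, ]), "non-empty")
})

test_that("two-sample test handles the null identity and degenerate groups", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  res <- two_sample_test(c(x, x), rep(c("a", "b"), each = 5))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(two_sample_test(x, rep("a", 5)), "two groups")
  expect_error(two_sample_test(1:6, c("a", "a", "a", "b", "c", "c")), "two groups")
  expect_error(two_sample_test(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("sex group tests recover the generator's null and real effects", {
  p_age <- numeric(100)
  p_b2icv <- numeric(100)
  for (s in seq_len(100)) {
    cohort <- generate_cohort(generator_config(seed = 5000 + s))
    p_age[s] <- two_sample_test(cohort$age, cohort$sex)$p
    p_b2icv[s] <- two_sample_test(cohort$brain2icv, cohort$sex)$p
  }
  # age by sex: no generating edge, so rejections at 1% stay near the nominal rate
  expect_lte(mean(p_age < 0.01), 0.05)
  # brain2icv by sex: 0.42 sd effect at n = 890 gives essentially full power
  expect_gte(mean(p_b2icv < 0.01), 0.99)
})

test_that("association matrix is symmetric with unit diagonal and tagged methods", {
  cohort <- generate_cohort(generator_config(seed = 6))
  am <- association_matrix(cohort)
  expect_identical(unname(diag(am$values)), rep(1, length(am$labels)))
  expect_identical(am$values, t(am$values))
  expect_true(all(abs(am$values) <= 1, na.rm = TRUE))
  expect_identical(am$method["age", "brain2icv"], "pearson")
  expect_identical(am$method["sex", "brain2icv"], "point_biserial")
  expect_identical(am$method["education", "brain2icv"], "ordinal_pearson")
  expect_identical(am$method["sex", "apoe"], "point_biserial")
  # calibrated age correlation (per-cohort sampling sd is ~0.03)
  expect_lt(am$values["age", "brain2icv"], -0.2)
  expect_gt(am$values["age", "brain2icv"], -0.45)
  expect_error(association_matrix(cohort[1:2, ]), "at least 3")
})

test_that("point-biserial coefficient equals Pearson on the 0/1 coding", {
  cohort <- generate_cohort(generator_config(seed = 6))
  am <- association_matrix(cohort)
  sex01 <- as.integer(cohort$sex == "F")
  expect_equal(am$values["sex", "brain2icv"], cor(sex01, cohort$brain2icv),
               tolerance = 1e-15)
  # and its p-value matches the t-transform used by cor.test
  ct <- cor.test(sex01, cohort$brain2icv)
  expect_equal(am$p_values["sex", "brain2icv"], ct$p.value, tolerance = 1e-12)
})

test_that("constant columns yield NA associations with the reason recorded", {
  cohort <- generate_cohort(generator_config(seed = 6))
  cohort$famad <- 0L
  am <- association_matrix(cohort)
  expect_identical(am$degenerate, "famad")
  expect_true(all(is.na(am$values["famad", ])))
  expect_true(all(is.na(am$values[, "famad"])))
  expect_false(anyNA(am$values[setdiff(am$labels, "famad"),
                               setdiff(am$labels, "famad")]))
})

test_that("univariate OLS F equals the squared pooled-variance t for a binary predictor", {
  cohort <- generate_cohort(generator_config(seed = 7))
  an <- ols_anova(cohort, "sex")
  tt <- two_sample_test(cohort$brain2icv, cohort$sex, var_equal = TRUE)
  expect_equal(an$f_stat, tt$t^2, tolerance = 1e-8)
  expect_identical(an$df_num, 1L)
  expect_identical(an$df_den, 888L)
})

test_that("OLS F matches the brute-force sums-of-squares oracle", {
  # fixed 6-point dataset, binary grouping
  y6 <- c(0.71, 0.68, 0.70, 0.66, 0.73, 0.65)
  g6 <- c("M", "M", "M", "F", "F", "F")
  cohort6 <- data.frame(subject_id = paste0("s", 1:6), age = c(71, 74, 76, 72, 70, 80),
                        sex = g6, apoe = 0L, famad = 0L, education = c(0, 1, 2, 3, 1, 2),
                        cog_score = 9, brain2icv = y6)
  an <- ols_anova(cohort6, c("sex", "age", "education"))
  expect_equal(an$f_stat[an$predictor == "sex"], anova_brute_groups(y6, g6),
               tolerance = 1e-10)
  expect_equal(an$f_stat[an$predictor == "age"],
               anova_brute_slope(y6, cohort6$age), tolerance = 1e-10)
  expect_equal(an$f_stat[an$predictor == "education"],
               anova_brute_slope(y6, cohort6$education), tolerance = 1e-10)

  # property: random small datasets agree with the oracle on both paths
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    y <- rnorm(n, 0.7, 0.03)
    g <- sample(c("M", "F"), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c("M", "F")
    x <- rnorm(n, 74, 4)
    co <- data.frame(subject_id = paste0("s", 1:n), age = x, sex = g, apoe = 0L,
                     famad = 0L, education = 0L, cog_score = 9, brain2icv = y)
    an <- ols_anova(co, c("sex", "age"))
    expect_equal(an$f_stat[an$predictor == "sex"], anova_brute_groups(y, g),
                 tolerance = 1e-10)
    expect_equal(an$f_stat[an$predictor == "age"], anova_brute_slope(y, x),
                 tolerance = 1e-10)
  }
})

test_that("ols_anova enforces the predictor contract", {
  cohort <- generate_cohort(generator_config(seed = 7))
  expect_error(ols_anova(cohort, "cog_score"), "not permitted")
  expect_error(ols_anova(cohort, "nonsense"), "not permitted")
  cohort$famad <- 0L
  expect_error(ols_anova(cohort, "famad"), "constant")
  # categorical education uses 3 numerator df
  an <- ols_anova(generate_cohort(generator_config(seed = 7)), "education",
                  education_categorical = TRUE)
  expect_identical(an$df_num, 3L)
})

test_that("default-generator ANOVA pattern matches the study design over repeated seeds", {
  hits <- t(vapply(seq_len(100), function(s) {
    cohort <- generate_cohort(generator_config(seed = 7000 + s))
    an <- ols_anova(cohort)
    p <- setNames(an$p_value, an$predictor)
    c(age = p[["age"]] < 0.01, sex = p[["sex"]] < 0.01,
      apoe = p[["apoe"]] < 0.01, famad = p[["famad"]] < 0.01)
  }, logical(4)))
  expect_gte(mean(hits[, "age"]), 0.99)   # built-in age effect: full power
  expect_gte(mean(hits[, "sex"]), 0.99)   # built-in sex effect: full power
  expect_lte(mean(hits[, "apoe"]), 0.05)  # generator null
  expect_lte(mean(hits[, "famad"]), 0.05) # generator null
})
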