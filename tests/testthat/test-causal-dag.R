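test_that("study DAG encodes the assumed causal structure", {
  dag <- build_study_dag()
  expect_true(is_acyclic(dag))
  expect_identical(dag_parents(dag, "brain2icv"), c("age", "sex"))
  expect_identical(dag_parents(dag, "cog_score"), c("brain2icv", "education"))
  expect_identical(dag_parents(dag, "apoe"), character(0))
  # optional edges toggle on
  dag2 <- build_study_dag(edu_to_b2icv = TRUE)
  expect_identical(dag_parents(dag2, "brain2icv"), c("age", "education", "sex"))
})

test_that("DAG validation rejects malformed graphs and cycles", {
  expect_error(dag_spec(c("a", "b"), data.frame(from = "a", to = "c")), "not declared")
  expect_error(dag_spec(c("a", "b"), data.frame(from = "a", to = "a")), "self-loops")
  expect_error(dag_spec(c("a", "b", "c"),
                        data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))),
               "cycle")
  dag <- build_study_dag()
  expect_error(dag_add_edge(dag, "cog_score", "education"), "cycle")
  expect_s3_class(dag_add_edge(dag, "apoe", "brain2icv"), "dag_spec")
})

test_that("acyclicity agrees with brute-force path enumeration on random graphs", {
  set.seed(13)
  nodes <- letters[1:6]
  for (rep in 1:60) {
    all_pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
    edges <- all_pairs[runif(nrow(all_pairs)) < 0.15, ]
    candidate <- structure(list(nodes = nodes, edges = edges), class = "dag_spec")
    expect_identical(is_acyclic(candidate), !has_cycle_dfs(nodes, edges))
  }
})

test_that("collider detection matches a brute-force edge scan on all ordered triples", {
  dag <- build_study_dag()
  expect_true(is_collider(dag, "sex", "brain2icv", "age"))
  expect_false(is_collider(dag, "sex", "age", "brain2icv"))
  expect_error(is_collider(dag, "sex", "brain2icv", "nope"), "unknown node")

  set.seed(14)
  nodes <- c("w", "x", "y", "z")
  for (rep in 1:20) {
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from < pairs$to, ]  # acyclic by construction
    edges <- pairs[runif(nrow(pairs)) < 0.4, ]
    g <- dag_spec(nodes, edges)
    for (x in nodes) for (z in nodes) for (y in nodes) {
      if (length(unique(c(x, z, y))) < 3) next
      oracle <- any(edges$from == x & edges$to == z) &&
        any(edges$from == y & edges$to == z)
      expect_identical(is_collider(g, x, z, y), oracle)
    }
  }
})

test_that("DAG edge-list files round-trip", {
  dag <- build_study_dag()
  path <- withr::local_tempfile(fileext = ".txt")
  write_dag(dag, path)
  back <- read_dag(path)
  expect_setequal(back$nodes, dag$nodes)
  expect_equal(back$edges[order(back$edges$from, back$edges$to), ],
               dag$edges[order(dag$edges$from, dag$edges$to), ],
               ignore_attr = TRUE)
})

test_that("nested regressions recover the built-in age and sex effects", {
  cohort <- generate_cohort(generator_config(seed = 41))
  fits <- fit_nested_regressions(cohort, quick_sampler(41)) |> suppressWarnings()
  expect_named(fits, c("sex_only", "age_only", "age_plus_sex"))
  for (label in c("age_only", "age_plus_sex")) {
    d <- as.vector(fits[[label]]$draws[, , "age"])
    h <- hdi(d, 0.94)
    expect_lt(h$upper, 0)  # negative age effect, HDI excluding 0
  }
  d_sex <- as.vector(fits$age_plus_sex$draws[, , "sex"])
  expect_gt(hdi(d_sex, 0.94)$lower, 0)  # female indicator positive

  stab <- coefficient_stability_report(fits)
  expect_true(stab$all_stable)
  expect_identical(stab$thresholds$shift_threshold, 0.5)
})

test_that("a generator without a sex effect yields a sex HDI containing zero", {
  cfg <- generator_config(b2icv_mean_by_sex = c(male = 0.702, female = 0.702),
                          seed = 42)
  cohort <- generate_cohort(cfg)
  fits <- fit_nested_regressions(cohort, quick_sampler(42)) |> suppressWarnings()
  h <- hdi(as.vector(fits$sex_only$draws[, , "sex"]), 0.94)
  expect_lt(h$lower, 0)
  expect_gt(h$upper, 0)
})

test_that("stability report flags induced confounding and passes the identity check", {
  # confounded variant: age depends on sex, so omitting sex shifts the age slope
  set.seed(43)
  n <- 890
  sexF <- rep(c(0, 1), c(303, 587))
  age <- 74.7 + 4 * sexF + rnorm(n, 0, 3.5)
  b2icv <- 0.87 - 0.0023 * age + 0.02 * sexF + rnorm(n, 0, 0.02)
  confounded <- data.frame(subject_id = sprintf("s%03d", 1:n), age = age,
                           sex = ifelse(sexF == 1, "F", "M"), apoe = 0L,
                           famad = 0L, education = 1L, cog_score = 9,
                           brain2icv = b2icv)
  fits <- fit_nested_regressions(confounded, quick_sampler(43)) |> suppressWarnings()
  stab <- coefficient_stability_report(fits)
  expect_false(stab$table$stable[stab$table$predictor == "age"])
  expect_gt(stab$table$mean_shift_sd[stab$table$predictor == "age"], 0.5)

  # comparing a model against itself: zero shift, unit sd ratio
  self <- list(sex_only = fits$age_plus_sex, age_only = fits$age_plus_sex,
               age_plus_sex = fits$age_plus_sex)
  stab_self <- coefficient_stability_report(self)
  expect_equal(stab_self$table$mean_shift_sd, c(0, 0), tolerance = 1e-12)
  expect_equal(stab_self$table$sd_ratio, c(1, 1), tolerance = 1e-12)
})

test_that("constant predictors are rejected by the regression stage", {
  cohort <- generate_cohort(generator_config(seed = 44))
  cohort$sex <- "F"
  expect_error(fit_nested_regressions(cohort, quick_sampler(44)),
               "constant predictor: sex")
})

test_that("conditioning on the collider induces an age-sex association", {
  cohort <- generate_cohort(generator_config(seed = 45))
  demo <- collider_conditioning_demo(cohort, n_strata = 5)
  expect_lt(abs(demo$marginal$r), 3 / sqrt(890))
  expect_identical(nrow(demo$strata), 5L)

  # aggregate over seeds: within a brain2icv band, older subjects are more
  # likely to be the sex with less atrophy, so the pooled within-stratum
  # correlation is systematically positive while the marginal one is null
  stats <- t(vapply(1:25, function(s) {
    co <- generate_cohort(generator_config(seed = 4500 + s))
    d <- collider_conditioning_demo(co, n_strata = 5)
    pc <- partial_correlation_test(co, "age", "sex", "brain2icv")
    c(marginal = d$marginal$r,
      pooled = sum(d$strata$r * d$strata$n) / sum(d$strata$n),
      partial = pc$estimate)
  }, numeric(3)))
  # marginal association only carries the configured 0.15-year age offset
  expect_lt(abs(mean(stats[, "marginal"])), 0.035)
  expect_gt(mean(stats[, "pooled"] - stats[, "marginal"]), 0.02)
  expect_gt(mean(stats[, "partial"]), 0.03)
  expect_gte(mean(stats[, "pooled"] > 0), 0.75)

  # both arrows are needed: removing the age effect kills the induced
  # association (stratification no longer changes the age-sex correlation)
  rs <- vapply(1:25, function(s) {
    demo0 <- collider_conditioning_demo(
      generate_cohort(generator_config(age_effect_on_b2icv = 0, seed = 4600 + s)))
    demo0$marginal$r -
      sum(demo0$strata$r * demo0$strata$n) / sum(demo0$strata$n)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("small strata are dropped with a warning", {
  cohort <- generate_cohort(generator_config(seed = 46))[1:12, ]
  warns <- testthat::capture_warnings(
    demo <- collider_conditioning_demo(cohort, n_strata = 6)
  )
  expect_true(any(grepl("fewer than 3", warns)))
  expect_lt(NROW(demo$strata), 6L)
  expect_error(collider_conditioning_demo(cohort, n_strata = 1), "at least 2")
})
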