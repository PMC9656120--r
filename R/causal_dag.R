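#' Directed acyclic graph specification
#'
#' A minimal DAG container for encoding causal assumptions: named nodes and
#' directed cause -> effect edges. Construction validates that edge endpoints
#' are declared nodes, that there are no self-loops, and that the graph is
#' acyclic (checked by Kahn's topological sort).
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column matrix or data.frame of edges (`from`, `to`); may
#'   have zero rows.
#' @return A list of class `dag_spec` with `nodes` and `edges` (a
#'   `data.frame` with columns `from`, `to`).
#' @export
dag_spec <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes)
  if (length(unknown)) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  if (anyDuplicated(paste(edges$from, edges$to))) {
    stop("duplicate edges", call. = FALSE)
  }
  dag <- structure(list(nodes = nodes, edges = edges), class = "dag_spec")
  if (!is_acyclic(dag)) {
    stop("graph contains a directed cycle", call. = FALSE)
  }
  dag
}

#' Test a graph for acyclicity
#'
#' Kahn's algorithm: repeatedly remove nodes of in-degree zero; the graph is
#' acyclic iff all nodes can be removed.
#'
#' @param dag A `dag_spec` (validation of acyclicity is skipped during
#'   construction for this call, so it can also be used on candidate graphs).
#' @return `TRUE` if acyclic.
#' @export
is_acyclic <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(edges$to, levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  remaining <- nodes
  repeat {
    zero <- remaining[indeg[remaining] == 0L]
    if (!length(zero)) break
    for (n in zero) {
      out <- edges$to[edges$from == n & edges$to %in% remaining]
      indeg[out] <- indeg[out] - 1L
    }
    remaining <- setdiff(remaining, zero)
  }
  length(remaining) == 0L
}

#' Add an edge to a DAG
#'
#' @param dag A `dag_spec`.
#' @param from,to Node names. Adding an edge that creates a cycle is an
#'   error.
#' @return The extended `dag_spec`.
#' @export
dag_add_edge <- function(dag, from, to) {
  stopifnot(inherits(dag, "dag_spec"))
  dag_spec(dag$nodes, rbind(dag$edges,
                            data.frame(from = from, to = to,
                                       stringsAsFactors = FALSE)))
}

#' Parents of a node
#'
#' @param dag A `dag_spec`.
#' @param node Node name.
#' @return Character vector of direct causes of `node`.
#' @export
dag_parents <- function(dag, node) {
  stopifnot(inherits(dag, "dag_spec"))
  if (!node %in% dag$nodes) stop("unknown node '", node, "'", call. = FALSE)
  sort(dag$edges$from[dag$edges$to == node])
}

#' The study's causal DAG
#'
#' Encodes the causal assumptions of the analysis: sex and age are the only
#' direct influences on Brain2ICV, education and Brain2ICV drive the
#' cognitive score, and APOE and family history stand as independent
#' marginals (their null associations motivate leaving them unconnected by
#' default). Candidate edges into Brain2ICV from education, APOE or family
#' history can be toggled on to express alternative assumptions.
#'
#' @param edu_to_b2icv,apoe_to_b2icv,famad_to_b2icv Include the optional
#'   edge into `brain2icv` (all default `FALSE`).
#' @return A `dag_spec` over nodes `sex`, `age`, `apoe`, `famad`,
#'   `education`, `brain2icv`, `cog_score`.
#' @export
#' @examples
#' dag <- build_study_dag()
#' dag_parents(dag, "brain2icv")
#' is_collider(dag, "sex", "brain2icv", "age")
build_study_dag <- function(edu_to_b2icv = FALSE, apoe_to_b2icv = FALSE,
                            famad_to_b2icv = FALSE) {
  nodes <- c("sex", "age", "apoe", "famad", "education", "brain2icv",
             "cog_score")
  edges <- data.frame(
    from = c("sex", "age", "education", "brain2icv"),
    to = c("brain2icv", "brain2icv", "cog_score", "cog_score"),
    stringsAsFactors = FALSE
  )
  opt <- c(education = edu_to_b2icv, apoe = apoe_to_b2icv, famad = famad_to_b2icv)
  for (nm in names(opt)[opt]) {
    edges <- rbind(edges, data.frame(from = nm, to = "brain2icv",
                                     stringsAsFactors = FALSE))
  }
  dag_spec(nodes, edges)
}

#' Is z a collider between x and y?
#'
#' A collider is a node receiving arrows from both of the other two nodes:
#' x -> z <- y. Conditioning on a collider (or a descendant of one) can
#' induce a spurious association between its parents.
#'
#' @param dag A `dag_spec`.
#' @param x,z,y Node names; `z` is the candidate collider.
#' @return `TRUE` iff both edges `x -> z` and `y -> z` are present.
#' @export
is_collider <- function(dag, x, z, y) {
  stopifnot(inherits(dag, "dag_spec"))
  for (node in c(x, z, y)) {
    if (!node %in% dag$nodes) stop("unknown node '", node, "'", call. = FALSE)
  }
  has_edge <- function(a, b) any(dag$edges$from == a & dag$edges$to == b)
  has_edge(x, z) && has_edge(y, z)
}

#' Read and write DAG edge-list files
#'
#' The exchange format is a plain text file with one `cause<TAB>effect` pair
#' per line; lines starting with `#` are comments. Nodes are the union of
#' endpoints plus any extra isolated nodes listed after a `# nodes:` comment.
#'
#' @param dag A `dag_spec`.
#' @param path File path.
#' @return `read_dag()` returns a `dag_spec`; `write_dag()` returns `path`
#'   invisibly.
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "dag_spec"))
  isolated <- setdiff(dag$nodes, c(dag$edges$from, dag$edges$to))
  header <- if (length(isolated)) {
    paste0("# nodes: ", paste(isolated, collapse = ","))
  } else {
    "# edge list: cause<TAB>effect"
  }
  writeLines(c(header, paste(dag$edges$from, dag$edges$to, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_dag
#' @export
read_dag <- function(path) {
  lines <- readLines(path, warn = FALSE)
  extra <- character()
  node_line <- grep("^#\\s*nodes:", lines, value = TRUE)
  if (length(node_line)) {
    extra <- trimws(strsplit(sub("^#\\s*nodes:\\s*", "", node_line[1]), ",")[[1]])
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t")
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad)) stop("malformed edge line(s): ", lines[bad][1], call. = FALSE)
    edges <- data.frame(from = vapply(parts, `[[`, "", 1),
                        to = vapply(parts, `[[`, "", 2),
                        stringsAsFactors = FALSE)
  } else {
    edges <- NULL
  }
  nodes <- unique(c(if (!is.null(edges)) c(edges$from, edges$to), extra))
  dag_spec(nodes, edges)
}

# Bayesian linear regression of a standardized outcome by componentwise
# random-walk Metropolis; N(0,1) priors on coefficients, HalfNormal(1) on
# the residual scale. X must include the intercept column.
.fit_bayes_lm <- function(y, X, config, model_label) {
  n <- length(y)
  p <- ncol(X)
  # center non-intercept columns: slopes are unchanged, but the intercept
  # decorrelates from them, which the random-walk sampler needs to mix well
  for (j in seq_len(p)) {
    if (stats::sd(X[, j]) > 0) X[, j] <- X[, j] - mean(X[, j])
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  log_post <- function(theta) {
    b <- theta[seq_len(p)]
    u <- theta[p + 1L]
    s <- exp(u)
    rss <- yty - 2 * sum(b * Xty) + sum(b * (XtX %*% b))
    -n * u - rss / (2 * s^2) + sum(stats::dnorm(b, 0, 1, log = TRUE)) -
      s^2 / 2 + u
  }
  ols <- solve(XtX, Xty)
  resid_sd <- sqrt(max((yty - sum(ols * Xty)) / max(1, n - p), 1e-8))
  init <- c(as.vector(ols), log(resid_sd))
  scales <- c(resid_sd * sqrt(pmax(diag(solve(XtX)), 1e-12)),
              1 / sqrt(2 * n))
  draws <- .rw_metropolis(log_post, init, scales, config)
  draws[, , p + 1L] <- exp(draws[, , p + 1L])
  param_names <- c(colnames(X), "sigma")
  dimnames(draws) <- list(NULL, NULL, param_names)
  diagnostics <- .diagnose_draws(draws, param_names)
  converged <- all(is.finite(diagnostics$rhat)) &&
    all(diagnostics$rhat <= 1.01) && all(diagnostics$ess >= 400)
  if (!converged) {
    warning("regression sampler convergence not established for model '",
            model_label, "'", call. = FALSE)
  }
  structure(list(model_label = model_label, draws = draws,
                 parameters = param_names, diagnostics = diagnostics,
                 converged = converged, seed = config$seed, config = config),
            class = "regression_posterior")
}

# flat draws of one regression coefficient
.coef_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "regression_posterior"))
  if (!parameter %in% fit$parameters) {
    stop("unknown parameter '", parameter, "' in model '", fit$model_label,
         "'", call. = FALSE)
  }
  as.vector(fit$draws[, , parameter])
}

#' Nested Bayesian regressions of Brain2ICV on sex and age
#'
#' Fits three Bayesian linear regressions of standardized Brain2ICV: on sex
#' alone, on standardized age alone, and on both together. Coefficients get
#' N(0, 1) priors and the residual scale a HalfNormal(1) prior; age is
#' standardized (mean 0, sd 1) and sex enters as a 0/1 indicator (1 =
#' female), so all coefficients are in outcome-sd units. Comparing the
#' simple and multiple fits operationalizes the conditional-independence
#' question: if sex and age are marginally independent causes of a collider
#' (Brain2ICV), each coefficient should be essentially unchanged by adding
#' the other predictor.
#'
#' @param cohort A cohort table with `age`, `sex`, `brain2icv`.
#' @param config A [sampler_config()]; each model is fitted with a seed
#'   offset so fits are independent but reproducible.
#' @param mass HDI mass attached to coefficient summaries (default 0.94).
#' @return A named list of three `regression_posterior` objects:
#'   `sex_only`, `age_only`, `age_plus_sex`.
#' @export
fit_nested_regressions <- function(cohort, config = sampler_config(),
                                   mass = 0.94) {
  .check_cohort(cohort, require = c("age", "sex", "brain2icv"))
  y <- .zscore(cohort$brain2icv)
  z_age <- .zscore(cohort$age)
  sex01 <- .sex01(cohort$sex)
  if (stats::sd(cohort$brain2icv) == 0) stop("constant outcome", call. = FALSE)
  if (stats::sd(z_age) == 0) stop("constant predictor: age", call. = FALSE)
  if (stats::sd(sex01) == 0) stop("constant predictor: sex", call. = FALSE)
  n <- length(y)
  one <- rep(1, n)
  cfg_k <- function(k) sampler_config(config$chains, config$draws,
                                      config$warmup, config$seed + k)
  list(
    sex_only = .fit_bayes_lm(y, cbind(intercept = one, sex = sex01),
                             cfg_k(1L), "sex_only"),
    age_only = .fit_bayes_lm(y, cbind(intercept = one, age = z_age),
                             cfg_k(2L), "age_only"),
    age_plus_sex = .fit_bayes_lm(y, cbind(intercept = one, age = z_age,
                                          sex = sex01),
                                 cfg_k(3L), "age_plus_sex")
  )
}

#' Coefficient stability across nested regressions
#'
#' For each of age and sex, compares the posterior from the simple
#' (single-predictor) model with the multiple (both-predictor) model: the
#' shift in posterior mean in units of the simple model's posterior sd, and
#' the ratio of posterior sds. A predictor is declared stable — i.e. adding
#' the other variable contributes no additional information — when the shift
#' is below `shift_threshold` and the sd ratio lies inside `sd_ratio_band`.
#' Thresholds are configurable and echoed in the report.
#'
#' @param fits The list returned by [fit_nested_regressions()].
#' @param shift_threshold Maximal mean shift, in simple-model posterior sds
#'   (default 0.5).
#' @param sd_ratio_band Acceptable multiple/simple posterior-sd ratio
#'   (default `c(0.8, 1.25)`).
#' @param mass HDI mass for the per-model coefficient intervals.
#' @return A list of class `stability_report`: `table` (per-predictor means,
#'   sds, HDIs, shift, sd ratio, stable flag), `thresholds`, `all_stable`.
#' @export
coefficient_stability_report <- function(fits, shift_threshold = 0.5,
                                         sd_ratio_band = c(0.8, 1.25),
                                         mass = 0.94) {
  for (nm in c("sex_only", "age_only", "age_plus_sex")) {
    if (!nm %in% names(fits)) stop("missing fit '", nm, "'", call. = FALSE)
  }
  n_draws <- vapply(fits, function(f) length(.coef_draws(f, "sigma")),
                    numeric(1))
  if (length(unique(n_draws)) != 1L) {
    stop("mismatched draw counts across fits", call. = FALSE)
  }
  simple_of <- c(age = "age_only", sex = "sex_only")
  rows <- lapply(names(simple_of), function(v) {
    ds <- .coef_draws(fits[[simple_of[[v]]]], v)
    dm <- .coef_draws(fits$age_plus_sex, v)
    hs <- hdi(ds, mass)
    hm <- hdi(dm, mass)
    shift <- abs(mean(dm) - mean(ds)) / stats::sd(ds)
    ratio <- stats::sd(dm) / stats::sd(ds)
    data.frame(predictor = v,
               simple_mean = mean(ds), simple_sd = stats::sd(ds),
               simple_hdi_low = hs$lower, simple_hdi_high = hs$upper,
               multiple_mean = mean(dm), multiple_sd = stats::sd(dm),
               multiple_hdi_low = hm$lower, multiple_hdi_high = hm$upper,
               mean_shift_sd = shift, sd_ratio = ratio,
               stable = shift < shift_threshold &&
                 ratio >= sd_ratio_band[1] && ratio <= sd_ratio_band[2],
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table,
                 thresholds = list(shift_threshold = shift_threshold,
                                   sd_ratio_band = sd_ratio_band),
                 all_stable = all(table$stable)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Coefficient stability across nested regressions\n")
  cat(sprintf("  thresholds: mean shift < %.2f simple-model sd, sd ratio in [%.2f, %.2f]\n",
              x$thresholds$shift_threshold, x$thresholds$sd_ratio_band[1],
              x$thresholds$sd_ratio_band[2]))
  tbl <- x$table
  num <- vapply(tbl, is.numeric, logical(1))
  tbl[num] <- lapply(tbl[num], round, 3)
  print(tbl, row.names = FALSE)
  cat(if (x$all_stable) {
    "  conclusion: no additional information from the second predictor\n"
  } else {
    "  conclusion: coefficients are NOT stable across nested models\n"
  })
  invisible(x)
}

#' Classical partial-correlation test of conditional independence
#'
#' Cross-check for the Bayesian stability analysis: the partial correlation
#' of `x` and `y` given `z` (from residuals of the linear projections on
#' `z`) with its t-test.
#'
#' @param cohort A cohort table.
#' @param x,y,given Column names; `sex` is coded 0/1 (1 = female) and `apoe`
#'   as the binary carrier indicator.
#' @return A list: `estimate`, `statistic`, `p_value`, `df`.
#' @export
partial_correlation_test <- function(cohort, x = "age", y = "sex",
                                     given = "brain2icv") {
  .check_cohort(cohort)
  m <- as.data.frame(.analysis_matrix(cohort))
  for (v in c(x, y, given)) {
    if (!v %in% names(m)) stop("unknown variable '", v, "'", call. = FALSE)
  }
  rx <- stats::resid(stats::lm(m[[x]] ~ as.matrix(m[given])))
  ry <- stats::resid(stats::lm(m[[y]] ~ as.matrix(m[given])))
  r <- stats::cor(rx, ry)
  df <- nrow(m) - 2L - length(given)
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(estimate = r, statistic = tstat,
       p_value = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' Collider-conditioning demonstration
#'
#' Shows the collider effect empirically: the marginal age-sex association
#' (point-biserial correlation) is compared with the same association within
#' quantile strata of Brain2ICV. When sex and age are independent causes of
#' Brain2ICV, the marginal association is null while the within-stratum
#' associations are systematically nonzero — conditioning on the collider
#' opens the sex -> Brain2ICV <- age path. With both causal effects negative
#' toward higher atrophy for men and older subjects, the induced
#' within-stratum association is positive (within a stratum, an older
#' subject is more likely to be female).
#'
#' @param cohort A cohort table.
#' @param n_strata Number of Brain2ICV quantile bins (default 5, >= 2).
#' @return A list of class `collider_demo`: `marginal` (r, p, n), `strata`
#'   (per-stratum r, p, n; strata with fewer than 3 subjects are dropped
#'   with a warning), `n_strata`.
#' @export
collider_conditioning_demo <- function(cohort, n_strata = 5L) {
  .check_cohort(cohort, require = c("age", "sex", "brain2icv"))
  if (n_strata < 2L) stop("n_strata must be at least 2", call. = FALSE)
  sex01 <- .sex01(cohort$sex)
  age <- cohort$age
  cor_test <- function(a, s) {
    if (stats::sd(a) == 0 || stats::sd(s) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(a, s)
    df <- length(a) - 2L
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    c(r = r, p = 2 * stats::pt(-abs(tstat), df))
  }
  marg <- cor_test(age, sex01)
  breaks <- unique(stats::quantile(cohort$brain2icv,
                                   probs = seq(0, 1, length.out = n_strata + 1)))
  stratum <- cut(cohort$brain2icv, breaks = breaks, include.lowest = TRUE,
                 labels = FALSE)
  rows <- lapply(sort(unique(stratum)), function(s) {
    sel <- stratum == s
    if (sum(sel) < 3L) {
      warning("stratum ", s, " has fewer than 3 subjects; dropped",
              call. = FALSE)
      return(NULL)
    }
    ct <- cor_test(age[sel], sex01[sel])
    data.frame(stratum = s, n = sum(sel), r = ct[["r"]], p = ct[["p"]],
               b2icv_low = min(cohort$brain2icv[sel]),
               b2icv_high = max(cohort$brain2icv[sel]),
               stringsAsFactors = FALSE)
  })
  strata <- do.call(rbind, rows)
  structure(list(marginal = list(r = marg[["r"]], p = marg[["p"]],
                                 n = nrow(cohort)),
                 strata = strata, n_strata = n_strata),
            class = "collider_demo")
}

#' @export
print.collider_demo <- function(x, ...) {
  cat(sprintf("Marginal corr(age, sex): r = %.4f (p = %.3g, n = %d)\n",
              x$marginal$r, x$marginal$p, x$marginal$n))
  cat("Within Brain2ICV strata:\n")
  tbl <- x$strata
  tbl$r <- round(tbl$r, 4)
  tbl$p <- signif(tbl$p, 3)
  tbl$b2icv_low <- round(tbl$b2icv_low, 4)
  tbl$b2icv_high <- round(tbl$b2icv_high, 4)
  print(tbl, row.names = FALSE)
  invisible(x)
}
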