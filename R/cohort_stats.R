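#' Descriptive summary of a cohort
#'
#' Mean and sd for the continuous variables (age, cognitive score, Brain2ICV)
#' and class counts with percentages for the categorical ones (sex, APOE e4
#' allele count, education level, family history). Percentages are computed
#' on the full cohort and rounded to two decimals; with a single subject the
#' sd is reported as `NA` rather than a division by zero.
#'
#' @param cohort A cohort table.
#' @return A list of class `cohort_summary` with elements `continuous`
#'   (variable, n, mean, sd) and `categorical` (variable, class, n, pct).
#' @export
#' @examples
#' summarize_cohort(generate_cohort(generator_config(seed = 1)))
summarize_cohort <- function(cohort) {
  .check_cohort(cohort)
  n <- nrow(cohort)
  cont <- c(age = "age", cog_score = "cog_score", brain2icv = "brain2icv")
  continuous <- data.frame(
    variable = unname(cont),
    n = n,
    mean = vapply(cont, function(v) mean(cohort[[v]]), numeric(1)),
    sd = vapply(cont, function(v) if (n < 2) NA_real_ else stats::sd(cohort[[v]]),
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  cat_levels <- list(
    sex = c("M", "F"),
    apoe = c("0", "1", "2"),
    education = c("0", "1", "2", "3"),
    famad = c("0", "1")
  )
  categorical <- do.call(rbind, lapply(names(cat_levels), function(v) {
    counts <- table(factor(as.character(cohort[[v]]), levels = cat_levels[[v]]))
    data.frame(variable = v, class = names(counts), n = as.integer(counts),
               pct = round(100 * as.integer(counts) / n, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(categorical) <- NULL
  structure(list(continuous = continuous, categorical = categorical, n = n),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$n, ")\n\nContinuous variables:\n", sep = "")
  cont <- x$continuous
  cont$mean <- round(cont$mean, 2)
  cont$sd <- round(cont$sd, 2)
  print(cont, row.names = FALSE)
  cat("\nCategorical variables:\n")
  print(x$categorical, row.names = FALSE)
  invisible(x)
}

#' Two-sample test of group means
#'
#' Compares a continuous variable between exactly two groups, by default with
#' the Welch (unequal-variance) t-test; a pooled-variance variant is
#' available via `var_equal = TRUE`. Used for the age-by-sex and
#' Brain2ICV-by-sex screens.
#'
#' @param values Numeric vector.
#' @param group_labels Vector with exactly two distinct values, each group of
#'   size at least 2.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A list of class `two_sample_test`: `t`, `p`, `df`, `group_means`,
#'   `group_sds`, `group_n`, `method`.
#' @export
two_sample_test <- function(values, group_labels, var_equal = FALSE) {
  g <- as.character(group_labels)
  levels <- sort(unique(g))
  if (length(levels) != 2L) {
    stop("group_labels must contain exactly two groups (got ", length(levels),
         ")", call. = FALSE)
  }
  n_by <- table(g)
  if (any(n_by < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  x <- values[g == levels[1]]
  y <- values[g == levels[2]]
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(list(
    t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
    group_means = stats::setNames(c(mean(x), mean(y)), levels),
    group_sds = stats::setNames(c(stats::sd(x), stats::sd(y)), levels),
    group_n = stats::setNames(as.integer(n_by[levels]), levels),
    method = if (var_equal) "pooled t-test" else "Welch t-test"
  ), class = "two_sample_test")
}

# numeric coding used for association and regression screens
.analysis_matrix <- function(cohort) {
  cbind(
    age = cohort$age,
    sex = .sex01(cohort$sex),              # 1 = female
    apoe = .apoe_carrier(cohort$apoe),     # 1 = any e4 allele
    famad = as.numeric(cohort$famad),
    education = as.numeric(cohort$education),
    cog_score = cohort$cog_score,
    brain2icv = cohort$brain2icv
  )
}

.var_kind <- c(age = "continuous", sex = "dichotomous", apoe = "dichotomous",
               famad = "dichotomous", education = "ordinal",
               cog_score = "continuous", brain2icv = "continuous")

#' Mixed-type association matrix
#'
#' Pairwise linear association between all study variables: Pearson's r for
#' continuous pairs, the point-biserial coefficient (numerically identical to
#' Pearson on a 0/1 coding) when a dichotomous variable is involved, and
#' plain Pearson on the numeric 0-3 coding for pairs involving the ordinal
#' education level (tagged `ordinal_pearson`). APOE enters as the binary
#' e4-carrier indicator; sex as 1 = female. Each coefficient carries a
#' two-sided p-value from the t transform `t = r * sqrt((n-2)/(1-r^2))`.
#' Constant columns yield `NA` coefficients with the reason recorded.
#'
#' @param cohort A cohort table with at least 3 subjects.
#' @return A list of class `association_matrix`: `labels`, `values`
#'   (symmetric, unit diagonal), `p_values`, `method` (per-pair tag matrix),
#'   `n`, `degenerate` (character vector of constant columns, if any).
#' @export
association_matrix <- function(cohort) {
  .check_cohort(cohort)
  if (nrow(cohort) < 3L) stop("need at least 3 subjects", call. = FALSE)
  x <- .analysis_matrix(cohort)
  labels <- colnames(x)
  k <- length(labels)
  n <- nrow(x)
  constant <- labels[apply(x, 2, function(col) stats::sd(col) == 0)]

  values <- diag(1, k)
  p_values <- matrix(NA_real_, k, k)
  method <- matrix(NA_character_, k, k, dimnames = list(labels, labels))
  dimnames(values) <- dimnames(p_values) <- list(labels, labels)
  pair_method <- function(a, b) {
    kinds <- .var_kind[c(a, b)]
    if (any(kinds == "ordinal")) "ordinal_pearson"
    else if (any(kinds == "dichotomous")) "point_biserial"
    else "pearson"
  }
  for (i in seq_len(k)) {
    method[i, i] <- pair_method(labels[i], labels[i])
    for (j in seq_len(k)[-seq_len(i)]) {
      method[i, j] <- method[j, i] <- pair_method(labels[i], labels[j])
      if (labels[i] %in% constant || labels[j] %in% constant) next
      r <- stats::cor(x[, i], x[, j])
      values[i, j] <- values[j, i] <- r
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      p_values[i, j] <- p_values[j, i] <- p
    }
  }
  # a constant column has no defined association with anything, itself included
  if (length(constant)) {
    values[constant, ] <- NA_real_
    values[, constant] <- NA_real_
  }
  structure(list(labels = labels, values = values, p_values = p_values,
                 method = method, n = n, degenerate = constant),
            class = "association_matrix")
}

#' Per-predictor OLS analysis of variance for Brain2ICV
#'
#' For each requested predictor separately, fits the univariate ordinary
#' least squares model `brain2icv ~ predictor` and reports the F test of
#' that predictor. Sex and APOE enter as 0/1 indicators, family history as
#' 0/1, and education as a single numeric ordinal regressor (1 numerator df)
#' by default; `education_categorical = TRUE` switches education to a factor
#' (3 df). The cognitive score is never a permitted predictor: the screen is
#' restricted to variables whose causal arrow could point toward Brain2ICV.
#'
#' @param cohort A cohort table.
#' @param predictors Subset of `c("age", "sex", "apoe", "famad", "education")`.
#' @param education_categorical Fit education as an unordered factor.
#' @return A `data.frame` with columns `predictor`, `f_stat`, `p_value`,
#'   `df_num`, `df_den`.
#' @export
ols_anova <- function(cohort,
                      predictors = c("age", "sex", "apoe", "famad", "education"),
                      education_categorical = FALSE) {
  .check_cohort(cohort)
  allowed <- c("age", "sex", "apoe", "famad", "education")
  unknown <- setdiff(predictors, allowed)
  if (length(unknown)) {
    stop("unknown or not permitted predictor(s): ",
         paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  x <- as.data.frame(.analysis_matrix(cohort))
  rows <- lapply(predictors, function(p) {
    predictor <- if (p == "education" && education_categorical) {
      factor(x[[p]])
    } else {
      x[[p]]
    }
    if (length(unique(predictor)) < 2L) {
      stop("predictor '", p, "' is constant; F test undefined", call. = FALSE)
    }
    fit <- stats::lm(x$brain2icv ~ predictor)
    an <- stats::anova(fit)
    data.frame(predictor = p, f_stat = an[["F value"]][1],
               p_value = an[["Pr(>F)"]][1], df_num = an[["Df"]][1],
               df_den = an[["Df"]][2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
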