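# Independent oracles and small fixture builders used across the suite.

# Brute-force shortest-interval search: scan every contiguous window of
# ceiling(mass * n) sorted draws and return the narrowest (lowest start on
# ties). Independent of hdi()'s vectorized path.
hdi_brute <- function(x, mass = 0.94) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- c(lower = x[1], upper = x[k])
  best_width <- x[k] - x[1]
  i <- 2L
  while (i + k - 1L <= n) {
    w <- x[i + k - 1L] - x[i]
    if (w < best_width) {  # strict: ties keep the earlier window
      best_width <- w
      best <- c(lower = x[i], upper = x[i + k - 1L])
    }
    i <- i + 1L
  }
  best
}

# Brute-force one-way F statistic by explicit sums-of-squares decomposition
# (grouped predictor), df = (g - 1, n - g).
anova_brute_groups <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  groups <- unique(g)
  ssb <- 0
  ssw <- 0
  for (lev in groups) {
    yi <- y[g == lev]
    ssb <- ssb + length(yi) * (mean(yi) - grand)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# Brute-force F for a single continuous regressor: regression SS vs residual
# SS from the explicit moment sums, df = (1, n - 2).
anova_brute_slope <- function(y, x) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  ssr <- sxy^2 / sxx
  sse <- syy - ssr
  ssr / (sse / (length(y) - 2))
}

# Conjugate normal-normal posterior for a group mean with known sigma and
# prior N(m0, s0): returns c(mean, sd).
conjugate_posterior <- function(y, sigma, m0 = 0, s0 = 1) {
  n <- length(y)
  prec <- 1 / s0^2 + n / sigma^2
  m <- (m0 / s0^2 + sum(y) / sigma^2) / prec
  c(mean = m, sd = sqrt(1 / prec))
}

# Brute-force cycle check by path enumeration (depth-first search for a back
# edge), independent of the package's Kahn implementation.
has_cycle_dfs <- function(nodes, edges) {
  adj <- lapply(stats::setNames(nodes, nodes),
                function(n) edges$to[edges$from == n])
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(n) {
    if (state[[n]] == 1L) return(TRUE)
    if (state[[n]] == 2L) return(FALSE)
    state[[n]] <<- 1L
    for (m in adj[[n]]) if (visit(m)) return(TRUE)
    state[[n]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

# Write a minimal aseg.stats-dialect file; lines supplied in the given order.
write_stats_file <- function(path, tbv = NULL, etiv = NULL,
                             subjectname = NULL, extra = character(),
                             order = c("tbv", "etiv")) {
  lines <- c("# Title Segmentation Statistics")
  if (!is.null(subjectname)) lines <- c(lines, paste0("# subjectname ", subjectname))
  measure <- list(
    tbv = if (!is.null(tbv))
      sprintf("# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, %s, mm^3", tbv),
    etiv = if (!is.null(etiv))
      sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %s, mm^3", etiv)
  )
  for (key in order) if (!is.null(measure[[key]])) lines <- c(lines, measure[[key]])
  writeLines(c(lines, extra), path)
  path
}

# A fast sampler configuration for tests that exercise behaviour rather than
# high-precision posterior summaries.
quick_sampler <- function(seed, chains = 2L, draws = 800L, warmup = 400L) {
  sampler_config(chains = chains, draws = draws, warmup = warmup, seed = seed)
}

# Metadata view of a cohort (the cohort CSV schema minus brain2icv).
cohort_metadata <- function(cohort) {
  cohort[, c("subject_id", "age", "sex", "apoe", "famad", "education",
             "cog_score")]
}
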