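# Self-contained componentwise random-walk Metropolis sampler with
# Robbins-Monro scale adaptation during warmup. Works on an unconstrained
# parameterization (the caller transforms, e.g. sigma -> log sigma, and
# includes the Jacobian in log_post). Deliberately dependency-free: the
# models here have 3-5 parameters and Gaussian likelihoods reducible to
# sufficient statistics, where a tuned random walk mixes well.

#' Sampler configuration
#'
#' @param chains Number of independent chains (>= 2 for diagnostics).
#' @param draws Retained draws per chain after warmup.
#' @param warmup Adaptation iterations discarded per chain.
#' @param seed Integer seed; every stochastic element of a fit derives from it.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, draws = 2000L, warmup = 1000L,
                           seed = 1L) {
  stopifnot(chains >= 1L, draws >= 1L, warmup >= 0L)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "sampler_config")
}

# log_post: function(theta) -> log posterior density (unnormalized)
# init: center of the overdispersed chain starts
# scales: rough posterior scale per parameter (sets jitter + initial proposal)
# returns draws array [draws, chains, params]
.rw_metropolis <- function(log_post, init, scales, config,
                           target_accept = 0.44) {
  p <- length(init)
  stopifnot(length(scales) == p, all(scales > 0))
  out <- array(NA_real_, dim = c(config$draws, config$chains, p))
  set.seed(config$seed)
  total <- config$warmup + config$draws
  for (ch in seq_len(config$chains)) {
    cur <- init + stats::rnorm(p, 0, scales)  # overdispersed start
    lp_cur <- log_post(cur)
    tries <- 0L
    while (!is.finite(lp_cur) && tries < 100L) {
      cur <- init + stats::rnorm(p, 0, scales)
      lp_cur <- log_post(cur)
      tries <- tries + 1L
    }
    if (!is.finite(lp_cur)) {
      stop("could not find a finite-density starting point", call. = FALSE)
    }
    ls <- log(2.4 * scales)  # classic random-walk starting scale
    for (it in seq_len(total)) {
      for (j in seq_len(p)) {
        prop <- cur
        prop[j] <- cur[j] + exp(ls[j]) * stats::rnorm(1)
        lp_prop <- log_post(prop)
        accept <- is.finite(lp_prop) &&
          (lp_prop - lp_cur > log(stats::runif(1)))
        if (accept) {
          cur <- prop
          lp_cur <- lp_prop
        }
        if (it <= config$warmup) {
          # Robbins-Monro step toward the target acceptance rate
          ls[j] <- ls[j] + (as.numeric(accept) - target_accept) / sqrt(it)
        }
      }
      if (it > config$warmup) out[it - config$warmup, ch, ] <- cur
    }
  }
  out
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence.
#' Values at 1 indicate the chains agree; above ~1.01 they do not.
#'
#' @param mat Matrix of draws, iterations x chains.
#' @return The split R-hat (scalar); `NA` for fewer than 4 draws per chain
#'   or a constant parameter.
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(mat[seq_len(half), , drop = FALSE],
                 mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  chain_means <- colMeans(split)
  chain_vars <- apply(split, 2, stats::var)
  w <- mean(chain_vars)
  b <- nn * stats::var(chain_means)
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Effective sample size
#'
#' Multi-chain effective sample size from averaged within-chain
#' autocorrelations, truncated with Geyer's initial monotone positive
#' sequence.
#'
#' @param mat Matrix of draws, iterations x chains.
#' @return Estimated ESS (scalar); `NA` for degenerate input.
#' @export
effective_sample_size <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  max_lag <- n - 1L
  acov <- vapply(seq_len(m), function(ch) {
    a <- stats::acf(mat[, ch], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(max_lag + 1L))
  acov <- matrix(acov, nrow = max_lag + 1L)
  mean_acov <- rowMeans(acov)
  w <- mean_acov[1] * n / (n - 1)
  var_plus <- w * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(mat))
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  rho <- 1 - (w - mean_acov) / var_plus
  # Geyer: sum consecutive-lag pairs while positive, enforce monotonicity
  tau <- -1
  prev_pair <- Inf
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- max(tau, 1 / log10(n * m + 1))
  n * m / tau
}

# diagnostics table for a [draws, chains, params] array
.diagnose_draws <- function(draws, param_names) {
  data.frame(
    parameter = param_names,
    rhat = vapply(seq_along(param_names),
                  function(j) split_rhat(draws[, , j]), numeric(1)),
    ess = vapply(seq_along(param_names),
                 function(j) effective_sample_size(draws[, , j]), numeric(1)),
    stringsAsFactors = FALSE
  )
}
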