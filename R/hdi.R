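#' Highest-density interval of a sample
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' `n` sorted draws — the empirical shortest-interval algorithm. For a
#' unimodal posterior this estimates the interval in which every value has
#' higher posterior density than any value outside it. Ties in width are
#' broken toward the lowest starting draw, so the result is deterministic
#' given the draws.
#'
#' @param samples Numeric vector of at least 100 posterior draws.
#' @param mass Probability mass in (0, 1); default 0.94.
#' @return A list of class `hdi_interval` with fields `lower`, `upper`,
#'   `mass`.
#' @export
#' @examples
#' set.seed(1)
#' hdi(rnorm(10000))  # approx +/- 1.88 at mass 0.94
hdi <- function(samples, mass = 0.94) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("mass must be a single probability in (0, 1)", call. = FALSE)
  }
  x <- samples[is.finite(samples)]
  n <- length(x)
  if (n < 100L) {
    stop("hdi needs at least 100 draws (got ", n, ")", call. = FALSE)
  }
  k <- ceiling(mass * n)
  if (k < 2L) stop("too few draws to define the interval", call. = FALSE)
  x <- sort(x)
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)  # which.min takes the first (lowest-start) minimum
  structure(list(lower = x[i], upper = x[i + k - 1L], mass = mass),
            class = "hdi_interval")
}

#' @export
print.hdi_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HDI: [%.6g, %.6g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}
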