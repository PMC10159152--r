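#' Bivariate compound Poisson distribution for dual-observer counts
#'
#' The joint distribution of two independent counts of the same sample, each
#' a binomial thinning (detection probability `p`, shared between observers)
#' of one latent Poisson number of potentially visible objects with mean
#' `lambda`.  Equivalently `Y1 = U1 + W`, `Y2 = U2 + W` with
#' `U1, U2 ~ Poisson(lambda p (1 - p))` and `W ~ Poisson(lambda p^2)`
#' independent, so the marginals are `Poisson(lambda p)`, the covariance is
#' `lambda p^2` and the inter-observer correlation is `p`.
#'
#' @param y1,y2 Nonnegative integer counts (vectorised, recycled).
#' @param lambda Expected number of potentially visible objects, `>= 0`.
#' @param p Detection probability in `(0, 1]` (`p = 1` is the degenerate
#'   full-detection boundary, allowed for checks).
#'
#' @return `dual_count_logpmf()`: numeric vector of log probabilities.
#' @examples
#' dual_count_logpmf(1, 0, lambda = 2, p = 0.5)  # log(0.5 * exp(-1.5))
#' @export
dual_count_logpmf <- function(y1, y2, lambda, p) {
  n <- max(length(y1), length(y2), length(lambda), length(p))
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  lambda <- rep_len(lambda, n); p <- rep_len(p, n)
  if (any(y1 < 0 | y2 < 0 | y1 != round(y1) | y2 != round(y2))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]", call. = FALSE)
  dual_logpmf_cpp(as.integer(y1), as.integer(y2), lambda, p)
}

#' @describeIn dual_count_logpmf Draw i.i.d. count pairs from the
#'   trivariate decomposition.  Returns a tibble with columns `y1`, `y2`.
#' @param n Number of pairs to draw.
#' @param seed Optional seed for reproducibility.
#' @export
dual_count_sample <- function(lambda, p, n, seed = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (lambda < 0 || p <= 0 || p > 1) stop("invalid parameters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- rpois(n, lambda * p^2)
  tibble::tibble(y1 = rpois(n, lambda * p * (1 - p)) + w,
                 y2 = rpois(n, lambda * p * (1 - p)) + w)
}

#' @describeIn dual_count_logpmf Independent verification oracle: the
#'   probability computed by direct truncated summation over the latent
#'   count `N`, `sum_N Poisson(N; lambda) Binomial(y1; N, p)
#'   Binomial(y2; N, p)`.  Errors if the Poisson tail mass beyond `n_max`
#'   exceeds `tail_tol`.
#' @param n_max Truncation point for the latent-count sum.
#' @param tail_tol Maximum tolerated Poisson tail mass beyond `n_max`.
#' @export
dual_count_pmf_oracle <- function(y1, y2, lambda, p, n_max = 400,
                                  tail_tol = 1e-12) {
  stopifnot(length(y1) == 1, length(y2) == 1)
  if (lambda == 0) return(as.numeric(y1 == 0 && y2 == 0))
  tail <- stats::ppois(n_max, lambda, lower.tail = FALSE)
  if (tail > tail_tol) {
    stop(sprintf("n_max too small: Poisson tail mass %.3g > %.3g",
                 tail, tail_tol), call. = FALSE)
  }
  N <- max(y1, y2):n_max
  sum(dpois(N, lambda) * stats::dbinom(y1, N, p) * stats::dbinom(y2, N, p))
}
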