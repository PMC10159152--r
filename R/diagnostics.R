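# Convergence diagnostics: split R-hat and effective sample size, computed
# from the draws tibble (.chain / .iteration columns plus named parameters).

split_chains <- function(x) {
  # x: iterations x chains matrix -> halve each chain
  n <- nrow(x)
  n2 <- floor(n / 2)
  if (n2 < 2) return(x)
  cbind(x[seq_len(n2), , drop = FALSE],
        x[(n - n2 + 1):n, , drop = FALSE])
}

rhat_split <- function(x) {
  x <- split_chains(x)
  m <- ncol(x); n <- nrow(x)
  if (n < 3 || stats::sd(as.vector(x)) == 0) return(NA_real_)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, var))
  B <- n * var(mu)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_mean <- function(x) {
  # Effective sample size for the mean, averaged chain autocorrelations with
  # Geyer's initial positive-sequence truncation.
  x <- split_chains(x)
  m <- ncol(x); n <- nrow(x)
  if (n < 4) return(NA_real_)
  vars <- apply(x, 2, var)
  if (all(vars == 0)) return(NA_real_)
  max_lag <- min(n - 1, 200L)
  rho_ch <- sapply(seq_len(m), function(k) {
    a <- acf(x[, k], lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * vars[k]
  })
  mu <- colMeans(x)
  W <- mean(vars)
  B <- if (m > 1) var(mu) else 0
  var_plus <- (n - 1) / n * W + B
  # rho[t] is the combined autocorrelation at lag t - 1
  rho <- 1 - (W - rowMeans(rho_ch)) / var_plus
  # Geyer initial positive sequence: sum lag pairs (0,1), (2,3), ... while
  # each pair sum stays positive; tau = -1 + 2 * sum(pairs)
  tot <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    tot <- tot + pair
    t <- t + 2
  }
  tau_int <- max(-1 + 2 * tot, 1 / (m * n))
  ess <- m * n / tau_int
  max(1, min(ess, m * n))
}

ess_quantile <- function(x, prob) {
  q <- quantile(as.vector(x), prob, names = FALSE)
  ess_mean(1 * (x <= q))
}

mcmc_diagnostics <- function(draws, param_cols) {
  chains <- sort(unique(draws$.chain))
  mats <- lapply(param_cols, function(cc) {
    sapply(chains, function(k) draws[[cc]][draws$.chain == k])
  })
  tibble::tibble(
    parameter = param_cols,
    rhat = vapply(mats, rhat_split, numeric(1)),
    ess_bulk = vapply(mats, ess_mean, numeric(1)),
    ess_tail = vapply(mats, function(m) {
      min(ess_quantile(m, 0.05), ess_quantile(m, 0.95))
    }, numeric(1)))
}
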