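#' Pointwise leave-one-out cross-validation
#'
#' For every observation, the expected log predictive density under
#' leave-one-out cross-validation, computed by importance sampling over the
#' posterior draws.  Because the model has observation-level random effects,
#' the pointwise likelihood integrates out the held-out site's effect
#' vector: `p(y_i | beta, Sigma, p)` is a Monte Carlo average over
#' `MVN(0, Sigma)` draws for each posterior draw.  Importance ratios are
#' Pareto-smoothed; sites whose generalized-Pareto shape diagnostic exceeds
#' `k_threshold` are flagged as unreliable and, when `refit = TRUE`,
#' re-evaluated by an exact refit without that site.
#'
#' @param fit A `neuston_fit`.
#' @param n_eps Monte Carlo draws of the random-effect vector per posterior
#'   draw.
#' @param seed Seed for the integration draws.
#' @param k_threshold Flagging threshold on the Pareto shape.
#' @param refit Re-evaluate flagged sites by exact refit (slow).
#' @param ... Passed to the refits.
#'
#' @return A tibble of class `neuston_loo` with columns `site_id`, `elpd`
#'   (smoothed importance-sampling estimate), `pareto_k`, `flagged`, and
#'   `elpd_refit` (exact value where computed, otherwise `NA`).
#' @export
loo_pointwise <- function(fit, n_eps = 200, seed = 1L, k_threshold = 0.7,
                          refit = FALSE, ...) {
  stopifnot(inherits(fit, "neuston_fit"))
  S <- nrow(fit$draws)
  if (S < 100) stop("too few posterior draws for stable LOO estimates", call. = FALSE)
  ll <- site_loglik_matrix(fit, n_eps, seed)      # n x S
  n <- nrow(ll)
  elpd <- numeric(n); k <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_weights(-ll[i, ])
    k[i] <- ps$k
    lw <- ps$log_weights
    elpd[i] <- log_sum_exp(lw + ll[i, ]) - log_sum_exp(lw)
  }
  out <- tibble::tibble(site_id = fit$data$obs$site_id, elpd = elpd,
                        pareto_k = k, flagged = k > k_threshold,
                        elpd_refit = NA_real_)
  if (refit && any(out$flagged)) {
    for (i in which(out$flagged)) {
      rf <- refit_without(fit$data$obs, out$site_id[i],
                          categories = fit$categories, seed = seed, ...)
      ll_i <- site_loglik_one(rf, fit$data$obs[i, , drop = FALSE], n_eps,
                              stage_seed(seed, paste0("refit-loo", i)))
      out$elpd_refit[i] <- log_sum_exp(ll_i) - log(length(ll_i))
    }
  }
  class(out) <- c("neuston_loo", class(out))
  out
}

# n x S matrix of integrated per-site log likelihoods under the fit's draws
site_loglik_matrix <- function(fit, n_eps, seed) {
  cats <- fit$categories$category
  J <- length(cats); S <- nrow(fit$draws)
  beta_array <- fit_beta_array(fit)
  P <- dim(beta_array)[3]
  beta_flat <- matrix(NA_real_, S, J * P)
  for (j in seq_len(J)) for (c in seq_len(P)) {
    beta_flat[, (j - 1) * P + c] <- beta_array[, j, c]
  }
  sigma_array <- fit_sigma_array(fit)
  Lflat <- matrix(0, S, J * J)
  for (s in seq_len(S)) {
    Ls <- t(chol(sigma_array[s, , ] + diag(1e-10, J)))
    Lflat[s, ] <- as.vector(t(Ls))       # row-major rows of L
  }
  pmat <- if (fit$data$likelihood == 0) fit_p_matrix(fit) else
    matrix(1, S, J)
  set.seed(stage_seed(seed, "loo-integration"))
  site_marginal_loglik_cpp(fit$data$Y1, fit$data$Y2, fit$data$X, fit$data$A,
                           fit$data$likelihood, beta_flat, Lflat, pmat, n_eps)
}

# integrated log likelihood of one held-out observation under another fit
site_loglik_one <- function(fit, obs_row, n_eps, seed) {
  hold <- fit
  hold$data$X <- design_for_cols(log(obs_row$tracer), obs_row$region,
                                 fit$priors$design_cols, design_ref(fit))
  hold$data$A <- obs_row$swept_area
  cats <- fit$categories$category
  if (fit$data$likelihood == 0) {
    hold$data$Y1 <- matrix(as.integer(
      sapply(cats, function(cc) obs_row[[paste0(cc, "_obs1")]])), 1)
    hold$data$Y2 <- matrix(as.integer(
      sapply(cats, function(cc) obs_row[[paste0(cc, "_obs2")]])), 1)
  } else {
    hold$data$Y1 <- hold$data$Y2 <- matrix(as.integer(
      sapply(cats, function(cc) obs_row[[paste0(cc, "_count")]])), 1)
  }
  as.vector(site_loglik_matrix(hold, n_eps, seed))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pareto-smoothed importance sampling weights (log scale) and the
# generalized Pareto shape diagnostic of the ratio tail.
psis_weights <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  n_tail <- min(ceiling(0.2 * S), max(5, floor(3 * sqrt(S))))
  if (n_tail < 5 || S < 25) {
    return(list(log_weights = lw, k = NA_real_))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - n_tail + 1):S]
  cutoff <- lw[ord[S - n_tail]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  gpd <- gpd_fit(exceed)
  if (is.finite(gpd$k)) {
    # replace tail weights by expected order statistics of the fitted GPD
    q <- (seq_len(n_tail) - 0.5) / n_tail
    smoothed <- gpd_quantile(q, gpd$k, gpd$sigma) + exp(cutoff)
    lw[tail_idx[order(lw[tail_idx])]] <- pmin(log(smoothed), 0)
  }
  list(log_weights = lw, k = gpd$k)
}

# Zhang & Stephens (2009) empirical-Bayes generalized Pareto fit.  The
# shape k is scale-invariant, so the exceedances are rescaled by their
# maximum first; a tail so heavy that all but a handful of rescaled values
# underflow is reported as k = Inf (certainly unreliable).
gpd_fit <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 5) return(list(k = NA_real_, sigma = NA_real_))
  scale0 <- max(x)
  x <- sort(x / scale0)
  x <- x[x > 1e-14]
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / prior_bs / x[ceiling(n / 4 + 0.5)]
  lik <- function(b) {
    k <- mean(log1p(-b * x))
    n * (log(-b / k) - k - 1)
  }
  ls <- vapply(bs, lik, numeric(1))
  w <- exp(ls - max(ls)); w <- w / sum(w)
  b_hat <- sum(bs * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat * scale0
  # weak prior shrinkage toward k = 0.5 stabilises small tails
  k_hat <- (n * k_hat + 5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

gpd_quantile <- function(q, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-q))
  sigma * expm1(-k * log1p(-q)) / k
}
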