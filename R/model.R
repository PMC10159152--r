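#' Design matrix for log-density regression
#'
#' Builds the covariate matrix of the hierarchical model: an intercept, the
#' log tracer concentration, dummies for every region level except the
#' reference, and the dummies' interactions with log tracer.  For the
#' canonical two-region survey (`inside`/`outside`, reference `outside`)
#' this is `(1, x, z, x z)` with `z = 1` inside the patch, and the columns
#' are named `intercept`, `log_tracer`, `patch`, `log_tracer:patch`.
#'
#' @param x Log tracer concentration per site.
#' @param region Region codes per site (character/factor).
#' @param ref Reference level; default `"outside"` when present, otherwise
#'   the last sorted level.
#'
#' @return An `n x (2K)` numeric matrix with named columns, `K` the number
#'   of region levels.
#' @export
design_matrix <- function(x, region, ref = NULL) {
  stopifnot(length(x) == length(region), all(is.finite(x)))
  region <- as.character(region)
  lev <- sort(unique(region))
  if (is.null(ref)) ref <- if ("outside" %in% lev) "outside" else lev[length(lev)]
  if (!ref %in% lev) stop("reference level not present in region codes", call. = FALSE)
  others <- setdiff(lev, ref)
  X <- cbind(1, x)
  nm <- c("intercept", "log_tracer")
  for (lv in others) {
    X <- cbind(X, as.numeric(region == lv))
    nm <- c(nm, if (identical(sort(lev), c("inside", "outside"))) "patch"
            else paste0("region", lv))
  }
  for (lv in others) {
    X <- cbind(X, x * as.numeric(region == lv))
    nm <- c(nm, if (identical(sort(lev), c("inside", "outside")))
      "log_tracer:patch" else paste0("log_tracer:region", lv))
  }
  colnames(X) <- nm
  attr(X, "ref") <- ref
  attr(X, "levels") <- lev
  X
}

#' Linear predictor of log density
#'
#' `eta = beta0 + beta1 x + beta2 z + beta3 x z`: expected log density of
#' potentially visible objects at log tracer concentration `x`, inside
#' (`z = 1`) or outside (`z = 0`) the patch.
#'
#' @param beta Numeric vector of 4 coefficients (intercept, log-tracer
#'   slope, patch effect, interaction).
#' @param x Log tracer concentration (vectorised).
#' @param z Patch indicator in `{0, 1}` (vectorised).
#' @return Numeric vector of log densities.
#' @export
linear_predictor <- function(beta, x, z) {
  stopifnot(length(beta) == 4, all(z %in% c(0, 1)))
  beta[1] + beta[2] * x + beta[3] * z + beta[4] * x * z
}

#' Joint log density of the hierarchical model
#'
#' Reference implementation (plain R) of the unnormalised joint density on
#' the natural parameter scale: the dual-count likelihood with
#' `lambda_ij = A_i exp(eta_ij)` where `eta_ij = X_i beta_j + eps_ij`, the
#' multivariate normal density of each site's random-effect vector under
#' `Sigma = diag(tau) Omega diag(tau)`, and the log priors (without
#' transform Jacobians; the LKJ term is unnormalised).  With no
#' observations the value is the prior alone.
#'
#' @param obs Observation tibble (may have zero rows).
#' @param params List with elements `beta` (J x P), `tau`, `Omega`, `p`, and
#'   `eps` (n x J).
#' @param priors A [default_priors()] object.
#' @param categories Category table.
#' @return A scalar log density.
#' @export
joint_log_density <- function(obs, params, priors = default_priors(),
                              categories = neuston_categories()) {
  categories <- check_categories(categories)
  J <- nrow(categories)
  beta <- as.matrix(params$beta); tau <- params$tau
  Omega <- as.matrix(params$Omega); p <- params$p
  lp <- sum(dnorm(beta, priors$beta_loc, priors$beta_scale, log = TRUE)) +
    sum(-0.5 * (tau / priors$tau_scale)^2 - log(priors$tau_scale)) +
    (priors$lkj_eta - 1) * determinant(Omega, logarithm = TRUE)$modulus[1] +
    sum(dbeta(p, priors$p_shape1, priors$p_shape2, log = TRUE))
  n <- nrow(obs)
  if (n == 0) return(lp)
  eps <- as.matrix(params$eps)
  stopifnot(nrow(eps) == n, ncol(eps) == J)
  Sigma <- diag(tau, J) %*% Omega %*% diag(tau, J)
  Ls <- t(chol(Sigma))
  logdet <- 2 * sum(log(diag(Ls)))
  qf <- colSums(forwardsolve(Ls, t(eps))^2)
  lp <- lp + sum(-0.5 * (J * log(2 * pi) + logdet + qf))
  X <- design_for_cols(log(obs$tracer), obs$region, priors$design_cols,
                       ref = "outside")
  eta <- X %*% t(beta) + eps
  lam <- obs$swept_area * exp(eta)
  for (j in seq_len(J)) {
    cat_j <- categories$category[j]
    llj <- dual_count_logpmf(obs[[paste0(cat_j, "_obs1")]],
                             obs[[paste0(cat_j, "_obs2")]],
                             lam[, j], p[j])
    lp <- lp + sum(llj)
  }
  if (!is.finite(lp)) stop("non-finite joint log density", call. = FALSE)
  lp
}

# Moment-based initial values, jittered per chain (uses the current RNG
# stream, so chains started from different seeds differ).
make_init <- function(Y1, Y2, A, X, P, dual, jitter = 0.4) {
  n <- nrow(Y1); J <- ncol(Y1)
  if (n == 0) {
    mean_counts <- rep(1, J)
    A <- 1
  } else {
    mean_counts <- pmax(colMeans((Y1 + Y2) / 2), 0.25 / n)
  }
  b0 <- log(mean_counts / mean(A)) - log(0.5)   # assume p near 0.5 initially
  beta <- matrix(0, J, P)
  beta[, 1] <- b0
  beta <- beta + matrix(rnorm(J * P, 0, jitter), J, P)
  list(beta = beta,
       log_tau = rnorm(J, log(0.5), jitter / 2),
       y_z = rnorm(J * (J - 1) / 2, 0, jitter / 2),
       logit_p = if (dual) rnorm(J, 0, jitter / 2) else rep(0, J),
       U = matrix(rnorm(n * J, 0, 0.1), n, J))
}

draw_col_names <- function(categories, design_cols, dual, save_eps, site_ids) {
  J <- nrow(categories); cats <- categories$category
  nm <- c(as.vector(t(outer(cats, design_cols,
                            function(a, b) sprintf("beta[%s,%s]", a, b)))),
          sprintf("tau[%s]", cats))
  for (k in 2:J) for (m in 1:(k - 1)) {
    nm <- c(nm, sprintf("Omega[%s,%s]", cats[k], cats[m]))
  }
  if (dual) nm <- c(nm, sprintf("p[%s]", cats))
  if (save_eps) {
    for (i in seq_along(site_ids)) for (j in seq_len(J)) {
      nm <- c(nm, sprintf("eps[%s,%s]", site_ids[i], cats[j]))
    }
  }
  c(nm, "lp__")
}

run_chains <- function(X, A, Y1, Y2, likelihood, centered, priors,
                       chains, warmup, iter, thin, save_eps, seed,
                       categories, site_ids) {
  J <- ncol(Y1); P <- ncol(X)
  dual <- likelihood == 0L
  cols <- draw_col_names(categories, colnames(X), dual, save_eps, site_ids)
  all_draws <- vector("list", chains)
  accepts <- vector("list", chains)
  for (k in seq_len(chains)) {
    set.seed(stage_seed(seed, paste0("chain", k)))
    init <- make_init(Y1, Y2, A, X, P, dual)
    res <- mcmc_chain_cpp(X, A, Y1, Y2, likelihood, centered,
                          priors$beta_loc, priors$beta_scale,
                          priors$tau_scale, priors$lkj_eta,
                          priors$p_shape1, priors$p_shape2,
                          warmup, iter, thin, save_eps, init)
    d <- res$draws
    colnames(d) <- cols
    df <- tibble::as_tibble(d)
    df <- dplyr::mutate(df, .chain = k, .iteration = dplyr::row_number(),
                        .before = 1)
    all_draws[[k]] <- df
    accepts[[k]] <- res$accept
  }
  list(draws = dplyr::bind_rows(all_draws), accept = accepts)
}

new_neuston_fit <- function(draws, accept, obs, X, A, Y1, Y2, likelihood,
                            categories, priors, config) {
  param_cols <- setdiff(names(draws), c(".chain", ".iteration"))
  diag_cols <- param_cols[!startsWith(param_cols, "eps[") & param_cols != "lp__"]
  diagnostics <- mcmc_diagnostics(draws, diag_cols)
  structure(list(draws = draws, accept = accept,
                 data = list(obs = obs, X = X, A = A, Y1 = Y1, Y2 = Y2,
                             likelihood = likelihood),
                 categories = categories, priors = priors, config = config,
                 diagnostics = diagnostics),
            class = "neuston_fit")
}

#' Fit the dual-observer hierarchical model
#'
#' Samples the posterior of the multivariate hierarchical regression with
#' bivariate compound Poisson observation model by adaptive
#' Metropolis-within-Gibbs on an unconstrained reparametrization
#' (log scales, Cholesky-parametrized correlation matrix, logit detection
#' probabilities, non-centered observation-level effects by default).
#' Proposal scales adapt only during warmup; sampling is deterministic given
#' `seed` and the chain count.
#'
#' @param obs Observation tibble from [read_observations()] or
#'   [simulate_counts()].
#' @param categories Category table.
#' @param priors A [default_priors()] object.
#' @param chains,warmup,iter,thin Sampler schedule (post-warmup draws per
#'   chain = `iter / thin`).
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param centered Use the centered random-effect parametrization instead of
#'   the non-centered default.
#' @param save_eps Keep the per-site random-effect draws (needed for
#'   posterior predictive checks conditional on sites; increases memory).
#'
#' @return A `neuston_fit` object: posterior draws (tibble, one row per
#'   draw), sampler acceptance rates, data, priors and convergence
#'   diagnostics (split R-hat, bulk/tail effective sample size).
#' @seealso [fit_single_count()], [tidy.neuston_fit()], [delta_in_out()]
#' @export
fit_posterior <- function(obs, categories = neuston_categories(),
                          priors = NULL, chains = 4, warmup = 1000,
                          iter = 1000, thin = 1, seed = 1L,
                          centered = FALSE, save_eps = TRUE) {
  categories <- check_categories(categories)
  validate_observations(obs, categories)
  # zero observations is allowed: the sampler then explores the prior
  X <- if (nrow(obs) == 0) {
    design_for_cols(numeric(0), character(0),
                    c("intercept", "log_tracer", "patch", "log_tracer:patch"),
                    ref = "outside")
  } else {
    design_matrix(log(obs$tracer), obs$region)
  }
  if (is.null(priors)) {
    priors <- default_priors(categories, design_cols = colnames(X))
  }
  if (!identical(length(priors$design_cols), ncol(X))) {
    stop("prior design columns do not match the data's design matrix",
         call. = FALSE)
  }
  J <- nrow(categories)
  Y1 <- matrix(as.integer(unlist(
    lapply(categories$category, function(cc) obs[[paste0(cc, "_obs1")]]))),
    nrow(obs), J)
  Y2 <- matrix(as.integer(unlist(
    lapply(categories$category, function(cc) obs[[paste0(cc, "_obs2")]]))),
    nrow(obs), J)
  res <- run_chains(X, obs$swept_area, Y1, Y2, 0L, centered, priors,
                    chains, warmup, iter, thin, save_eps, seed,
                    categories, obs$site_id)
  new_neuston_fit(res$draws, res$accept, obs, X, obs$swept_area, Y1, Y2, 0L,
                  categories, priors,
                  list(chains = chains, warmup = warmup, iter = iter,
                       thin = thin, seed = seed, centered = centered,
                       save_eps = save_eps))
}

#' Fit the single-count Poisson variant
#'
#' The same hierarchical structure with a Poisson likelihood for one count
#' per site and category (no detection stage), and region dummies plus
#' their log-tracer interactions replacing the single patch indicator.
#' With two regions the design matrix reduces to the dual-count design.
#'
#' @param obs Tibble with `site_id`, `swept_area`, `region` (K >= 2 levels),
#'   `tracer` and one `<category>_count` column per category.
#' @param ref Reference region level for the dummies.
#' @inheritParams fit_posterior
#' @return A `neuston_fit` object (no detection-probability parameters).
#' @export
fit_single_count <- function(obs, categories = neuston_categories(),
                             ref = NULL, priors = NULL, chains = 4,
                             warmup = 1000, iter = 1000, thin = 1, seed = 1L,
                             centered = FALSE, save_eps = TRUE) {
  categories <- check_categories(categories)
  if (nrow(obs) < 1) stop("need at least one observation", call. = FALSE)
  # K = 1 (a single region, intercept + slope only) is permitted for
  # degenerate checks; the survey designs of interest have K >= 2.
  lev <- sort(unique(as.character(obs$region)))
  X <- if (length(lev) == 1) {
    m <- cbind(1, log(obs$tracer))
    colnames(m) <- c("intercept", "log_tracer")
    m
  } else {
    design_matrix(log(obs$tracer), obs$region, ref = ref)
  }
  if (is.null(priors)) {
    priors <- default_priors(categories, design_cols = colnames(X))
  }
  J <- nrow(categories)
  Y <- sapply(categories$category, function(cc) obs[[paste0(cc, "_count")]])
  Y <- matrix(as.integer(Y), nrow(obs), J)
  if (any(Y < 0)) stop("counts must be nonnegative", call. = FALSE)
  res <- run_chains(X, obs$swept_area, Y, Y, 1L, centered, priors,
                    chains, warmup, iter, thin, save_eps, seed,
                    categories, obs$site_id)
  new_neuston_fit(res$draws, res$accept, obs, X, obs$swept_area, Y, Y, 1L,
                  categories, priors,
                  list(chains = chains, warmup = warmup, iter = iter,
                       thin = thin, seed = seed, centered = centered,
                       save_eps = save_eps, ref = attr(X, "ref")))
}

#' @export
print.neuston_fit <- function(x, ...) {
  cat(sprintf("<neuston_fit> %s likelihood, %d sites, %d categories, %d draws (%d chains)\n",
              if (x$data$likelihood == 0) "dual-count" else "single-count",
              nrow(x$data$Y1), nrow(x$categories),
              nrow(x$draws), x$config$chains))
  bad <- x$diagnostics$rhat > 1.05
  cat(sprintf("  max split R-hat %.3f (%d of %d parameters > 1.05)\n",
              max(x$diagnostics$rhat, na.rm = TRUE), sum(bad, na.rm = TRUE),
              nrow(x$diagnostics)))
  invisible(x)
}

# --- draw extraction helpers ------------------------------------------------

fit_draw_matrix <- function(fit, prefix) {
  cols <- grep(paste0("^", prefix, "\\["), names(fit$draws), value = TRUE)
  as.matrix(fit$draws[cols])
}

# S x J x P array of regression coefficient draws
fit_beta_array <- function(fit) {
  cats <- fit$categories$category
  dc <- fit$priors$design_cols
  S <- nrow(fit$draws)
  out <- array(NA_real_, c(S, length(cats), length(dc)),
               dimnames = list(NULL, cats, dc))
  for (j in seq_along(cats)) for (c in seq_along(dc)) {
    out[, j, c] <- fit$draws[[sprintf("beta[%s,%s]", cats[j], dc[c])]]
  }
  out
}

# S x J x J array of covariance draws Sigma = diag(tau) Omega diag(tau)
fit_sigma_array <- function(fit) {
  cats <- fit$categories$category
  J <- length(cats); S <- nrow(fit$draws)
  tau <- sapply(cats, function(cc) fit$draws[[sprintf("tau[%s]", cc)]])
  out <- array(0, c(S, J, J), dimnames = list(NULL, cats, cats))
  for (j in seq_len(J)) out[, j, j] <- tau[, j]^2
  if (J > 1) {
    for (k in 2:J) for (m in 1:(k - 1)) {
      om <- fit$draws[[sprintf("Omega[%s,%s]", cats[k], cats[m])]]
      out[, k, m] <- out[, m, k] <- om * tau[, k] * tau[, m]
    }
  }
  out
}

fit_p_matrix <- function(fit) {
  cats <- fit$categories$category
  m <- sapply(cats, function(cc) fit$draws[[sprintf("p[%s]", cc)]])
  if (is.null(dim(m))) m <- matrix(m, 1, dimnames = list(NULL, cats))
  m
}
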