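#' Prior configuration for the hierarchical count model
#'
#' Weakly informative defaults on the log-density scale.  Regression
#' coefficients get independent normal priors; the intercept prior is wide
#' (`sd = 10`) because with swept areas of order 10^-3 km² the intercepts
#' must reach log densities spanning roughly 10^2 to 10^5 km^-2, while
#' slope, patch-effect and interaction priors are `normal(0, 2)`.
#' Random-effect scales get half-normal priors, the correlation matrix an
#' LKJ prior (concentration > 1 places mass toward the identity), and the
#' detection probabilities beta priors that keep them in the interior of
#' (0, 1).
#'
#' @param categories Category table; priors are per-category overridable.
#' @param design_cols Design-matrix column names (defaults to the
#'   two-region dual-count design).
#' @param beta_loc,beta_scale Numeric vectors of length `length(design_cols)`
#'   (recycled over categories) or J x P matrices of per-category values.
#' @param tau_scale Half-normal scale(s) for the random-effect standard
#'   deviations (length 1 or J).
#' @param lkj_eta LKJ concentration for the correlation matrix.
#' @param p_shape1,p_shape2 Beta prior shapes for the detection
#'   probabilities (length 1 or J).
#'
#' @return A list of class `prior_config`.
#' @export
default_priors <- function(categories = neuston_categories(),
                           design_cols = c("intercept", "log_tracer",
                                           "patch", "log_tracer:patch"),
                           beta_loc = 0,
                           beta_scale = c(10, rep(2, length(design_cols) - 1L)),
                           tau_scale = 1, lkj_eta = 2,
                           p_shape1 = 2, p_shape2 = 2) {
  categories <- check_categories(categories)
  J <- nrow(categories); P <- length(design_cols)
  expand <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(J, P))) stop(what, " matrix must be J x P", call. = FALSE)
      return(unname(x))
    }
    matrix(rep_len(x, P), J, P, byrow = TRUE)
  }
  out <- list(
    beta_loc = expand(beta_loc, "beta_loc"),
    beta_scale = expand(beta_scale, "beta_scale"),
    tau_scale = rep_len(tau_scale, J),
    lkj_eta = lkj_eta,
    p_shape1 = rep_len(p_shape1, J),
    p_shape2 = rep_len(p_shape2, J),
    design_cols = design_cols,
    categories = categories)
  if (any(out$beta_scale <= 0) || any(out$tau_scale <= 0) ||
      out$lkj_eta <= 0 || any(out$p_shape1 <= 0) || any(out$p_shape2 <= 0)) {
    stop("prior scales and concentrations must be positive", call. = FALSE)
  }
  structure(out, class = "prior_config")
}

# Sample one parameter set from the prior (natural scale).  Used by the
# prior pushforward and by prior-recovery checks.
prior_sample_params <- function(priors) {
  J <- nrow(priors$categories); P <- length(priors$design_cols)
  beta <- matrix(rnorm(J * P, priors$beta_loc, priors$beta_scale), J, P,
                 dimnames = list(priors$categories$category, priors$design_cols))
  tau <- abs(rnorm(J, 0, priors$tau_scale))
  Omega <- rlkj(J, priors$lkj_eta)
  p <- rbeta(J, priors$p_shape1, priors$p_shape2)
  list(beta = beta, tau = setNames(tau, priors$categories$category),
       Omega = Omega, p = setNames(p, priors$categories$category))
}

#' Sample a correlation matrix from the LKJ distribution
#'
#' Onion-method sampler: builds the matrix up one dimension at a time, the
#' new column drawn from a scaled beta radius and a uniform direction.
#'
#' @param J Dimension.
#' @param eta Concentration (> 0); `eta = 1` is uniform over correlation
#'   matrices, larger values concentrate near the identity.
#' @return A J x J correlation matrix.
#' @export
rlkj <- function(J, eta = 1) {
  stopifnot(J >= 1, eta > 0)
  if (J == 1) return(matrix(1, 1, 1))
  b <- eta + (J - 2) / 2
  r <- 2 * rbeta(1, b, b) - 1
  R <- matrix(c(1, r, r, 1), 2, 2)
  if (J == 2) return(R)
  for (k in 2:(J - 1)) {
    b <- b - 0.5
    y <- rbeta(1, k / 2, b)
    u <- rnorm(k); u <- u / sqrt(sum(u^2))
    w <- sqrt(y) * u
    Lk <- t(chol(R + diag(1e-12, k)))
    q <- as.vector(Lk %*% w)
    R <- rbind(cbind(R, q), c(q, 1))
  }
  dimnames(R) <- NULL
  R
}
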