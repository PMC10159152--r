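#' Covariate sample representing a region's tracer distribution
#'
#' Derived statistics are averaged over the distribution of log tracer
#' concentration within a region.  A covariate sample is a weighted set of
#' `(x = ln tracer, region)` points; by default the empirical tracer values
#' of the grid cells inside the region's mask with equal weights, or the
#' observed sites' values.
#'
#' @param x Log tracer concentrations.
#' @param region Region code attached to every point (single value or
#'   vector).
#' @param weights Optional nonnegative weights; normalised to sum to 1.
#' @return A tibble with columns `x`, `region`, `weight`.
#' @export
covariate_sample <- function(x, region, weights = NULL) {
  if (length(x) < 1) stop("covariate sample must be nonempty", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(x))
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  tibble::tibble(x = as.numeric(x),
                 region = rep_len(as.character(region), length(x)),
                 weight = weights / sum(weights))
}

#' @describeIn covariate_sample Covariate sample from the grid cells of a
#'   [derive_region_mask()] region (equal weights over cells in the mask).
#' @param field A [tracer_field()].
#' @param mask A `region_mask`.
#' @export
region_covariate_sample <- function(field, mask, region) {
  keep <- as.vector(mask$mask)
  if (!any(keep)) stop("region mask is empty", call. = FALSE)
  vals <- as.vector(field$values)[keep]
  covariate_sample(log(vals), region)
}

# Evaluate covariate points on a fitted design's named columns.  Unlike
# design_matrix() this works for samples holding a single region level
# (the reference region's dummy columns are simply zero).
design_for_cols <- function(x, region, design_cols, ref) {
  region <- rep_len(as.character(region), length(x))
  ok <- vapply(unique(region), function(lv) {
    lv == ref ||
      ("patch" %in% design_cols && lv == "inside") ||
      paste0("region", lv) %in% design_cols
  }, logical(1))
  if (!all(ok)) {
    stop("covariate sample region codes do not match the fitted design",
         call. = FALSE)
  }
  cols <- lapply(design_cols, function(col) {
    if (col == "intercept") rep(1, length(x))
    else if (col == "log_tracer") x
    else if (col == "patch") as.numeric(region == "inside")
    else if (col == "log_tracer:patch") x * (region == "inside")
    else if (startsWith(col, "log_tracer:region")) {
      x * (region == sub("^log_tracer:region", "", col))
    } else if (startsWith(col, "region")) {
      as.numeric(region == sub("^region", "", col))
    } else stop("unknown design column: ", col, call. = FALSE)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- design_cols
  X
}

# Weighted mean design row for a covariate sample, on the fit's design.
mean_design_row <- function(cov, design_cols, ref) {
  X <- design_for_cols(cov$x, cov$region, design_cols, ref)
  setNames(colSums(X * cov$weight), design_cols)
}

design_ref <- function(fit) {
  ref <- fit$config$ref
  if (is.null(ref)) ref <- "outside"
  ref
}

# Region-averaged expected log density per draw: S x J matrix.
region_average_eta <- function(beta_array, mrow) {
  S <- dim(beta_array)[1]; J <- dim(beta_array)[2]
  out <- matrix(0, S, J, dimnames = list(NULL, dimnames(beta_array)[[2]]))
  for (c in seq_along(mrow)) {
    out <- out + matrix(beta_array[, , c], nrow = S) * mrow[c]
  }
  out
}

#' Inside-outside contrast of expected log density
#'
#' For each posterior draw and category, the difference in expected log
#' density between the inside- and outside-patch regions, each averaged
#' over its region's tracer distribution.  With `m_in` and `m_out` the
#' weighted mean log tracer in the two regions, the closed form is
#' `Delta_j = beta2_j + beta1_j (m_in - m_out) + beta3_j m_in`; random
#' effects average to zero.  Delta does not involve the intercept or the
#' detection probabilities, so it is insensitive to absolute-density biases.
#'
#' @param fit A `neuston_fit` from [fit_posterior()].
#' @param cov_in,cov_out [covariate_sample()]s for the inside and outside
#'   regions (regions `"inside"` and `"outside"` respectively).
#'
#' @return A tibble with columns `.draw`, `category`, `delta`.
#' @export
delta_in_out <- function(fit, cov_in, cov_out) {
  stopifnot(inherits(fit, "neuston_fit"))
  if (!all(cov_in$region == "inside") || !all(cov_out$region == "outside")) {
    stop("cov_in must be an inside-region sample and cov_out an outside one",
         call. = FALSE)
  }
  beta_array <- fit_beta_array(fit)
  delta_core(beta_array, fit$priors$design_cols, design_ref(fit),
             cov_in, cov_out)
}

delta_core <- function(beta_array, design_cols, ref, cov_a, cov_b) {
  m_a <- mean_design_row(cov_a, design_cols, ref)
  m_b <- mean_design_row(cov_b, design_cols, ref)
  d <- region_average_eta(beta_array, m_a) - region_average_eta(beta_array, m_b)
  tibble::tibble(.draw = rep(seq_len(nrow(d)), times = ncol(d)),
                 category = rep(colnames(d), each = nrow(d)),
                 delta = as.vector(d))
}

#' Marginal correlation between two categories' log densities
#'
#' The correlation induced jointly by shared covariate variation and the
#' random-effect covariance: with `mu_j(x, z)` the linear predictor, the
#' total covariance over a region's covariate distribution is
#' `C_jk = Cov(mu_j, mu_k) + Sigma_jk` and
#' `rho = C_jk / sqrt(C_jj C_kk)`.  Covariate moments use the sample's
#' weights (population convention).
#'
#' @param fit A `neuston_fit`.
#' @param cov A [covariate_sample()] for the region (may mix region codes,
#'   e.g. the whole study region).
#' @param pairs Two-column character matrix (or vector of length 2) of
#'   category pairs; default every neuston taxon against `"plastic"`.
#'
#' @return A tibble with columns `.draw`, `category_a`, `category_b`, `rho`.
#' @export
marginal_correlation <- function(fit, cov, pairs = NULL) {
  stopifnot(inherits(fit, "neuston_fit"))
  pairs <- default_pairs(pairs, fit$categories)
  rho_core(fit_beta_array(fit), fit_sigma_array(fit),
           fit$priors$design_cols, design_ref(fit), cov, pairs)
}

default_pairs <- function(pairs, categories) {
  if (is.null(pairs)) {
    taxa <- categories$category[categories$is_neuston]
    pairs <- cbind(taxa, "plastic")
  }
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("correlation pairs must involve two distinct categories", call. = FALSE)
  }
  pairs
}

rho_core <- function(beta_array, sigma_array, design_cols, ref, cov, pairs) {
  S <- dim(beta_array)[1]
  cats <- dimnames(beta_array)[[2]]
  Xc <- design_for_cols(cov$x, cov$region, design_cols, ref)
  w <- cov$weight
  out <- vector("list", S)
  ja <- match(pairs[, 1], cats); jb <- match(pairs[, 2], cats)
  if (anyNA(ja) || anyNA(jb)) stop("unknown category in pairs", call. = FALSE)
  rho <- matrix(NA_real_, S, nrow(pairs))
  for (s in seq_len(S)) {
    B <- matrix(beta_array[s, , ], nrow = length(cats))
    M <- Xc %*% t(B)                       # points x categories
    mbar <- colSums(M * w)
    Mc <- sweep(M, 2, mbar)
    C <- t(Mc) %*% (Mc * w) + sigma_array[s, , ]
    dC <- diag(C)
    if (any(dC[c(ja, jb)] <= 0)) {
      stop("degenerate (zero) total variance for a requested category",
           call. = FALSE)
    }
    rho[s, ] <- C[cbind(ja, jb)] / sqrt(dC[ja] * dC[jb])
  }
  tibble::tibble(.draw = rep(seq_len(S), times = nrow(pairs)),
                 category_a = rep(pairs[, 1], each = S),
                 category_b = rep(pairs[, 2], each = S),
                 rho = as.vector(rho))
}

#' Marginal correlation between total log neuston density and log plastic
#'
#' The log of the summed neuston densities is a log-sum-exp of correlated
#' log densities, with no closed-form covariance, so the correlation is
#' computed by Monte Carlo per posterior draw: sample covariate points and
#' random effects, form `T = ln sum_j exp(eta_j)` over the neuston
#' categories and the reference category's `eta`, and take their empirical
#' correlation.
#'
#' @param fit A `neuston_fit`.
#' @param cov A [covariate_sample()].
#' @param reference Category correlated with the neuston total
#'   (default `"plastic"`).
#' @param n Monte Carlo draws per posterior draw (floor 100).
#' @param seed Seed for the Monte Carlo sub-streams.
#'
#' @return A tibble with columns `.draw`, `rho`.
#' @export
total_neuston_correlation <- function(fit, cov, reference = "plastic",
                                      n = 10000, seed = 1L) {
  stopifnot(inherits(fit, "neuston_fit"))
  if (n < 100) stop("n too small for a stable correlation (floor 100)", call. = FALSE)
  cats <- fit$categories$category
  taxa_idx <- which(fit$categories$is_neuston)
  if (length(taxa_idx) < 1) stop("no neuston categories", call. = FALSE)
  ref_idx <- match(reference, cats)
  if (is.na(ref_idx)) stop("unknown reference category", call. = FALSE)
  beta_array <- fit_beta_array(fit)
  sigma_array <- fit_sigma_array(fit)
  design_cols <- fit$priors$design_cols
  ref <- design_ref(fit)
  S <- dim(beta_array)[1]
  Xc <- design_for_cols(cov$x, cov$region, design_cols, ref)
  set.seed(stage_seed(seed, "total-neuston-correlation"))
  rho <- numeric(S)
  J <- length(cats)
  for (s in seq_len(S)) {
    idx <- sample.int(nrow(Xc), n, replace = TRUE, prob = cov$weight)
    B <- matrix(beta_array[s, , ], nrow = J)
    mu <- Xc[idx, , drop = FALSE] %*% t(B)
    Sig <- sigma_array[s, , ]
    Ls <- t(chol(Sig + diag(1e-10, J)))
    eps <- matrix(rnorm(n * J), n, J) %*% t(Ls)
    eta <- mu + eps
    tot <- log(rowSums(exp(eta[, taxa_idx, drop = FALSE])))
    rho[s] <- cor(tot, eta[, ref_idx])
  }
  tibble::tibble(.draw = seq_len(S), rho = rho)
}

#' Posterior probability that a statistic is positive
#'
#' @param draws Numeric vector of draws of the statistic.
#' @return The fraction of draws strictly greater than zero.
#' @examples
#' prob_positive(c(1, -1, 2, 3))  # 0.75
#' @export
prob_positive <- function(draws) {
  if (length(draws) < 1) stop("need at least one draw", call. = FALSE)
  mean(draws > 0)
}

#' Prior pushforward of the derived statistics
#'
#' Samples parameters from the prior and applies the same closed-form
#' contrast and correlation functionals as the posterior versions, giving
#' the prior distributions induced on `Delta` and `rho` for comparison with
#' their posteriors.
#'
#' @param priors A [default_priors()] object (4-column patch design).
#' @param cov_in,cov_out Covariate samples for the two regions.
#' @param n Number of prior draws.
#' @param seed Seed.
#' @param pairs Correlation pairs as in [marginal_correlation()].
#'
#' @return A list with tibbles `delta` (`.draw`, `category`, `delta`) and
#'   `rho` (`.draw`, `category_a`, `category_b`, `rho`).
#' @export
prior_pushforward <- function(priors, cov_in, cov_out, n = 2000, seed = 1L,
                              pairs = NULL) {
  cats <- priors$categories$category
  J <- length(cats); P <- length(priors$design_cols)
  pairs <- default_pairs(pairs, priors$categories)
  set.seed(stage_seed(seed, "prior-pushforward"))
  beta_array <- array(NA_real_, c(n, J, P),
                      dimnames = list(NULL, cats, priors$design_cols))
  sigma_array <- array(NA_real_, c(n, J, J), dimnames = list(NULL, cats, cats))
  for (s in seq_len(n)) {
    ps <- prior_sample_params(priors)
    beta_array[s, , ] <- ps$beta
    sigma_array[s, , ] <- diag(ps$tau, J) %*% ps$Omega %*% diag(ps$tau, J)
  }
  cov_all <- dplyr::bind_rows(cov_in, cov_out)
  cov_all$weight <- cov_all$weight / sum(cov_all$weight)
  list(delta = delta_core(beta_array, priors$design_cols, "outside",
                          cov_in, cov_out),
       rho = rho_core(beta_array, sigma_array, priors$design_cols, "outside",
                      cov_all, pairs))
}

#' Posterior fitted curves of detectable log density
#'
#' Summaries of `eta(x, z) + ln p_j` over the posterior draws along a grid
#' of log tracer concentrations: the expected log density of objects that
#' would be detected on a photograph (for single-count fits, of all
#' objects, since there is no detection stage).
#'
#' @param fit A `neuston_fit`.
#' @param x Grid of log tracer concentrations (nonempty).
#' @param region Region code for the curve (e.g. `"inside"`).
#' @param level Credible level for the equal-tailed band.
#' @param detectable Include `ln p_j` (dual-count fits only).
#'
#' @return A tibble with columns `category`, `x`, `mean`, `lower`, `upper`.
#' @export
fitted_curve <- function(fit, x, region = "inside", level = 0.95,
                         detectable = TRUE) {
  stopifnot(inherits(fit, "neuston_fit"))
  if (length(x) < 1) stop("x grid must be nonempty", call. = FALSE)
  beta_array <- fit_beta_array(fit)
  cats <- fit$categories$category
  design_cols <- fit$priors$design_cols
  Xg <- design_for_cols(x, rep(region, length(x)), design_cols,
                        design_ref(fit))
  common <- design_cols
  lp <- if (detectable && fit$data$likelihood == 0) {
    log(fit_p_matrix(fit))
  } else {
    matrix(0, dim(beta_array)[1], length(cats))
  }
  a <- (1 - level) / 2
  out <- list()
  for (j in seq_along(cats)) {
    B <- beta_array[, j, match(common, design_cols), drop = FALSE]
    eta <- matrix(B, ncol = length(common)) %*% t(Xg) + lp[, j]
    out[[j]] <- tibble::tibble(
      category = cats[j], x = x,
      mean = colMeans(eta),
      lower = apply(eta, 2, quantile, a, names = FALSE),
      upper = apply(eta, 2, quantile, 1 - a, names = FALSE))
  }
  dplyr::bind_rows(out)
}
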