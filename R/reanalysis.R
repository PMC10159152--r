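#' Fit the three-region single-count model
#'
#' The single-count Poisson variant for surveys whose sampling area is
#' divided into three regions (`A`, `B`, `C`): region dummies for the two
#' non-reference areas plus their log-tracer interactions, the same
#' observation-level multivariate random-effect structure, and one count
#' per site and category.  By default area `C` (inside the accumulation
#' zone) is the reference level so contrasts read as `C - A`, `C - B`,
#' `B - A`.
#'
#' @param obs Single-count tibble (see [simulate_single_counts()]); all
#'   three regions must be represented.
#' @param ref Reference region level (default `"C"`).
#' @inheritParams fit_posterior
#' @return A `neuston_fit`.
#' @export
fit_three_region <- function(obs, categories = neuston_categories(),
                             ref = "C", priors = NULL, chains = 4,
                             warmup = 1000, iter = 1000, thin = 1, seed = 1L,
                             centered = FALSE, save_eps = TRUE) {
  lev <- sort(unique(as.character(obs$region)))
  if (length(lev) != 3) {
    stop(sprintf("expected 3 region codes, found %d (%s); a region with no sites cannot be fitted",
                 length(lev), paste(lev, collapse = ", ")), call. = FALSE)
  }
  fit_single_count(obs, categories = categories, ref = ref, priors = priors,
                   chains = chains, warmup = warmup, iter = iter, thin = thin,
                   seed = seed, centered = centered, save_eps = save_eps)
}

#' Pairwise region contrasts of expected log density
#'
#' Differences in region-averaged expected log density between every pair
#' of regions, per posterior draw and category — the K-region
#' generalisation of [delta_in_out()].  Contrasts are antisymmetric:
#' `Delta(C - A) = -Delta(A - C)`.
#'
#' @param fit A `neuston_fit` from [fit_three_region()] (or any K-region
#'   single-count fit).
#' @param covs Named list of [covariate_sample()]s, one per region code.
#'
#' @return A tibble with columns `.draw`, `contrast` (e.g. `"C-A"`),
#'   `category`, `delta`.
#' @export
pairwise_region_delta <- function(fit, covs) {
  stopifnot(inherits(fit, "neuston_fit"))
  regs <- names(covs)
  if (is.null(regs) || any(!nzchar(regs))) {
    stop("covs must be a named list keyed by region code", call. = FALSE)
  }
  for (r in regs) {
    if (nrow(covs[[r]]) < 1) stop("empty covariate sample for region ", r, call. = FALSE)
    if (!all(covs[[r]]$region == r)) {
      stop("covariate sample for region ", r, " carries other region codes",
           call. = FALSE)
    }
  }
  beta_array <- fit_beta_array(fit)
  out <- list()
  ord <- sort(regs, decreasing = TRUE)   # C-A, C-B, B-A ordering for A/B/C
  for (a in seq_along(ord)) {
    for (b in seq_along(ord)) {
      if (b <= a) next
      d <- delta_core(beta_array, fit$priors$design_cols, design_ref(fit),
                      covs[[ord[a]]], covs[[ord[b]]])
      d$contrast <- paste0(ord[a], "-", ord[b])
      out[[length(out) + 1]] <- d
    }
  }
  dplyr::bind_rows(out) |> dplyr::relocate(".draw", "contrast")
}

#' Per-area marginal correlations
#'
#' [marginal_correlation()] restricted to each area's covariate
#' distribution.  Within one area the region dummies are constant, so only
#' log-tracer variation and the random-effect covariance contribute; with a
#' single tracer value the correlation reduces to the one implied by
#' `Sigma` alone.
#'
#' @param fit A `neuston_fit`.
#' @param covs Named list of [covariate_sample()]s, one per region code.
#' @param pairs Category pairs as in [marginal_correlation()].
#' @return A tibble with columns `area`, `.draw`, `category_a`,
#'   `category_b`, `rho`.
#' @export
per_area_correlation <- function(fit, covs, pairs = NULL) {
  out <- purrr::imap(covs, function(cov, area) {
    rr <- marginal_correlation(fit, cov, pairs = pairs)
    rr$area <- area
    rr
  })
  dplyr::bind_rows(out) |> dplyr::relocate("area")
}
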