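#' Posterior predictive check statistics
#'
#' For a subsample of posterior draws, simulates a full replicate dataset
#' from the generative model at the observed covariates and swept areas —
#' new random effects, new latent counts, new binomial thinnings, using the
#' same generative code as the synthetic-data simulator — and returns
#' per-category discrepancy statistics (fraction of zero counts, maximum
#' count, total count) for the replicates and the observed data.
#'
#' @param fit A `neuston_fit`.
#' @param n_rep Number of replicate datasets (posterior draws are thinned
#'   evenly to this many).
#' @param seed Seed.
#'
#' @return A list of class `neuston_ppc` with tibbles `replicated`
#'   (`rep`, `category`, `statistic`, `value`) and `observed`
#'   (`category`, `statistic`, `value`).
#' @export
posterior_predictive <- function(fit, n_rep = 200, seed = 1L) {
  stopifnot(inherits(fit, "neuston_fit"))
  n <- nrow(fit$data$Y1); J <- nrow(fit$categories)
  cats <- fit$categories$category
  dual <- fit$data$likelihood == 0
  beta_array <- fit_beta_array(fit)
  sigma_array <- fit_sigma_array(fit)
  pmat <- if (dual) fit_p_matrix(fit) else NULL
  S <- dim(beta_array)[1]
  keep <- unique(round(seq(1, S, length.out = min(n_rep, S))))
  set.seed(stage_seed(seed, "posterior-predictive"))
  stats_one <- function(Y1, Y2) {
    counts <- rbind(Y1, Y2)
    tibble::tibble(
      category = rep(cats, each = 3),
      statistic = rep(c("zero_fraction", "max_count", "total_count"), J),
      value = as.vector(rbind(colMeans(counts == 0),
                              apply(counts, 2, max),
                              colSums(counts))))
  }
  reps <- vector("list", length(keep))
  for (r in seq_along(keep)) {
    s <- keep[r]
    tau_s <- sqrt(diag(sigma_array[s, , ]))
    Omega_s <- stats::cov2cor(sigma_array[s, , ] + diag(1e-12, J))
    eps <- sim_random_effects(n, tau_s, Omega_s)
    eta <- fit$data$X %*% t(matrix(beta_array[s, , ], nrow = J)) + eps
    lam <- fit$data$A * exp(eta)
    if (dual) {
      cr <- r_dual_counts(lam, pmat[s, ])
      st <- stats_one(cr$Y1, cr$Y2)
    } else {
      Y <- matrix(rpois(n * J, lam), n, J)
      st <- stats_one(Y, Y)
    }
    st$rep <- r
    reps[[r]] <- st
  }
  observed <- if (dual) stats_one(fit$data$Y1, fit$data$Y2) else
    stats_one(fit$data$Y1, fit$data$Y1)
  structure(list(replicated = dplyr::bind_rows(reps) |>
                   dplyr::relocate("rep"),
                 observed = observed),
            class = "neuston_ppc")
}

#' @export
print.neuston_ppc <- function(x, ...) {
  tails <- ppc_tail_probabilities(x)
  cat(sprintf("<neuston_ppc> %d replicates; %d of %d observed statistics inside the central 95%% band\n",
              max(x$replicated$rep), sum(tails$inside_95), nrow(tails)))
  invisible(x)
}

#' @describeIn posterior_predictive Two-sided tail probabilities of the
#'   observed statistics within the replicate distributions.
#' @param ppc A `neuston_ppc`.
#' @export
ppc_tail_probabilities <- function(ppc) {
  ppc$replicated |>
    dplyr::left_join(ppc$observed, by = c("category", "statistic"),
                     suffix = c("", "_obs")) |>
    dplyr::group_by(.data$category, .data$statistic) |>
    dplyr::summarise(
      p_lower = mean(.data$value <= .data$value_obs[1]),
      p_upper = mean(.data$value >= .data$value_obs[1]),
      .groups = "drop") |>
    dplyr::mutate(inside_95 = .data$p_lower > 0.025 & .data$p_upper > 0.025)
}

#' Remove one observation and refit
#'
#' @param obs Observation tibble.
#' @param site_id Site to drop.
#' @param ... Passed to [fit_posterior()] (or [fit_single_count()] when
#'   `single = TRUE`).
#' @param single Refit the single-count variant instead.
#' @return A `neuston_fit` on the reduced data.
#' @export
refit_without <- function(obs, site_id, ..., single = FALSE) {
  reduced <- drop_site(obs, site_id)
  if (single) fit_single_count(reduced, ...) else fit_posterior(reduced, ...)
}

#' @describeIn refit_without Return the reduced data without refitting.
#' @export
drop_site <- function(obs, site_id) {
  if (!site_id %in% obs$site_id) {
    stop(sprintf("unknown site '%s'", site_id), call. = FALSE)
  }
  reduced <- obs[obs$site_id != site_id, , drop = FALSE]
  lost <- setdiff(unique(obs$region), unique(reduced$region))
  if (length(lost) > 0) {
    stop(sprintf("removing '%s' leaves region '%s' without observations",
                 site_id, lost[1]), call. = FALSE)
  }
  reduced
}

#' Recode one site's a-priori region membership
#'
#' Returns a copy of the data with the region code of one site changed and
#' everything else untouched — the sensitivity check for sites whose
#' geographic coding disagrees with their tracer concentration.
#'
#' @param obs Observation tibble.
#' @param site_id Site to recode.
#' @param new_region New region code.
#' @return The modified tibble.
#' @export
recode_region <- function(obs, site_id, new_region) {
  hit <- obs$site_id == site_id
  if (!any(hit)) stop(sprintf("unknown site '%s'", site_id), call. = FALSE)
  obs$region[hit] <- new_region
  obs
}

#' Parameter-recovery experiment
#'
#' Simulates datasets from known truth, fits each, and reports the
#' empirical coverage of equal-tailed 95% posterior intervals for the
#' log-tracer slopes, patch effects, detection probabilities and the
#' derived inside-outside contrasts, together with the normalised rank of
#' the truth within each posterior (uniform under calibration).
#'
#' @param scenario A [scenario_config()].
#' @param truth A [truth_params()].
#' @param n_rep Number of replicates.
#' @param seed Master seed.
#' @param chains,warmup,iter Sampler schedule per replicate fit.
#' @param level Credible level checked.
#'
#' @return A list with `results` (tibble: `rep`, `parameter`, `truth`,
#'   `lower`, `upper`, `covered`, `rank`) and `coverage` (tibble:
#'   `parameter_class`, `n`, `coverage`).
#' @export
recovery_experiment <- function(scenario, truth, n_rep = 20, seed = 1L,
                                chains = 2, warmup = 600, iter = 600,
                                level = 0.95) {
  field <- make_tracer_field(scenario)
  a <- (1 - level) / 2
  cats <- truth$categories$category
  rows <- list()
  for (r in seq_len(n_rep)) {
    sites <- select_sites(field, scenario,
                          seed = stage_seed(seed, paste0("sites", r)))
    obs <- simulate_counts(sites, truth, scenario,
                           seed = stage_seed(seed, paste0("counts", r)))
    fit <- fit_posterior(obs, truth$categories, chains = chains,
                         warmup = warmup, iter = iter,
                         seed = stage_seed(seed, paste0("fit", r)),
                         save_eps = FALSE)
    cov_in <- covariate_sample(log(obs$tracer[obs$region == "inside"]), "inside")
    cov_out <- covariate_sample(log(obs$tracer[obs$region == "outside"]), "outside")
    dd <- delta_in_out(fit, cov_in, cov_out)
    true_delta <- delta_core(
      array(truth$beta, c(1, dim(truth$beta)), dimnames = list(NULL, cats, colnames(truth$beta))),
      fit$priors$design_cols, "outside", cov_in, cov_out)
    check <- function(param, draws, tr) {
      tibble::tibble(rep = r, parameter = param, truth = tr,
                     lower = quantile(draws, a, names = FALSE),
                     upper = quantile(draws, 1 - a, names = FALSE),
                     covered = tr >= lower & tr <= upper,
                     rank = mean(draws < tr))
    }
    for (j in seq_along(cats)) {
      rows[[length(rows) + 1]] <- check(
        sprintf("beta1[%s]", cats[j]),
        fit$draws[[sprintf("beta[%s,log_tracer]", cats[j])]],
        truth$beta[j, 2])
      rows[[length(rows) + 1]] <- check(
        sprintf("beta2[%s]", cats[j]),
        fit$draws[[sprintf("beta[%s,patch]", cats[j])]],
        truth$beta[j, 3])
      rows[[length(rows) + 1]] <- check(
        sprintf("p[%s]", cats[j]),
        fit$draws[[sprintf("p[%s]", cats[j])]],
        truth$p[j])
      rows[[length(rows) + 1]] <- check(
        sprintf("delta[%s]", cats[j]),
        dd$delta[dd$category == cats[j]],
        true_delta$delta[true_delta$category == cats[j]])
    }
  }
  results <- dplyr::bind_rows(rows)
  coverage <- results |>
    dplyr::mutate(parameter_class = sub("\\[.*", "", .data$parameter)) |>
    dplyr::group_by(.data$parameter_class) |>
    dplyr::summarise(n = dplyr::n(), coverage = mean(.data$covered),
                     .groups = "drop")
  list(results = results, coverage = coverage)
}
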