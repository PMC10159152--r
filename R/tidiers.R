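#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `neuston_fit`.
#' @param pars Regular expression selecting parameters (default: all except
#'   the per-site random effects and `lp__`).
#' @param level Credible level for the equal-tailed interval.
#' @param ... Unused.
#'
#' @return A tibble with columns `parameter`, `mean`, `sd`, `lower`,
#'   `median`, `upper`, `rhat`, `ess_bulk`, `ess_tail`.
#' @method tidy neuston_fit
#' @export
tidy.neuston_fit <- function(x, pars = NULL, level = 0.95, ...) {
  cols <- setdiff(names(x$draws), c(".chain", ".iteration"))
  if (is.null(pars)) {
    cols <- cols[!startsWith(cols, "eps[") & cols != "lp__"]
  } else {
    cols <- grep(pars, cols, value = TRUE)
  }
  a <- (1 - level) / 2
  sums <- purrr::map_dfr(cols, function(cc) {
    v <- x$draws[[cc]]
    tibble::tibble(parameter = cc, mean = mean(v), sd = sd(v),
                   lower = quantile(v, a, names = FALSE),
                   median = median(v),
                   upper = quantile(v, 1 - a, names = FALSE))
  })
  dplyr::left_join(sums, x$diagnostics, by = "parameter")
}

#' One-row summary of a fitted model
#'
#' @param x A `neuston_fit`.
#' @param ... Unused.
#' @return A tibble with the sampler schedule, the worst split R-hat, the
#'   smallest effective sample sizes and the mean acceptance rates.
#' @method glance neuston_fit
#' @export
glance.neuston_fit <- function(x, ...) {
  acc <- colMeans(do.call(rbind, x$accept))
  tibble::tibble(
    n_sites = nrow(x$data$Y1),
    n_categories = nrow(x$categories),
    chains = x$config$chains,
    draws = nrow(x$draws),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_bulk = min(x$diagnostics$ess_bulk, na.rm = TRUE),
    min_ess_tail = min(x$diagnostics$ess_tail, na.rm = TRUE),
    accept_eps = acc[["eps"]],
    accept_beta = acc[["beta"]])
}

#' Plot posterior densities of the inside-outside contrasts
#'
#' One panel per category, solid posterior density, dashed vertical line at
#' zero and, when supplied, a dotted prior-pushforward density; each panel
#' is annotated with the posterior probability that the contrast is
#' positive.
#'
#' @param delta Tibble from [delta_in_out()].
#' @param prior Optional tibble from [prior_pushforward()]`$delta`.
#' @return A ggplot object.
#' @export
plot_delta <- function(delta, prior = NULL) {
  labs <- delta |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(p = prob_positive(.data$delta), .groups = "drop") |>
    dplyr::mutate(label = sprintf("P(Δ>0) = %.2f", .data$p))
  gg <- ggplot2::ggplot(delta, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~category, scales = "free") +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = expression(Delta~"(inside - outside expected log density)"),
                  y = "posterior density")
  if (!is.null(prior)) {
    gg <- gg + ggplot2::geom_density(data = prior, linetype = "dotted")
  }
  gg
}

#' Plot posterior densities of marginal correlations
#'
#' @param rho Tibble from [marginal_correlation()] (or the `rho` element of
#'   [prior_pushforward()]).
#' @return A ggplot object.
#' @export
plot_correlations <- function(rho) {
  labs <- rho |>
    dplyr::group_by(.data$category_a, .data$category_b) |>
    dplyr::summarise(p = prob_positive(.data$rho), .groups = "drop") |>
    dplyr::mutate(label = sprintf("P(ρ>0) = %.2f", .data$p))
  ggplot2::ggplot(rho, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~category_a, scales = "free_y") +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = expression(rho), y = "posterior density")
}

#' Plot fitted detectable log-density curves over the data
#'
#' @param fit A `neuston_fit`.
#' @param x Grid of log tracer concentrations; defaults to the observed
#'   range.
#' @param level Credible level of the band.
#' @return A ggplot object with one panel per category, posterior mean
#'   curves and equal-tailed bands for each region, and the observed mean
#'   log densities as points.
#' @export
plot_fitted_curves <- function(fit, x = NULL, level = 0.95) {
  obs <- fit$data$obs
  if (is.null(x)) {
    x <- seq(min(log(obs$tracer)), max(log(obs$tracer)), length.out = 50)
  }
  curves <- dplyr::bind_rows(
    dplyr::mutate(fitted_curve(fit, x, "inside", level), region = "inside"),
    dplyr::mutate(fitted_curve(fit, x, "outside", level), region = "outside"))
  dens <- density_from_counts(obs, fit$categories) |>
    dplyr::mutate(x = log(obs$tracer[match(.data$site_id, obs$site_id)]),
                  log_density = ifelse(.data$density > 0,
                                       log(.data$density), NA_real_))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, colour = .data$region)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$region), alpha = 0.2,
                         colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_point(data = dens,
                        ggplot2::aes(y = .data$log_density), size = 1,
                        na.rm = TRUE) +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = "ln tracer concentration",
                  y = expression("ln detectable density (km"^-2*")"))
}

#' @describeIn posterior_predictive Replicate-versus-observed densities per
#'   category and statistic.
#' @param object A `neuston_ppc`.
#' @param ... Unused.
#' @method autoplot neuston_ppc
#' @export
autoplot.neuston_ppc <- function(object, ...) {
  ggplot2::ggplot(object$replicated,
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(data = object$observed,
                        ggplot2::aes(xintercept = .data$value),
                        colour = "red") +
    ggplot2::facet_wrap(statistic ~ category, scales = "free") +
    ggplot2::labs(x = "statistic value", y = "replicates")
}

#' @describeIn tidy.neuston_fit Trace plot of selected parameters.
#' @param object A `neuston_fit`.
#' @method autoplot neuston_fit
#' @export
autoplot.neuston_fit <- function(object, pars = "^beta\\[.*log_tracer\\]$", ...) {
  cols <- grep(pars, names(object$draws), value = TRUE)
  long <- object$draws |>
    dplyr::select(dplyr::all_of(c(".chain", ".iteration", cols))) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.iteration, y = .data$value,
                                     colour = factor(.data$.chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain")
}
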