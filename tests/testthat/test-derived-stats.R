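# A one-draw coefficient array for closed-form checks
one_draw_beta <- function(values, cats = c("Velella", "plastic")) {
  P <- ncol(values)
  dimnames <- list(NULL, cats,
                   c("intercept", "log_tracer", "patch",
                     "log_tracer:patch")[seq_len(P)])
  array(values, c(1, length(cats), P), dimnames = dimnames)
}

test_that("the inside-outside contrast matches its closed form", {
  # beta1 = 1, beta2 = 0.5, beta3 = 0.2, m_in = -1, m_out = -2 -> 1.3
  ba <- one_draw_beta(matrix(c(9, 9, 1, 1, 0.5, 0.5, 0.2, 0.2), 2, 4))
  d <- neuston:::delta_core(ba, dimnames(ba)[[3]], "outside",
                            covariate_sample(-1, "inside"),
                            covariate_sample(-2, "outside"))
  expect_equal(d$delta, c(1.3, 1.3))

  # beta2 = beta3 = 0 and identical tracer distributions: exactly zero
  ba0 <- one_draw_beta(matrix(c(5, 2, 0.7, 0.7, 0, 0, 0, 0), 2, 4))
  d0 <- neuston:::delta_core(ba0, dimnames(ba0)[[3]], "outside",
                             covariate_sample(c(-1, -2), "inside"),
                             covariate_sample(c(-1, -2), "outside"))
  expect_equal(d0$delta, c(0, 0))

  # single shared tracer value, beta3 = 0: delta = beta2 exactly
  ba2 <- one_draw_beta(matrix(c(5, 2, 0.7, 0.3, 1.1, -0.4, 0, 0), 2, 4))
  d2 <- neuston:::delta_core(ba2, dimnames(ba2)[[3]], "outside",
                             covariate_sample(-1.5, "inside"),
                             covariate_sample(-1.5, "outside"))
  expect_equal(d2$delta, c(1.1, -0.4))

  # weighted covariate means are honoured
  ba3 <- one_draw_beta(matrix(c(0, 0, 1, 1, 0, 0, 0, 0), 2, 4))
  cov_in <- covariate_sample(c(-1, -3), "inside", weights = c(3, 1))
  cov_out <- covariate_sample(-2, "outside")
  d3 <- neuston:::delta_core(ba3, dimnames(ba3)[[3]], "outside",
                             cov_in, cov_out)
  expect_equal(d3$delta, rep((-1 * 0.75 + -3 * 0.25) - (-2), 2))

  expect_error(covariate_sample(numeric(0), "inside"), "nonempty")
})

test_that("delta and rho are invariant to recentring log tracer", {
  fit <- study_fit()
  cov_in <- covariate_sample(log(fit$data$obs$tracer[fit$data$obs$region == "inside"]),
                             "inside")
  cov_out <- covariate_sample(log(fit$data$obs$tracer[fit$data$obs$region == "outside"]),
                              "outside")
  d1 <- delta_in_out(fit, cov_in, cov_out)

  # recentring x by c is absorbed by beta0 <- beta0 + c beta1 and
  # beta2 <- beta2 + c beta3; apply the transform per draw and recompute
  shift <- 1.7
  fit2 <- fit
  for (cc in fit$categories$category) {
    b1 <- fit$draws[[sprintf("beta[%s,log_tracer]", cc)]]
    b3 <- fit$draws[[sprintf("beta[%s,log_tracer:patch]", cc)]]
    fit2$draws[[sprintf("beta[%s,intercept]", cc)]] <-
      fit$draws[[sprintf("beta[%s,intercept]", cc)]] + shift * b1
    fit2$draws[[sprintf("beta[%s,patch]", cc)]] <-
      fit$draws[[sprintf("beta[%s,patch]", cc)]] + shift * b3
  }
  cov_in_s <- covariate_sample(cov_in$x - shift, "inside")
  cov_out_s <- covariate_sample(cov_out$x - shift, "outside")
  d2 <- delta_in_out(fit2, cov_in_s, cov_out_s)
  expect_equal(d1$delta, d2$delta, tolerance = 1e-10)

  cov_all <- dplyr::bind_rows(cov_in, cov_out)
  cov_all$weight <- cov_all$weight / sum(cov_all$weight)
  cov_all_s <- dplyr::bind_rows(cov_in_s, cov_out_s)
  cov_all_s$weight <- cov_all_s$weight / sum(cov_all_s$weight)
  r1 <- marginal_correlation(fit, cov_all)
  r2 <- marginal_correlation(fit2, cov_all_s)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-10)
})

test_that("marginal correlation reduces to known limits", {
  cats2 <- neuston_categories(c("Velella", "plastic"), c(TRUE, FALSE))
  ba <- one_draw_beta(matrix(c(5, 8, 1, 1, 0, 0, 0, 0), 2, 4))

  # single covariate point: only Sigma contributes
  Sig <- array(c(1, 0.5, 0.5, 1), c(1, 2, 2))
  r <- neuston:::rho_core(ba, Sig, dimnames(ba)[[3]], "outside",
                          covariate_sample(-1, "outside"),
                          matrix(c("Velella", "plastic"), 1))
  expect_equal(r$rho, 0.5)

  # equal slopes, Sigma = 0, varying x: perfectly shared signal
  Sig0 <- array(0, c(1, 2, 2))
  r1 <- neuston:::rho_core(ba, Sig0, dimnames(ba)[[3]], "outside",
                           covariate_sample(c(-2, -1, 0), "outside"),
                           matrix(c("Velella", "plastic"), 1))
  expect_equal(r1$rho, 1)

  # degenerate zero total variance errors
  ba0 <- one_draw_beta(matrix(c(5, 8, 0, 0, 0, 0, 0, 0), 2, 4))
  expect_error(
    neuston:::rho_core(ba0, Sig0, dimnames(ba0)[[3]], "outside",
                       covariate_sample(c(-2, -1), "outside"),
                       matrix(c("Velella", "plastic"), 1)),
    "degenerate")
})

test_that("closed-form correlation matches a Monte Carlo sampling oracle", {
  fit <- study_fit()
  obs <- fit$data$obs
  cov_all <- covariate_sample(log(obs$tracer), obs$region)
  rho <- marginal_correlation(fit, cov_all)
  beta_array <- neuston:::fit_beta_array(fit)
  sigma_array <- neuston:::fit_sigma_array(fit)
  X <- neuston:::design_for_cols(cov_all$x, cov_all$region,
                                 fit$priors$design_cols, "outside")
  set.seed(50)
  n_mc <- 40000
  for (s in c(3, 211, 977)) {
    idx <- sample(nrow(X), n_mc, replace = TRUE)
    mu <- X[idx, ] %*% t(matrix(beta_array[s, , ], nrow = 6))
    eps <- matrix(rnorm(n_mc * 6), n_mc) %*% chol(sigma_array[s, , ])
    eta <- mu + eps
    oracle <- cor(eta[, 1], eta[, 6])     # Velella vs plastic
    closed <- rho$rho[rho$.draw == s & rho$category_a == "Velella"]
    mcse <- (1 - oracle^2) / sqrt(n_mc)
    expect_lt(abs(closed - oracle), 3 * mcse + 0.01)
  }
})

test_that("total-neuston correlation reduces correctly in limiting cases", {
  fit <- study_fit()
  obs <- fit$data$obs
  cov_all <- covariate_sample(log(obs$tracer), obs$region)

  # a fit restricted to one neuston category must reproduce the pairwise rho
  fit1 <- fit
  fit1$categories <- fit$categories
  fit1$categories$is_neuston <- fit$categories$category == "Velella"
  thin <- fit1
  keep <- seq(1, nrow(fit$draws), by = 16)
  thin$draws <- fit$draws[keep, ]
  tot <- total_neuston_correlation(thin, cov_all, n = 4000, seed = 2)
  pair <- marginal_correlation(thin, cov_all, pairs = c("Velella", "plastic"))
  expect_equal(mean(tot$rho), mean(pair$rho), tolerance = 0.02)
  expect_true(all(abs(tot$rho) <= 1))

  # dominance: inflate one category's intercept so it carries the total
  dom <- thin
  dom$categories <- fit$categories
  dom$draws[["beta[Janthina,intercept]"]] <-
    dom$draws[["beta[Janthina,intercept]"]] + 15
  tot_dom <- total_neuston_correlation(dom, cov_all, n = 4000, seed = 3)
  pair_dom <- marginal_correlation(dom, cov_all,
                                   pairs = c("Janthina", "plastic"))
  expect_equal(mean(tot_dom$rho), mean(pair_dom$rho), tolerance = 0.03)

  expect_error(total_neuston_correlation(fit, cov_all, n = 10), "floor")
})

test_that("prob_positive counts strictly positive draws", {
  expect_equal(prob_positive(c(1, -1, 2, 3)), 0.75)
  expect_equal(prob_positive(c(-2, -5)), 0)
  expect_equal(prob_positive(0), 0)
  set.seed(8)
  expect_equal(prob_positive(rnorm(20000)), 0.5, tolerance = 0.02)
  expect_error(prob_positive(numeric(0)), "at least one")
})

test_that("prior pushforward applies the same functionals to prior draws", {
  pr <- default_priors()
  cov_in <- covariate_sample(c(-0.5, -0.2), "inside")
  cov_out <- covariate_sample(c(-2.5, -2), "outside")
  pp <- prior_pushforward(pr, cov_in, cov_out, n = 800, seed = 3)
  expect_equal(sort(unique(pp$delta$category)),
               sort(neuston_categories()$category))
  expect_true(all(abs(pp$rho$rho) <= 1))
  # reproducible
  pp2 <- prior_pushforward(pr, cov_in, cov_out, n = 800, seed = 3)
  expect_identical(pp$delta, pp2$delta)

  # degenerate point-mass priors push forward to the closed-form point
  pr0 <- default_priors(beta_loc = c(0, 1, 0.5, 0.2), beta_scale = 1e-12,
                        tau_scale = 1e-12, p_shape1 = 2, p_shape2 = 2)
  pp0 <- prior_pushforward(pr0, covariate_sample(-1, "inside"),
                           covariate_sample(-2, "outside"), n = 50, seed = 1)
  expect_equal(pp0$delta$delta, rep(1.3, 300), tolerance = 1e-6)
})

test_that("fitted curves summarise detectable log density", {
  fit <- study_fit()
  xg <- seq(-3, 0, length.out = 7)
  fc <- fitted_curve(fit, xg, region = "inside")
  expect_equal(nrow(fc), 7 * 6)
  expect_true(all(fc$lower <= fc$mean & fc$mean <= fc$upper))

  # degenerate one-draw "posterior": zero band width
  one <- fit
  one$draws <- fit$draws[1, ]
  fc1 <- fitted_curve(one, xg, region = "outside")
  expect_equal(fc1$lower, fc1$upper)

  # without the detectability term the curve is higher by -ln p > 0
  fc_nd <- fitted_curve(fit, xg, region = "inside", detectable = FALSE)
  expect_true(all(fc_nd$mean > fc$mean))

  # bands widen outside the observed tracer range
  obs_x <- log(fit$data$obs$tracer)
  inside_band <- fitted_curve(fit, median(obs_x), region = "inside")
  outside_band <- fitted_curve(fit, min(obs_x) - 4, region = "inside")
  w_in <- inside_band$upper - inside_band$lower
  w_out <- outside_band$upper - outside_band$lower
  expect_true(all(w_out > w_in))
})
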