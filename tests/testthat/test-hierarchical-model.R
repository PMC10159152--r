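test_that("linear predictor and design matrix follow the patch regression", {
  expect_equal(linear_predictor(c(1, 0.5, 2, 0), x = 2, z = 1), 4)
  expect_equal(linear_predictor(rep(0, 4), x = 3.7, z = 1), 0)
  # z = 0: the interaction has no effect
  expect_equal(linear_predictor(c(1, 2, 3, 99), x = 1.5, z = 0),
               linear_predictor(c(1, 2, 3, -99), x = 1.5, z = 0))

  X <- design_matrix(c(-1, -2), c("inside", "outside"))
  expect_equal(colnames(X), c("intercept", "log_tracer", "patch",
                              "log_tracer:patch"))
  expect_equal(unname(X[1, ]), c(1, -1, 1, -1))
  expect_equal(unname(X[2, ]), c(1, -2, 0, 0))
})

test_that("joint log density decomposes as likelihood + effects + priors", {
  cats <- neuston_categories()
  pr <- default_priors(cats)
  tr <- default_truth()
  params <- list(beta = tr$beta, tau = rep(1e-6, 6), Omega = diag(6),
                 p = rep(0.6, 6), eps = matrix(0, 1, 6))

  # empty data: prior-only value, finite
  prior_only <- joint_log_density(empty_observations(), params, pr, cats)
  expect_true(is.finite(prior_only))

  # one site, Sigma -> 0: equals the dual-count likelihood at
  # lambda = A exp(eta) plus the prior terms plus the (degenerate) effect
  # density at zero — assembled by hand
  obs1 <- toy_observations(1, region = "inside", tracer = 0.5,
                           counts = matrix(3L, 1, 6))
  jld <- joint_log_density(obs1, params, pr, cats)
  eta <- as.vector(design_matrix(log(c(0.5, 1)),
                                 c("inside", "outside"))[1, ] %*% t(tr$beta))
  lik <- sum(dual_count_logpmf(3, 3, obs1$swept_area * exp(eta), 0.6))
  mvn_at_zero <- 6 * (-0.5 * log(2 * pi) - log(1e-6))
  expect_equal(jld, lik + prior_only + mvn_at_zero, tolerance = 1e-8)

  # permutation invariance over sites
  sv <- study_survey()
  set.seed(4)
  params_n <- list(beta = tr$beta, tau = tr$tau, Omega = tr$Omega, p = tr$p,
                   eps = matrix(rnorm(22 * 6, 0, 0.5), 22, 6))
  j1 <- joint_log_density(sv$obs, params_n, pr, cats)
  ord <- sample(22)
  j2 <- joint_log_density(sv$obs[ord, ],
                          modifyList(params_n,
                                     list(eps = params_n$eps[ord, ])),
                          pr, cats)
  expect_equal(j1, j2)
})

test_that("sampling is deterministic given the seed and chain count", {
  sv <- study_survey()
  f1 <- fit_posterior(sv$obs, chains = 1, warmup = 50, iter = 50, seed = 123)
  f2 <- fit_posterior(sv$obs, chains = 1, warmup = 50, iter = 50, seed = 123)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_posterior(sv$obs, chains = 1, warmup = 50, iter = 50, seed = 124)
  expect_false(identical(f3$draws, f1$draws))
})

test_that("the study-scale fit converges and attaches diagnostics", {
  fit <- study_fit()
  expect_s3_class(fit, "neuston_fit")
  expect_true(all(c("rhat", "ess_bulk", "ess_tail") %in%
                    names(fit$diagnostics)))
  expect_lt(max(fit$diagnostics$rhat, na.rm = TRUE), 1.35)
  expect_equal(nrow(fit$draws), 1600)
  # detection probabilities live in (0, 1)
  p_cols <- grep("^p\\[", names(fit$draws), value = TRUE)
  expect_true(all(sapply(fit$draws[p_cols], function(v) all(v > 0 & v < 1))))
  # correlations in [-1, 1]
  o_cols <- grep("^Omega\\[", names(fit$draws), value = TRUE)
  expect_true(all(sapply(fit$draws[o_cols], function(v) all(abs(v) <= 1))))
})

test_that("with no data the posterior reproduces the prior pushforward", {
  fit0 <- memo("prior_fit", function() {
    fit_posterior(empty_observations(), chains = 2, warmup = 500, iter = 1500,
                  seed = 4)
  })
  # independent prior-sampling oracle
  set.seed(11)
  pr <- default_priors()
  oracle <- replicate(4000, {
    ps <- neuston:::prior_sample_params(pr)
    c(beta1 = unname(ps$beta[1, 2]), tau = unname(ps$tau[1]),
      p = unname(ps$p[1]), omega = ps$Omega[2, 1])
  })
  cmp <- function(col, oracle_row, tol) {
    draws <- fit0$draws[[col]]
    for (q in c(0.25, 0.5, 0.75)) {
      expect_equal(quantile(draws, q, names = FALSE),
                   quantile(oracle[oracle_row, ], q, names = FALSE),
                   tolerance = tol)
    }
  }
  cmp("beta[Velella,log_tracer]", "beta1", 0.12)
  cmp("p[Velella]", "p", 0.05)
  cmp("tau[Velella]", "tau", 0.1)
  expect_equal(mean(fit0$draws[["Omega[Porpita,Velella]"]]), 0,
               tolerance = 0.05)
})

test_that("centered and non-centered parametrizations agree", {
  sv <- study_survey()
  f_nc <- study_fit()
  f_c <- memo("centered_fit", function() {
    fit_posterior(sv$obs, chains = 2, warmup = 800, iter = 800, seed = 17,
                  centered = TRUE, save_eps = FALSE)
  })
  for (col in c("beta[Velella,log_tracer]", "beta[plastic,patch]",
                "tau[Janthina]", "p[Porpita]")) {
    m1 <- mean(f_nc$draws[[col]]); m2 <- mean(f_c$draws[[col]])
    s1 <- sd(f_nc$draws[[col]])
    ess <- min(f_nc$diagnostics$ess_bulk[f_nc$diagnostics$parameter == col],
               f_c$diagnostics$ess_bulk[f_c$diagnostics$parameter == col],
               na.rm = TRUE)
    mcse <- s1 * sqrt(2 / max(ess, 10))
    expect_lt(abs(m1 - m2), 5 * mcse + 0.05 * s1)
  }
})

test_that("absolute density is weakly identified but beta0 + ln p is tight", {
  # The counts pin only the product lambda * p.  The detection probability
  # is identified through inter-observer agreement, whose information
  # content scales with the counts, so the beta0 / ln p confounding shows
  # itself in the low-count regime: a survey with means of about two
  # objects per photograph at a constant tracer concentration.
  cats <- neuston_categories()
  n <- 30
  sites <- tibble::tibble(site_id = sprintf("L%03d", 1:n), longitude = 0,
                          latitude = 0, region = "outside", tracer = 1)
  beta <- matrix(0, 6, 4); beta[, 1] <- 8
  tr <- truth_params(beta, rep(0.5, 6), diag(6), rep(0.5, 6), cats)
  obs <- simulate_counts(sites, tr, scenario_config(), seed = 4)
  fit <- memo("lowcount_fit", function() {
    fit_posterior(obs, chains = 2, warmup = 800, iter = 800, seed = 3,
                  save_eps = FALSE)
  })
  for (cc in c("Velella", "Porpita", "Janthina")) {
    b0 <- fit$draws[[sprintf("beta[%s,intercept]", cc)]]
    lp <- log(fit$draws[[sprintf("p[%s]", cc)]])
    # strong ridge: the sum is much tighter than the intercept alone
    expect_lt(var(b0 + lp) / var(b0), 0.6)
    expect_lt(cor(b0, lp), -0.5)
  }
})

test_that("single-count fit matches the Poisson conjugacy oracle", {
  cats <- neuston_categories()
  set.seed(1)
  n <- 40
  obs <- tibble::tibble(site_id = sprintf("S%02d", 1:n), longitude = 0,
                        latitude = 0, swept_area = runif(n, 8e-4, 1.7e-3),
                        region = "R", tracer = 1)
  dens_true <- 5000
  for (cc in cats$category) {
    obs[[paste0(cc, "_count")]] <- rpois(n, obs$swept_area * dens_true)
  }
  # tiny tau scale: effectively a fixed-effects Poisson regression; with
  # tracer = 1 the slope column is zero, so exp(beta0) is the density and
  # its posterior mean approaches total count / total area
  pr <- default_priors(cats, design_cols = c("intercept", "log_tracer"),
                       beta_scale = c(10, 2), tau_scale = 0.05)
  fit <- fit_single_count(obs, cats, priors = pr, chains = 2, warmup = 800,
                          iter = 800, seed = 3, save_eps = FALSE)
  for (cc in c("Velella", "plastic")) {
    conj <- sum(obs[[paste0(cc, "_count")]]) / sum(obs$swept_area)
    post <- mean(exp(fit$draws[[sprintf("beta[%s,intercept]", cc)]]))
    expect_equal(post, conj, tolerance = 0.03)
  }
})

test_that("a two-region single-count design reduces to the patch design", {
  sv <- study_survey()
  X2 <- design_matrix(log(sv$obs$tracer), sv$obs$region, ref = "outside")
  expect_equal(colnames(X2), c("intercept", "log_tracer", "patch",
                               "log_tracer:patch"))
  obs_sc <- sv$obs
  for (cc in neuston_categories()$category) {
    obs_sc[[paste0(cc, "_count")]] <- obs_sc[[paste0(cc, "_obs1")]]
  }
  fit <- fit_single_count(obs_sc, chains = 1, warmup = 30, iter = 30, seed = 1)
  expect_equal(fit$priors$design_cols, colnames(X2))
  expect_false(any(grepl("^p\\[", names(fit$draws))))
})
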