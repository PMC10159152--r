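# A shared three-region single-count dataset and fit
three_region_data <- function() {
  memo("three_region_data", function() {
    tr <- default_truth()
    scen <- scenario_config(n_inside = 8, n_outside = 14, seed = 3)
    f <- make_tracer_field(scen)
    s0 <- select_sites(f, scen)
    sites <- assign_three_regions(
      s0, thresholds = unname(quantile(s0$tracer, c(1 / 3, 2 / 3))))
    truth3 <- truth_params(cbind(tr$beta[, 1:2], 0.6, 1.2, 0, 0),
                           tr$tau, tr$Omega, tr$p)
    obs <- simulate_single_counts(sites, truth3, scen, ref = "C")
    covs <- lapply(setNames(c("A", "B", "C"), c("A", "B", "C")), function(r) {
      covariate_sample(log(sites$tracer[sites$region == r]), r)
    })
    list(truth = truth3, sites = sites, obs = obs, covs = covs,
         scenario = scen)
  })
}

three_region_fit <- function() {
  memo("three_region_fit", function() {
    fit_three_region(three_region_data()$obs, chains = 2, warmup = 800,
                     iter = 800, seed = 2)
  })
}

test_that("the three-region fit requires all regions and uses C as reference", {
  d <- three_region_data()
  expect_error(fit_three_region(d$obs[d$obs$region != "A", ]),
               "3 region codes")
  fit <- three_region_fit()
  expect_equal(fit$config$ref, "C")
  expect_equal(fit$priors$design_cols,
               c("intercept", "log_tracer", "regionA", "regionB",
                 "log_tracer:regionA", "log_tracer:regionB"))
  expect_false(any(grepl("^p\\[", names(fit$draws))))
  expect_lt(max(fit$diagnostics$rhat, na.rm = TRUE), 1.35)
})

test_that("planted region contrasts are recovered from synthetic data", {
  d <- three_region_data()
  fit <- three_region_fit()
  pd <- pairwise_region_delta(fit, d$covs)
  # truth: eta = b0 + b1 x + 0.6 [A] + 1.2 [B] (interactions zero), so the
  # true contrast C - B averaged over covariates is b1 (mC - mB) - 1.2
  b1 <- d$truth$beta[, 2]
  mB <- mean(d$covs$B$x); mC <- mean(d$covs$C$x)
  nB <- sum(d$sites$region == "B"); nC <- sum(d$sites$region == "C")
  for (cc in c("Velella", "Porpita", "plastic")) {
    true_cb <- b1[cc] * (mC - mB) - 1.2
    est <- pd$delta[pd$contrast == "C-B" & pd$category == cc]
    # the realised dataset's contrast differs from the ensemble truth by
    # the region means of the observation-level effects, sd ~ tau sqrt(1/nB
    # + 1/nC); the check must allow for both that and the posterior spread
    tau_cc <- d$truth$tau[cc]
    tot_sd <- sqrt(sd(est)^2 + tau_cc^2 * (1 / nB + 1 / nC))
    expect_lt(abs(mean(est) - true_cb), 3 * tot_sd)
  }
})

test_that("pairwise region contrasts are antisymmetric and zero when null", {
  fit <- three_region_fit()
  d <- three_region_data()
  pd <- pairwise_region_delta(fit, d$covs)
  expect_setequal(unique(pd$contrast), c("C-B", "C-A", "B-A"))
  # antisymmetry: recompute with swapped covariate order
  ca <- pd$delta[pd$contrast == "C-A"]
  cb <- pd$delta[pd$contrast == "C-B"]
  ba <- pd$delta[pd$contrast == "B-A"]
  expect_equal(ca, cb + ba, tolerance = 1e-10)

  # identical covariate distributions and zero region effects -> all zero
  ba0 <- array(c(3, 3, 0.5, 0.5, 0, 0, 0, 0, 0, 0, 0, 0), c(1, 2, 6),
               dimnames = list(NULL, c("Velella", "plastic"),
                               c("intercept", "log_tracer", "regionA",
                                 "regionB", "log_tracer:regionA",
                                 "log_tracer:regionB")))
  same <- covariate_sample(c(-1, -2), "A")
  sameB <- covariate_sample(c(-1, -2), "B")
  dd <- neuston:::delta_core(ba0, dimnames(ba0)[[3]], "C", same, sameB)
  expect_equal(dd$delta, c(0, 0))

  # matches a Monte Carlo averaging oracle (weighted resampling of the
  # covariate points instead of the closed-form mean)
  set.seed(6)
  covA <- covariate_sample(c(-2.5, -2, -1.8), "A", weights = c(1, 2, 1))
  covB <- covariate_sample(c(-1.2, -0.8), "B")
  ba1 <- array(c(3, 3, 0.5, 0.9, 0.7, -0.2, 0.2, 0.4, 0.1, 0, 0.05, 0),
               c(1, 2, 6), dimnames = dimnames(ba0))
  closed <- neuston:::delta_core(ba1, dimnames(ba1)[[3]], "C", covA, covB)
  mc_eta <- function(cov, j) {
    idx <- sample(nrow(cov), 2e5, replace = TRUE, prob = cov$weight)
    X <- neuston:::design_for_cols(cov$x[idx], cov$region[idx],
                                   dimnames(ba1)[[3]], "C")
    mean(X %*% ba1[1, j, ])
  }
  for (j in 1:2) {
    oracle <- mc_eta(covA, j) - mc_eta(covB, j)
    expect_equal(closed$delta[j], oracle, tolerance = 0.01)
  }
})

test_that("per-area correlations respect the covariance-only limit", {
  fit <- three_region_fit()
  d <- three_region_data()
  pa <- per_area_correlation(fit, d$covs, pairs = c("Velella", "plastic"))
  expect_setequal(unique(pa$area), c("A", "B", "C"))
  expect_true(all(abs(pa$rho) <= 1))

  # area with a single tracer value: rho equals the Sigma-implied
  # correlation draw by draw
  single <- list(C = covariate_sample(-0.4, "C"))
  pa1 <- per_area_correlation(fit, single, pairs = c("Velella", "plastic"))
  sig <- neuston:::fit_sigma_array(fit)
  implied <- sig[, 1, 6] / sqrt(sig[, 1, 1] * sig[, 6, 6])
  expect_equal(pa1$rho, implied, tolerance = 1e-10)
})

test_that("whole-region and per-area correlations can disagree in sign", {
  # constructed case: within each area the slope-driven signal is negative
  # (opposite slopes), but area means are aligned so pooling flips the sign
  cats <- c("Velella", "plastic")
  dn <- list(NULL, cats, c("intercept", "log_tracer", "regionA",
                           "log_tracer:regionA"))
  ba <- array(c(0, 0,      # intercepts
                1, -1,     # opposite tracer slopes
                -4, -4,    # region A shifts both strongly the same way
                0, 0), c(1, 2, 4), dimnames = dn)
  Sig0 <- array(1e-6 * diag(2), c(1, 2, 2))
  covA <- covariate_sample(c(-2.2, -2, -1.8), "A")
  covB <- covariate_sample(c(-0.2, 0, 0.2), "B")
  per_A <- neuston:::rho_core(ba, Sig0, dn[[3]], "B", covA,
                              matrix(cats, 1))
  per_B <- neuston:::rho_core(ba, Sig0, dn[[3]], "B", covB,
                              matrix(cats, 1))
  pooled_cov <- dplyr::bind_rows(covA, covB)
  pooled_cov$weight <- pooled_cov$weight / sum(pooled_cov$weight)
  pooled <- neuston:::rho_core(ba, Sig0, dn[[3]], "B", pooled_cov,
                               matrix(cats, 1))
  expect_lt(per_A$rho, 0)
  expect_lt(per_B$rho, 0)
  expect_gt(pooled$rho, 0)
})

test_that("duplicated single counts are not the dual-count likelihood", {
  # feeding one count y as the pair (y, y) with p < 1 is NOT the Poisson
  # single-count model: the dual model has its own correlation structure
  lam <- 4; p <- 0.6
  y <- 0:10
  dual <- dual_count_logpmf(y, y, lam, p)
  pois <- dpois(y, lam * p, log = TRUE)
  expect_false(isTRUE(all.equal(dual, pois, tolerance = 1e-6)))
  # and not merely a constant offset: the difference varies in y
  expect_gt(diff(range(dual - pois)), 0.5)
  # (equality only arises in the degenerate full-detection boundary)
  expect_equal(dual_count_logpmf(y, y, lam, 1), dpois(y, lam, log = TRUE))
})

test_that("collapsing two areas reproduces the two-region design", {
  d <- three_region_data()
  obs2 <- d$obs
  obs2$region[obs2$region %in% c("A", "B")] <- "outside"
  obs2$region[obs2$region == "C"] <- "inside"
  fit2 <- fit_single_count(obs2, ref = "outside", chains = 1, warmup = 30,
                           iter = 30, seed = 1)
  expect_equal(fit2$priors$design_cols,
               c("intercept", "log_tracer", "patch", "log_tracer:patch"))
})
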