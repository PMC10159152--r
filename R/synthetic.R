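#' Scenario configuration for the synthetic survey generator
#'
#' Defines the tracer grid, the smooth accumulation-zone ("patch") bump, the
#' survey design (sites inside/outside the patch) and the swept-area range.
#' Defaults emulate the scale of the motivating survey: 22 tows (12 inside
#' the patch, 10 outside), swept areas of order 10^-3 km² (a 0.9 m net mouth
#' towed for 30 min at 1-2 knots), and tracer-biased site placement.
#'
#' @param lon_range,lat_range Grid extent, degrees.
#' @param resolution Grid spacing, degrees.
#' @param patch_center `c(lon, lat)` of the concentration bump.
#' @param patch_width `c(lon_sd, lat_sd)` of the Gaussian bump, degrees.
#' @param amplitude Bump amplitude relative to `background` before
#'   normalisation; `amplitude = 0` gives a constant field.
#' @param background Constant background concentration (> 0 keeps the tracer
#'   strictly positive everywhere).
#' @param patch_threshold Dimensionless concentration at or above which a
#'   grid cell belongs to the generating patch mask (ground-truth region).
#' @param n_inside,n_outside Numbers of sites in/out of the patch mask.
#' @param area_range Swept-area range, km²; areas are drawn uniformly.
#' @param site_weight_power Site-selection weight is `tracer^power`
#'   (`power = 1` default): sites are placed preferentially where the tracer
#'   is high, mimicking a survey routed through predicted debris.
#' @param seed Master seed for the generator.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(lon_range = c(-160, -125), lat_range = c(22, 42),
                            resolution = 0.5,
                            patch_center = c(-142, 32),
                            patch_width = c(8, 5),
                            amplitude = 19, background = 0.05,
                            patch_threshold = 0.3,
                            n_inside = 12, n_outside = 10,
                            area_range = c(8e-4, 1.7e-3),
                            site_weight_power = 1,
                            seed = 1L) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (n_inside < 0 || n_outside < 0) stop("site counts must be >= 0", call. = FALSE)
  if (any(area_range <= 0)) stop("swept areas must be positive", call. = FALSE)
  if (background <= 0) stop("background concentration must be positive", call. = FALSE)
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, patch_center = patch_center,
                 patch_width = patch_width, amplitude = amplitude,
                 background = background, patch_threshold = patch_threshold,
                 n_inside = n_inside, n_outside = n_outside,
                 area_range = area_range,
                 site_weight_power = site_weight_power,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Ground-truth generative parameters
#'
#' Regression coefficients, random-effect covariance (as scales `tau` and
#' correlation matrix `Omega`) and detection probabilities used to simulate
#' survey data.  `beta` has one row per category; its columns are the
#' coefficients of the design matrix (for the two-region dual-count design:
#' intercept, log-tracer slope, patch effect, interaction).
#'
#' @param beta J x P numeric matrix (rows named by category).
#' @param tau Length-J nonnegative random-effect scales.
#' @param Omega J x J correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).
#' @param p Length-J detection probabilities in (0, 1].
#' @param categories Category table; row/element names are taken from it.
#'
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(beta, tau, Omega, p,
                         categories = neuston_categories()) {
  categories <- check_categories(categories)
  J <- nrow(categories)
  beta <- as.matrix(beta)
  if (nrow(beta) != J) stop("beta must have one row per category", call. = FALSE)
  if (length(tau) != J || any(tau < 0)) {
    stop("tau must be J nonnegative scales", call. = FALSE)
  }
  Omega <- as.matrix(Omega)
  if (!isTRUE(all.equal(Omega, t(Omega))) ||
      !isTRUE(all.equal(unname(diag(Omega)), rep(1, J)))) {
    stop("Omega must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("Omega must be positive semi-definite", call. = FALSE)
  }
  if (any(p <= 0 | p > 1)) stop("detection probabilities must be in (0, 1]", call. = FALSE)
  rownames(beta) <- categories$category
  structure(list(beta = beta, tau = setNames(as.numeric(tau), categories$category),
                 Omega = Omega, p = setNames(as.numeric(p), categories$category),
                 categories = categories),
            class = "truth_params")
}

#' @describeIn truth_params Default truth emulating the study's scale:
#'   abundant taxa at 10^3-10^5 km^-2 inside the patch, rare taxa
#'   (*Glaucus*, *Physalia*) with mostly zero counts, moderate positive
#'   tracer slopes and patch effects, exchangeable positive random-effect
#'   correlations, and detection probabilities 0.5-0.9.
#' @export
default_truth <- function(categories = neuston_categories()) {
  categories <- check_categories(categories)
  J <- nrow(categories)
  beta <- matrix(0, J, 4,
                 dimnames = list(categories$category,
                                 c("intercept", "log_tracer", "patch",
                                   "interaction")))
  defaults <- rbind(
    Velella  = c(9.5, 0.6, 1.0, 0.2),
    Porpita  = c(8.0, 0.5, 1.2, 0.0),
    Janthina = c(8.5, 0.7, 1.0, 0.1),
    Glaucus  = c(5.5, 0.4, 0.3, 0.0),
    Physalia = c(5.0, 0.3, 0.0, 0.0),
    plastic  = c(10.5, 0.8, 1.5, 0.2))
  hit <- intersect(rownames(defaults), categories$category)
  beta[hit, ] <- defaults[hit, ]
  tau <- setNames(rep(0.9, J), categories$category)
  tau[intersect(c("Glaucus", "Physalia"), categories$category)] <- 1.1
  Omega <- matrix(0.4, J, J); diag(Omega) <- 1
  p <- setNames(rep(0.7, J), categories$category)
  p[intersect(c("Velella", "plastic"), categories$category)] <- 0.85
  p[intersect(c("Glaucus", "Physalia"), categories$category)] <- 0.5
  truth_params(beta, tau, Omega, p, categories)
}

#' Generate a smooth synthetic tracer field
#'
#' Background plus a Gaussian concentration bump, normalised so the maximum
#' is 1 — a smooth, strictly positive stand-in for a surface-drift tracer
#' accumulation field.
#'
#' @param config A [scenario_config()].
#' @return A [tracer_field()].
#' @export
make_tracer_field <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lon <- seq(config$lon_range[1], config$lon_range[2], by = config$resolution)
  lat <- seq(config$lat_range[1], config$lat_range[2], by = config$resolution)
  bump <- outer(exp(-0.5 * ((lon - config$patch_center[1]) / config$patch_width[1])^2),
                exp(-0.5 * ((lat - config$patch_center[2]) / config$patch_width[2])^2))
  values <- config$background * (1 + config$amplitude * bump)
  tracer_field(lon, lat, values, normalize = TRUE)
}

#' Select tracer-biased survey sites
#'
#' Samples `n_inside` grid cells from the patch mask (tracer at or above
#' `patch_threshold`) and `n_outside` cells from its complement, each without
#' replacement with probability proportional to `tracer^site_weight_power` —
#' so site placement is biased toward high concentrations, as in a survey
#' routed through the predicted accumulation zone.
#'
#' @param field A [tracer_field()].
#' @param config A [scenario_config()].
#' @param seed Seed; defaults to the scenario seed.
#'
#' @return A tibble with columns `site_id`, `longitude`, `latitude`,
#'   `region` (`"inside"`/`"outside"`, from the generating mask), `tracer`.
#' @export
select_sites <- function(field, config, seed = config$seed) {
  stopifnot(inherits(field, "tracer_field"), inherits(config, "scenario_config"))
  grid <- as_tibble.tracer_field(field)
  inside <- grid$tracer >= config$patch_threshold
  if (sum(inside) < config$n_inside) {
    stop("patch mask too small for the requested number of inside sites",
         call. = FALSE)
  }
  if (sum(!inside) < config$n_outside) {
    stop("too few cells outside the patch mask", call. = FALSE)
  }
  set.seed(seed)
  w <- grid$tracer^config$site_weight_power
  pick <- function(idx, n) {
    if (n == 0) return(integer(0))
    idx[sample.int(length(idx), n, replace = FALSE, prob = w[idx])]
  }
  rows <- c(pick(which(inside), config$n_inside),
            pick(which(!inside), config$n_outside))
  tibble::tibble(
    site_id = sprintf("SIM_%03d", seq_along(rows)),
    longitude = grid$lon[rows],
    latitude = grid$lat[rows],
    region = ifelse(inside[rows], "inside", "outside"),
    tracer = grid$tracer[rows])
}

# Draw observation-level random effects: n x J matrix, rows iid MVN(0, Sigma)
# with Sigma = diag(tau) %*% Omega %*% diag(tau).
sim_random_effects <- function(n, tau, Omega) {
  J <- length(tau)
  L <- t(chol(Omega + diag(1e-12, J)))
  Z <- matrix(rnorm(n * J), n, J)
  sweep(Z %*% t(L), 2, tau, "*")
}

# Latent Poisson counts plus two independent binomial thinnings.  This is
# the single generative implementation shared by the simulator and the
# posterior predictive machinery.
r_dual_counts <- function(lambda, p) {
  n <- nrow(lambda); J <- ncol(lambda)
  N <- matrix(rpois(n * J, lambda), n, J)
  P <- matrix(p, n, J, byrow = TRUE)
  Y1 <- matrix(rbinom(n * J, N, P), n, J)
  Y2 <- matrix(rbinom(n * J, N, P), n, J)
  list(Y1 = Y1, Y2 = Y2, N = N)
}

#' Simulate a dual-observer survey dataset
#'
#' For each site `i`, draws random effects `eps_i ~ MVN(0, Sigma)`, forms
#' the linear predictor `eta_ij = X_i beta_j + eps_ij` with covariates
#' `x = ln tracer` and `z = 1` inside the patch, draws the latent count
#' `N_ij ~ Poisson(A_i exp(eta_ij))`, and thins it twice independently with
#' the category's detection probability to give the two observers' counts.
#'
#' @param sites Site tibble from [select_sites()] (columns `site_id`,
#'   `longitude`, `latitude`, `region`, `tracer`).
#' @param truth A [truth_params()] with 4-column `beta`.
#' @param config A [scenario_config()] (swept-area range, seed).
#' @param seed Seed; defaults to the scenario seed plus one so that site
#'   selection and counting use distinct streams.
#'
#' @return An observation tibble in the format of [read_observations()].
#' @export
simulate_counts <- function(sites, truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(truth, "truth_params"), inherits(config, "scenario_config"))
  if (ncol(truth$beta) != 4) {
    stop("dual-count simulation needs a 4-column beta (intercept, slope, patch, interaction)",
         call. = FALSE)
  }
  if (any(sites$tracer <= 0)) stop("tracer must be positive at all sites", call. = FALSE)
  n <- nrow(sites); J <- nrow(truth$categories)
  set.seed(seed)
  A <- runif(n, config$area_range[1], config$area_range[2])
  # canonical patch design; handles site sets drawn from a single region
  X <- design_for_cols(log(sites$tracer), sites$region,
                       c("intercept", "log_tracer", "patch",
                         "log_tracer:patch"), ref = "outside")
  eps <- sim_random_effects(n, truth$tau, truth$Omega)
  eta <- X %*% t(truth$beta) + eps
  counts <- r_dual_counts(A * exp(eta), truth$p)
  obs <- tibble::tibble(
    site_id = sites$site_id,
    longitude = sites$longitude,
    latitude = sites$latitude,
    date = as.Date("2019-06-15") + seq_len(n) - 1L,
    net_type = rep(c("manta", "neuston"), length.out = n),
    swept_area = A,
    region = sites$region,
    tracer = sites$tracer)
  for (j in seq_len(J)) {
    obs[[paste0(truth$categories$category[j], "_obs1")]] <- counts$Y1[, j]
    obs[[paste0(truth$categories$category[j], "_obs2")]] <- counts$Y2[, j]
  }
  obs
}

#' Simulate a single-count, K-region survey dataset
#'
#' One laboratory count per site and category (no photographic detection
#' stage): `N_ij ~ Poisson(A_i exp(eta_ij))` with region dummies (and their
#' log-tracer interactions) replacing the single patch indicator.
#'
#' @param sites Site tibble with a `region` column holding K >= 2 levels and
#'   a positive `tracer` column.
#' @param truth A [truth_params()] whose `beta` has `2 * K` columns matching
#'   [design_matrix()]'s layout for the chosen reference level.
#' @param config A [scenario_config()].
#' @param ref Reference region level for the dummies.
#' @param seed Seed.
#'
#' @return A tibble with site metadata and one `<category>_count` column per
#'   category.
#' @export
simulate_single_counts <- function(sites, truth, config, ref = NULL,
                                   seed = config$seed + 2L) {
  stopifnot(inherits(truth, "truth_params"), inherits(config, "scenario_config"))
  levels_r <- sort(unique(sites$region))
  if (length(levels_r) < 2) stop("need at least 2 region codes", call. = FALSE)
  X <- design_matrix(log(sites$tracer), sites$region, ref = ref)
  if (ncol(truth$beta) != ncol(X)) {
    stop(sprintf("beta has %d columns but the %d-region design needs %d",
                 ncol(truth$beta), length(levels_r), ncol(X)), call. = FALSE)
  }
  n <- nrow(sites); J <- nrow(truth$categories)
  set.seed(seed)
  A <- runif(n, config$area_range[1], config$area_range[2])
  eps <- sim_random_effects(n, truth$tau, truth$Omega)
  eta <- X %*% t(truth$beta) + eps
  Y <- matrix(rpois(n * J, A * exp(eta)), n, J)
  obs <- tibble::tibble(
    site_id = if ("site_id" %in% names(sites)) sites$site_id
              else sprintf("SIM_%03d", seq_len(n)),
    longitude = sites$longitude,
    latitude = sites$latitude,
    swept_area = A,
    region = sites$region,
    tracer = sites$tracer)
  for (j in seq_len(J)) {
    obs[[paste0(truth$categories$category[j], "_count")]] <- Y[, j]
  }
  obs
}

#' Assign three survey areas by tracer concentration
#'
#' Splits sites into areas `A` (lowest tracer), `B` (peripheral) and `C`
#' (inside the accumulation zone) by the tracer thresholds given, emulating
#' a three-region survey design.
#'
#' @param sites Site tibble with a `tracer` column.
#' @param thresholds Two increasing cut points on dimensionless tracer
#'   concentration: below the first is `A`, between is `B`, at or above the
#'   second is `C`.
#' @return `sites` with its `region` column replaced by `"A"`/`"B"`/`"C"`.
#' @export
assign_three_regions <- function(sites, thresholds = c(0.1, 0.3)) {
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  sites$region <- cut(sites$tracer, c(-Inf, thresholds, Inf),
                      labels = c("A", "B", "C"), right = FALSE)
  sites$region <- as.character(sites$region)
  sites
}
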