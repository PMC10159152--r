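# Shared fixtures: everything is generated in code, and the expensive
# posterior fits are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

study_scenario <- function(seed = 1L) scenario_config(seed = seed)

study_survey <- function(seed = 1L) {
  memo(paste0("survey", seed), function() {
    scen <- study_scenario(seed)
    field <- make_tracer_field(scen)
    sites <- select_sites(field, scen)
    obs <- simulate_counts(sites, default_truth(), scen)
    list(scenario = scen, field = field, sites = sites, obs = obs)
  })
}

# A study-scale dual-count fit reused across test files (2 chains keeps it
# quick; diagnostics on this fit are checked once below where it is built).
study_fit <- function() {
  memo("study_fit", function() {
    sv <- study_survey()
    fit_posterior(sv$obs, chains = 2, warmup = 800, iter = 800, seed = 7)
  })
}

# Empty observation table with the canonical columns
empty_observations <- function(categories = neuston_categories()) {
  obs <- tibble::tibble(site_id = character(0), longitude = numeric(0),
                        latitude = numeric(0), date = as.Date(character(0)),
                        net_type = character(0), swept_area = numeric(0),
                        region = character(0), tracer = numeric(0))
  for (cc in categories$category) {
    obs[[paste0(cc, "_obs1")]] <- integer(0)
    obs[[paste0(cc, "_obs2")]] <- integer(0)
  }
  obs
}

# Small hand-buildable observation table (n rows, constant counts unless
# overridden)
toy_observations <- function(n = 3, categories = neuston_categories(),
                             region = rep(c("inside", "outside"), length.out = n),
                             tracer = seq(0.2, 0.8, length.out = n),
                             counts = NULL) {
  obs <- tibble::tibble(
    site_id = sprintf("TOY_%03d", seq_len(n)),
    longitude = seq(-150, -140, length.out = n),
    latitude = seq(28, 34, length.out = n),
    date = as.Date("2019-07-01") + seq_len(n),
    net_type = rep(c("manta", "neuston"), length.out = n),
    swept_area = rep(1e-3, n),
    region = region,
    tracer = tracer)
  for (j in seq_len(nrow(categories))) {
    cc <- categories$category[j]
    obs[[paste0(cc, "_obs1")]] <- if (is.null(counts)) rep(2L, n) else counts[, j]
    obs[[paste0(cc, "_obs2")]] <- if (is.null(counts)) rep(3L, n) else counts[, j]
  }
  obs
}
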