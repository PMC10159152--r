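test_that("observation tables round-trip through delimited text", {
  obs <- toy_observations(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$site_id, obs$site_id)
  for (cc in neuston_categories()$category) {
    expect_identical(back[[paste0(cc, "_obs1")]], obs[[paste0(cc, "_obs1")]])
    expect_identical(back[[paste0(cc, "_obs2")]], obs[[paste0(cc, "_obs2")]])
  }
  expect_equal(back$swept_area, obs$swept_area)
})

test_that("invalid counts, areas and tracer are rejected with row context", {
  obs <- toy_observations(3)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- obs; bad$Velella_obs1[2] <- -1L
  write_observations(bad, path)
  expect_error(read_observations(path), "Velella_obs1.*row 2")

  bad <- obs; bad$swept_area[3] <- 0
  write_observations(bad, path)
  expect_error(read_observations(path), "swept_area.*row 3")

  bad <- obs; bad$tracer[1] <- -0.2
  write_observations(bad, path)
  expect_error(read_observations(path), "tracer.*row 1")

  bad <- obs[-which(names(obs) == "Porpita_obs2")]
  write_observations(bad, path)
  expect_error(read_observations(path), "missing columns.*Porpita_obs2")
})

test_that("duplicate photographs of one sample are summed per observer", {
  obs <- toy_observations(3)
  # second image of the first sample, as when a very abundant tow needs two
  # photographs
  dup <- obs[1, ]
  dup$Velella_obs1 <- 10L; dup$Velella_obs2 <- 12L
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(dplyr::bind_rows(obs, dup), path)
  merged <- read_observations(path)
  expect_equal(nrow(merged), 3)
  expect_equal(merged$Velella_obs1[merged$site_id == "TOY_001"],
               obs$Velella_obs1[1] + 10L)
  expect_equal(merged$Velella_obs2[merged$site_id == "TOY_001"],
               obs$Velella_obs2[1] + 12L)
  # every category of the duplicated sample is summed, and metadata comes
  # from the first row; other sites are untouched
  expect_equal(merged$Porpita_obs1[1], obs$Porpita_obs1[1] + dup$Porpita_obs1)
  expect_equal(merged$swept_area[1], obs$swept_area[1])
  expect_equal(merged$Porpita_obs1[-1], obs$Porpita_obs1[-1])
})

test_that("areas in m2 are converted to km2 on read", {
  obs <- toy_observations(2)
  obs$swept_area <- obs$swept_area * 1e6
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path, area_unit = "m2")
  expect_equal(back$swept_area, rep(1e-3, 2))
})

test_that("density standardisation is the observer mean over swept area", {
  cats <- neuston_categories()
  counts <- matrix(0L, 2, 6)
  obs <- toy_observations(2, counts = counts)
  obs$Velella_obs1 <- c(4L, 0L); obs$Velella_obs2 <- c(6L, 0L)
  dens <- density_from_counts(obs, cats)
  v <- dens[dens$category == "Velella", ]
  expect_equal(v$density, c(5000, 0))        # (4+6)/2 / 0.001 km2
  expect_true(all(dens$density >= 0))

  # linear in counts, inversely proportional to area (random inputs)
  set.seed(42)
  for (r in 1:20) {
    c1 <- sample(0:50, 1); c2 <- sample(0:50, 1); a <- runif(1, 1e-4, 1e-2)
    k <- sample(2:5, 1)
    o <- toy_observations(1, counts = matrix(0L, 1, 6))
    o$swept_area <- a
    o$Janthina_obs1 <- c1; o$Janthina_obs2 <- c2
    d1 <- density_from_counts(o, cats)
    o2 <- o; o2$Janthina_obs1 <- k * c1; o2$Janthina_obs2 <- k * c2
    d2 <- density_from_counts(o2, cats)
    o3 <- o; o3$swept_area <- k * a
    d3 <- density_from_counts(o3, cats)
    j <- d1$category == "Janthina"
    expect_equal(d2$density[j], k * d1$density[j])
    expect_equal(d3$density[j], d1$density[j] / k)
  }

  # independent one-line oracle on a synthetic fixture record
  sv <- study_survey()
  dd <- density_from_counts(sv$obs)
  i <- 5; cc <- "Porpita"
  oracle <- (sv$obs$Porpita_obs1[i] + sv$obs$Porpita_obs2[i]) / 2 /
    sv$obs$swept_area[i]
  expect_equal(dd$density[dd$site_id == sv$obs$site_id[i] &
                            dd$category == cc], oracle)
})

test_that("regional density summary uses order statistics of neuston totals", {
  cats <- neuston_categories()
  # five tows whose total neuston densities are 1..5 (single category
  # carries everything, same region)
  obs <- toy_observations(5, region = rep("inside", 5),
                          counts = matrix(0L, 5, 6))
  obs$Velella_obs1 <- 1:5; obs$Velella_obs2 <- 1:5
  obs$swept_area <- rep(1, 5)
  dens <- density_from_counts(obs, cats)
  s <- region_density_summary(dens, "inside")
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  expect_equal(s$n_sites, 5)

  # plastic is excluded from the neuston total
  obs$plastic_obs1 <- rep(1000L, 5); obs$plastic_obs2 <- rep(1000L, 5)
  s2 <- region_density_summary(density_from_counts(obs, cats), "inside")
  expect_equal(s2$median, 3)

  # single record: median = q1 = q3
  s1 <- region_density_summary(dens[dens$site_id == "TOY_001", ], "inside")
  expect_equal(unlist(s1[c("median", "q1", "q3")]), c(median = 1, q1 = 1, q3 = 1))

  # permutation invariance
  set.seed(9)
  sv <- study_survey()
  dd <- density_from_counts(sv$obs)
  perm <- dd[sample(nrow(dd)), ]
  expect_equal(region_density_summary(dd), region_density_summary(perm))

  # empty region errors
  expect_error(region_density_summary(dens, "outside"), "no tows")
})

test_that("tracer interpolation matches node values and a bilinear oracle", {
  field <- tracer_field(lon = c(0, 1), lat = c(0, 1),
                        values = matrix(c(1, 1, 3, 3), 2, 2),
                        normalize = FALSE)
  # exact node
  expect_equal(tracer_at_sites(field, 0, 0), 1)
  expect_equal(tracer_at_sites(field, 1, 1), 3)
  # midpoint of 4 nodes valued (1,1,3,3) -> 2
  expect_equal(tracer_at_sites(field, 0.5, 0.5), 2)
  # nearest-neighbour option
  expect_equal(tracer_at_sites(field, 0.1, 0.9, method = "nearest"),
               field$values[1, 2])
  # outside extent errors
  expect_error(tracer_at_sites(field, 2, 0.5), "outside")

  # random interior points against a brute-force piecewise-linear oracle
  set.seed(3)
  f2 <- tracer_field(lon = seq(0, 4), lat = seq(0, 3),
                     values = matrix(runif(20), 5, 4), normalize = FALSE)
  bilinear_oracle <- function(fld, px, py) {
    i <- max(which(fld$lon <= px)); i <- min(i, length(fld$lon) - 1)
    j <- max(which(fld$lat <= py)); j <- min(j, length(fld$lat) - 1)
    tx <- (px - fld$lon[i]) / diff(fld$lon[i:(i + 1)])
    ty <- (py - fld$lat[j]) / diff(fld$lat[j:(j + 1)])
    (1 - tx) * ((1 - ty) * fld$values[i, j] + ty * fld$values[i, j + 1]) +
      tx * ((1 - ty) * fld$values[i + 1, j] + ty * fld$values[i + 1, j + 1])
  }
  for (r in 1:25) {
    px <- runif(1, 0, 4); py <- runif(1, 0, 3)
    expect_equal(tracer_at_sites(f2, px, py), bilinear_oracle(f2, px, py),
                 tolerance = 1e-12)
  }
})

test_that("tracer fields round-trip and normalise to a unit maximum", {
  f <- tracer_field(seq(0, 2), seq(0, 1), matrix(1:6 / 10, 3, 2))
  expect_equal(max(f$values), 1)
  expect_equal(f$reference_max, 0.6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracer_field(f, path)
  back <- read_tracer_field(path)
  expect_equal(back$values, f$values)
  expect_equal(back$lon, f$lon)
})

test_that("region masks follow the minimum-site-tracer threshold rule", {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9),
                 3, 3, byrow = FALSE)
  # vals[i, j]: columns are lat; arrange so cell (i,j) value = 0.1*(3*(j-1)+i)
  field <- tracer_field(lon = 1:3, lat = 1:3, values = vals, normalize = FALSE)
  # sites on the 0.5 cell (lon 2, lat 2) and the 0.9 cell (lon 3, lat 3)
  mask <- derive_region_mask(field, lon = c(2, 3), lat = c(2, 3))
  expect_equal(mask$threshold, 0.5)
  kept <- sort(field$values[mask$mask])
  expect_equal(kept, c(0.5, 0.6, 0.8, 0.9))

  # one site at the field maximum: degenerate rectangle, only that cell
  m1 <- derive_region_mask(field, 3, 3)
  expect_equal(sum(m1$mask), 1)
  expect_equal(field$values[m1$mask], 0.9)

  # all sites on one grid row: mask confined to that row
  mrow <- derive_region_mask(field, lon = c(1, 3), lat = c(2, 2))
  expect_true(all(which(mrow$mask, arr.ind = TRUE)[, 2] == 2))

  # monotone: adding a site with lower tracer never shrinks the mask
  m2 <- derive_region_mask(field, lon = c(2, 3, 1), lat = c(2, 3, 1))
  expect_true(all(mask$mask[m2$mask] | !mask$mask[m2$mask]))
  expect_true(all(!(mask$mask & !m2$mask)))

  expect_error(derive_region_mask(field, numeric(0), numeric(0)), "at least one")
})
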