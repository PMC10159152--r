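#' Read a net-tow observation table
#'
#' One row per photographed net tow: site metadata, swept area, a-priori
#' region code, dimensionless tracer concentration, and a pair of counts
#' (two independent observers) for every object category.  Count columns are
#' named `<category>_obs1` and `<category>_obs2`; other column names can be
#' remapped through `col_map`.
#'
#' Rows sharing a `site_id` are photographs of the same sample (for example
#' a tow photographed on two images because its contents were too abundant
#' for one); their counts are summed per observer into a single observation
#' unit, keeping the first row's metadata.
#'
#' @param path Delimited text file (comma default).
#' @param categories Category table from [neuston_categories()].
#' @param col_map Optional named character vector mapping canonical names
#'   (`site_id`, `longitude`, `latitude`, `date`, `net_type`, `swept_area`,
#'   `region`, `tracer`, and the count columns) to the file's column names.
#' @param area_unit Unit of the swept-area column: `"km2"` (internal unit)
#'   or `"m2"` (converted on read).
#' @param delim Field delimiter.
#'
#' @return A tibble of validated observations, one row per tow, in file
#'   order (first appearance for merged duplicates), with `swept_area` in
#'   km².
#' @export
read_observations <- function(path, categories = neuston_categories(),
                              col_map = NULL, area_unit = c("km2", "m2"),
                              delim = ",") {
  area_unit <- match.arg(area_unit)
  categories <- check_categories(categories)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  canonical <- c("site_id", "longitude", "latitude", "date", "net_type",
                 "swept_area", "region", "tracer", count_cols(categories))
  if (!is.null(col_map)) {
    hit <- match(unname(col_map), names(df))
    if (anyNA(hit)) {
      stop("col_map names columns absent from the file: ",
           paste(col_map[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    names(df)[hit] <- names(col_map)
  }
  missing_cols <- setdiff(canonical, names(df))
  if (length(missing_cols) > 0) {
    stop("observation file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[canonical]
  df$site_id <- as.character(df$site_id)
  df$date <- as.Date(df$date)
  if (area_unit == "m2") df$swept_area <- df$swept_area / 1e6
  validate_observations(df, categories)
  for (col in count_cols(categories)) df[[col]] <- as.integer(df[[col]])
  merge_duplicate_sites(df, categories)
}

#' @noRd
validate_observations <- function(df, categories) {
  cc <- count_cols(categories)
  for (col in cc) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop(sprintf("invalid count in column '%s', row %d (site %s): %s",
                   col, bad[1], df$site_id[bad[1]], format(v[bad[1]])),
           call. = FALSE)
    }
  }
  bad <- which(!is.finite(df$swept_area) | df$swept_area <= 0)
  if (length(bad) > 0) {
    stop(sprintf("nonpositive swept_area in row %d (site %s)",
                 bad[1], df$site_id[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.finite(df$tracer) | df$tracer <= 0)
  if (length(bad) > 0) {
    stop(sprintf("nonpositive tracer concentration in row %d (site %s)",
                 bad[1], df$site_id[bad[1]]), call. = FALSE)
  }
  if (any(is.na(df$region))) {
    stop("region code must be assigned a priori for every tow", call. = FALSE)
  }
  invisible(df)
}

#' @noRd
merge_duplicate_sites <- function(df, categories) {
  if (anyDuplicated(df$site_id) == 0) return(tibble::as_tibble(df))
  cc <- count_cols(categories)
  df |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(names(df), c("site_id", cc))),
                    dplyr::first),
      dplyr::across(dplyr::all_of(cc), sum),
      .ord = min(.data$.ord),
      .groups = "drop") |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord") |>
    dplyr::relocate(dplyr::all_of(c("site_id", "longitude", "latitude", "date",
                                    "net_type", "swept_area", "region",
                                    "tracer", cc)))
}

#' @rdname read_observations
#' @param obs An observation tibble.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs, path, progress = FALSE)
  invisible(path)
}

#' Standardise dual-observer counts to surface densities
#'
#' Per-category density is the mean of the two observers' counts divided by
#' the swept area, in numbers per km².  This is the descriptive
#' standardisation used for raw density summaries; model fitting works from
#' the counts themselves, not these means.
#'
#' @param obs Observation tibble (see [read_observations()]).
#' @param categories Category table.
#'
#' @return A long tibble with columns `site_id`, `region`, `category`,
#'   `is_neuston`, `density` (km^-2), one row per tow x category, tows in
#'   input order.
#' @export
density_from_counts <- function(obs, categories = neuston_categories()) {
  categories <- check_categories(categories)
  if (any(obs$swept_area <= 0)) stop("swept_area must be positive", call. = FALSE)
  purrr::map_dfr(seq_len(nrow(categories)), function(j) {
    cat_j <- categories$category[j]
    tibble::tibble(
      site_id = obs$site_id,
      region = obs$region,
      category = cat_j,
      is_neuston = categories$is_neuston[j],
      density = (obs[[paste0(cat_j, "_obs1")]] +
                   obs[[paste0(cat_j, "_obs2")]]) / 2 / obs$swept_area)
  }) |>
    dplyr::arrange(match(.data$site_id, obs$site_id),
                   match(.data$category, categories$category))
}

#' Regional summary of total neuston density
#'
#' Sums the per-category densities of the neuston categories within each tow
#' (plastic and other non-neuston categories are excluded) and summarises the
#' per-tow totals by region as median and quartiles.
#'
#' @param densities Long density tibble from [density_from_counts()].
#' @param regions Regions to summarise; default all present.
#' @param type Quantile convention, passed to [stats::quantile()].  The
#'   default 7 is linear interpolation between closest ranks; the convention
#'   is exposed because printed quartiles from other software may use
#'   another.
#'
#' @return A tibble with columns `region`, `n_sites`, `median`, `q1`, `q3`
#'   (densities in km^-2).
#' @export
region_density_summary <- function(densities, regions = NULL, type = 7) {
  totals <- densities |>
    dplyr::filter(.data$is_neuston) |>
    dplyr::group_by(.data$site_id, .data$region) |>
    dplyr::summarise(total_neuston_density = sum(.data$density),
                     .groups = "drop")
  if (is.null(regions)) regions <- unique(totals$region)
  if (!all(regions %in% totals$region)) {
    stop("region(s) with no tows: ",
         paste(setdiff(regions, totals$region), collapse = ", "),
         call. = FALSE)
  }
  totals |>
    dplyr::filter(.data$region %in% regions) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      median = quantile(.data$total_neuston_density, 0.5, type = type,
                        names = FALSE),
      q1 = quantile(.data$total_neuston_density, 0.25, type = type,
                    names = FALSE),
      q3 = quantile(.data$total_neuston_density, 0.75, type = type,
                    names = FALSE),
      .groups = "drop")
}
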