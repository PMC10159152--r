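#' Gridded dimensionless tracer concentration field
#'
#' A regular longitude/latitude grid of dimensionless tracer concentration
#' from a surface-drift accumulation model.  Concentrations are
#' non-dimensionalised relative to a reference maximum (normally the maximum
#' over the reference period, so the normalised field has maximum 1).
#'
#' @param lon,lat Strictly increasing numeric vectors of grid-node
#'   coordinates, degrees east in `[-180, 180]` and degrees north.  Grids are
#'   node-registered: `values[i, j]` is the concentration at
#'   `(lon[i], lat[j])`.
#' @param values Numeric matrix, `length(lon)` x `length(lat)`, of
#'   nonnegative concentrations.
#' @param normalize If `TRUE` (default), divide by the maximum so the stored
#'   field has maximum exactly 1; the divisor is kept as `reference_max`.
#'
#' @return An object of class `tracer_field`: a list with elements `lon`,
#'   `lat`, `values` and `reference_max`.
#' @seealso [tracer_at_sites()], [derive_region_mask()], [make_tracer_field()]
#' @export
tracer_field <- function(lon, lat, values, normalize = TRUE) {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  values <- as.matrix(values)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0)) {
    stop("grid coordinates must be strictly increasing", call. = FALSE)
  }
  if (!all(dim(values) == c(length(lon), length(lat)))) {
    stop("`values` must be a length(lon) x length(lat) matrix", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("tracer concentrations must be finite and >= 0", call. = FALSE)
  }
  reference_max <- max(values)
  if (normalize) {
    if (reference_max <= 0) stop("cannot normalize an all-zero field", call. = FALSE)
    values <- values / reference_max
  }
  structure(list(lon = lon, lat = lat, values = values,
                 reference_max = reference_max),
            class = "tracer_field")
}

#' @export
print.tracer_field <- function(x, ...) {
  cat(sprintf("<tracer_field> %d x %d grid, lon [%g, %g], lat [%g, %g], max %g\n",
              length(x$lon), length(x$lat), min(x$lon), max(x$lon),
              min(x$lat), max(x$lat), max(x$values)))
  invisible(x)
}

#' @describeIn tracer_field Long-format view: one row per grid cell with
#'   columns `lon`, `lat`, `tracer`.
#' @param x A `tracer_field`.
#' @param ... Unused.
#' @importFrom tibble as_tibble
#' @method as_tibble tracer_field
#' @export
as_tibble.tracer_field <- function(x, ...) {
  tibble::tibble(lon = rep(x$lon, times = length(x$lat)),
                 lat = rep(x$lat, each = length(x$lon)),
                 tracer = as.vector(x$values))
}

#' Read or write a tracer field as a three-column delimited grid
#'
#' The on-disk format is plain delimited text with columns `lon`, `lat`,
#' `tracer` (or `mask` for region masks), one row per node of a complete
#' regular grid.
#'
#' @param path File path.
#' @param normalize Passed to [tracer_field()]; the default `FALSE` preserves
#'   the stored values bit-for-bit.
#' @return `read_tracer_field()` returns a `tracer_field`;
#'   `write_tracer_field()` returns `path` invisibly.
#' @export
read_tracer_field <- function(path, normalize = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("lon", "lat", "tracer") %in% names(df))) {
    stop("tracer grid file needs columns lon, lat, tracer", call. = FALSE)
  }
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  if (nrow(df) != length(lon) * length(lat)) {
    stop("tracer grid file is not a complete regular grid", call. = FALSE)
  }
  values <- matrix(NA_real_, length(lon), length(lat))
  values[cbind(match(df$lon, lon), match(df$lat, lat))] <- df$tracer
  tracer_field(lon, lat, values, normalize = normalize)
}

#' @rdname read_tracer_field
#' @param field A `tracer_field`.
#' @export
write_tracer_field <- function(field, path) {
  readr::write_csv(as_tibble.tracer_field(field), path, progress = FALSE)
  invisible(path)
}

#' Interpolate a tracer field at site coordinates
#'
#' @param field A [tracer_field()].
#' @param lon,lat Numeric vectors of site coordinates (degrees).  All sites
#'   must lie within the grid extent.
#' @param method `"bilinear"` (default) interpolates between the four
#'   surrounding nodes; `"nearest"` returns the nearest node's value, which
#'   reproduces grid-sampled synthetic data exactly.
#'
#' @return Numeric vector of concentrations, one per site.
#' @export
tracer_at_sites <- function(field, lon, lat, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "tracer_field"), length(lon) == length(lat))
  if (any(lon < min(field$lon) | lon > max(field$lon) |
          lat < min(field$lat) | lat > max(field$lat))) {
    stop("site coordinates outside the tracer grid extent", call. = FALSE)
  }
  if (method == "nearest") {
    i <- vapply(lon, function(p) which.min(abs(field$lon - p)), integer(1))
    j <- vapply(lat, function(p) which.min(abs(field$lat - p)), integer(1))
    return(field$values[cbind(i, j)])
  }
  # bilinear: locate the cell, then interpolate along lon then lat
  i <- pmin(pmax(findInterval(lon, field$lon), 1L), length(field$lon) - 1L)
  j <- pmin(pmax(findInterval(lat, field$lat), 1L), length(field$lat) - 1L)
  if (length(field$lon) == 1L) i <- rep(1L, length(lon))
  if (length(field$lat) == 1L) j <- rep(1L, length(lat))
  x0 <- field$lon[i]; x1 <- field$lon[pmin(i + 1L, length(field$lon))]
  y0 <- field$lat[j]; y1 <- field$lat[pmin(j + 1L, length(field$lat))]
  tx <- ifelse(x1 > x0, (lon - x0) / (x1 - x0), 0)
  ty <- ifelse(y1 > y0, (lat - y0) / (y1 - y0), 0)
  v00 <- field$values[cbind(i, j)]
  v10 <- field$values[cbind(pmin(i + 1L, length(field$lon)), j)]
  v01 <- field$values[cbind(i, pmin(j + 1L, length(field$lat)))]
  v11 <- field$values[cbind(pmin(i + 1L, length(field$lon)),
                            pmin(j + 1L, length(field$lat)))]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Derive a patch region mask from a tracer field and site locations
#'
#' The region associated with a set of sites is the set of grid cells whose
#' tracer concentration is at least as large as the minimum concentration
#' over the sites, restricted to the smallest longitude/latitude rectangle
#' (axis-parallel) that just encloses the sites.
#'
#' @param field A [tracer_field()].
#' @param lon,lat Site coordinates (at least one site; within grid extent).
#' @param method Interpolation method used to evaluate the tracer at the
#'   sites; see [tracer_at_sites()].
#'
#' @return An object of class `region_mask`: list with `lon`, `lat`,
#'   `mask` (logical matrix aligned to the field), `threshold` and
#'   `rect` (`c(lon_min, lon_max, lat_min, lat_max)`).
#' @export
derive_region_mask <- function(field, lon, lat, method = "bilinear") {
  stopifnot(inherits(field, "tracer_field"))
  if (length(lon) < 1L) stop("need at least one site", call. = FALSE)
  threshold <- min(tracer_at_sites(field, lon, lat, method = method))
  rect <- c(min(lon), max(lon), min(lat), max(lat))
  in_rect <- outer(field$lon >= rect[1] & field$lon <= rect[2],
                   field$lat >= rect[3] & field$lat <= rect[4], "&")
  mask <- in_rect & (field$values >= threshold)
  structure(list(lon = field$lon, lat = field$lat, mask = mask,
                 threshold = threshold, rect = rect),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> threshold %.4g, rect [%g, %g] x [%g, %g], %d cells\n",
              x$threshold, x$rect[1], x$rect[2], x$rect[3], x$rect[4],
              sum(x$mask)))
  invisible(x)
}

#' @rdname read_tracer_field
#' @param mask A `region_mask`.
#' @export
write_region_mask <- function(mask, path) {
  df <- tibble::tibble(lon = rep(mask$lon, times = length(mask$lat)),
                       lat = rep(mask$lat, each = length(mask$lon)),
                       mask = as.integer(as.vector(mask$mask)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
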