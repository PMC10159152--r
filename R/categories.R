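#' Default object categories for gyre surface surveys
#'
#' The six categories modelled jointly in the accumulation-zone analysis:
#' five obligate neuston genera (*Velella*, *Porpita*, *Janthina*,
#' *Glaucus*, *Physalia*) and floating plastic.  Plastic is carried through
#' the same count model as the organisms but is flagged `is_neuston = FALSE`
#' so that totals over floating life exclude it.
#'
#' @param categories Character vector of category labels.  Must be unique.
#' @param is_neuston Logical vector parallel to `categories`; `TRUE` for
#'   obligate neuston taxa whose densities are summed into the neuston total.
#'
#' @return A tibble with columns `category` and `is_neuston`, one row per
#'   category, in model order.
#' @examples
#' neuston_categories()
#' @export
neuston_categories <- function(categories = c("Velella", "Porpita", "Janthina",
                                              "Glaucus", "Physalia", "plastic"),
                               is_neuston = categories != "plastic") {
  if (anyDuplicated(categories) > 0) {
    stop("category labels must be unique", call. = FALSE)
  }
  if (length(is_neuston) != length(categories)) {
    stop("`is_neuston` must have one flag per category", call. = FALSE)
  }
  if (length(categories) < 1) stop("need at least one category", call. = FALSE)
  tibble::tibble(category = as.character(categories),
                 is_neuston = as.logical(is_neuston))
}

#' @noRd
check_categories <- function(categories) {
  stopifnot(is.data.frame(categories),
            all(c("category", "is_neuston") %in% names(categories)))
  categories
}

# Column names used for the two observers' counts of one category.
count_cols <- function(categories) {
  c(paste0(categories$category, "_obs1"), paste0(categories$category, "_obs2"))
}
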