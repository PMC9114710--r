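#' Human activity intensity of land surface (HAILS)
#'
#' HAILS is the percentage of a sub-basin's area under direct human
#' interference: `100 * sum(fraction_i)` over the interference land-cover
#' classes (farmland and urban by default).
#'
#' @param land_use A data frame with `sample_id` and one column per
#'   land-use class holding area fractions in \[0, 1\] that sum to 1 per
#'   site.
#' @param classes Character vector of direct-interference classes.
#' @return Tibble with `sample_id`, `hails` (percent).
#' @examples
#' hails_index(tibble::tibble(sample_id = "L01", farmland = 0.25,
#'                            forest = 0.75, urban = 0))
#' @export
hails_index <- function(land_use, classes = c("farmland", "urban")) {
  stopifnot(is.data.frame(land_use), "sample_id" %in% names(land_use))
  missing <- setdiff(classes, names(land_use))
  if (length(missing)) {
    stop("land_use is missing required class column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  frac_cols <- intersect(names(land_use),
                         c(classes, "farmland", "forest", "grassland",
                           "freshwater", "urban", "other"))
  fr <- as.matrix(land_use[frac_cols])
  if (any(fr < -1e-9 | fr > 1 + 1e-9)) {
    stop("land-use fractions must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(fr)
  if (length(frac_cols) >= 6 && any(abs(sums - 1) > 1e-6)) {
    warning("land-use fractions do not sum to 1 for sample(s): ",
            paste(land_use$sample_id[abs(sums - 1) > 1e-6], collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    sample_id = as.character(land_use$sample_id),
    hails = 100 * rowSums(as.matrix(land_use[classes]))
  )
}

#' Classify HAILS values into low / middle / high levels
#'
#' The `"reach-map"` scheme reproduces the study convention: upper reaches
#' are low, middle reaches middle, lower reaches high. `"tertile"` splits at
#' the 33.3/66.7 percentiles (left-closed intervals; all-identical values
#' fall in `low` with a warning). `"fixed-breaks"` uses user thresholds
#' `breaks = c(low_upper, middle_upper)`.
#'
#' @param hails A data frame with `sample_id` and `hails` columns (as from
#'   [hails_index()]).
#' @param scheme One of `"reach-map"`, `"tertile"`, `"fixed-breaks"`.
#' @param reach For `"reach-map"`: character vector (or column name in
#'   `hails`) of `upper` / `middle` / `lower` labels.
#' @param breaks For `"fixed-breaks"`: two increasing thresholds in percent.
#' @return The input tibble with a `level` factor column
#'   (`low < middle < high`).
#' @export
classify_hails <- function(hails, scheme = c("reach-map", "tertile",
                                             "fixed-breaks"),
                           reach = NULL, breaks = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(hails), all(c("sample_id", "hails") %in% names(hails)))
  x <- hails$hails
  lev <- c("low", "middle", "high")
  level <- switch(scheme,
    "reach-map" = {
      if (is.null(reach) && "reach" %in% names(hails)) reach <- hails$reach
      if (is.null(reach)) {
        stop("reach-map scheme needs reach labels", call. = FALSE)
      }
      map <- c(upper = "low", middle = "middle", lower = "high")
      if (!all(reach %in% names(map))) {
        stop("reach labels must be upper/middle/lower", call. = FALSE)
      }
      unname(map[reach])
    },
    "tertile" = {
      if (length(x) < 3L) {
        stop("tertile scheme needs at least 3 values", call. = FALSE)
      }
      q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
      if (q[1] == q[2] && q[1] == min(x)) {
        warning("identical HAILS values: all sites assigned 'low'",
                call. = FALSE)
      }
      # left-closed: value == boundary goes to the lower class
      ifelse(x <= q[1], "low", ifelse(x <= q[2], "middle", "high"))
    },
    "fixed-breaks" = {
      if (is.null(breaks) || length(breaks) != 2L || diff(breaks) <= 0) {
        stop("fixed-breaks scheme needs two increasing thresholds",
             call. = FALSE)
      }
      ifelse(x <= breaks[1], "low", ifelse(x <= breaks[2], "middle", "high"))
    }
  )
  dplyr::mutate(tibble::as_tibble(hails),
                level = factor(level, levels = lev, ordered = TRUE))
}
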