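#' Temperature grid of a multiplexed melt-curve experiment
#'
#' One TMT plex carries one melt curve: each reporter channel corresponds to
#' one temperature of the denaturation gradient. The grid records the ordered
#' temperatures and which channel is the reference (the lowest temperature,
#' relative to which fold changes are formed).
#'
#' @param temperatures Numeric vector of channel temperatures in degrees
#'   Celsius, strictly ascending, length >= 3. Default: ten points evenly
#'   spanning 37-67 degrees C, the usual TPP gradient.
#' @param reference_index Index of the reference channel; must point at the
#'   minimum temperature.
#' @return An object of class `"temp_grid"`: a list with elements
#'   `temperatures` and `reference_index`.
#' @examples
#' grid <- temperature_grid()
#' grid$temperatures
#' @export
temperature_grid <- function(temperatures = seq(37, 67, length.out = 10),
                             reference_index = which.min(temperatures)) {
  if (!is.numeric(temperatures) || length(temperatures) < 3) {
    stop("`temperatures` must be a numeric vector of length >= 3")
  }
  if (anyNA(temperatures) || any(!is.finite(temperatures))) {
    stop("`temperatures` must be finite")
  }
  if (any(diff(temperatures) <= 0)) {
    stop("`temperatures` must be strictly ascending")
  }
  reference_index <- as.integer(reference_index)
  if (length(reference_index) != 1L || is.na(reference_index) ||
      reference_index < 1L || reference_index > length(temperatures)) {
    stop("`reference_index` out of range")
  }
  if (temperatures[reference_index] != min(temperatures)) {
    stop("reference channel must be the lowest temperature")
  }
  structure(list(temperatures = as.numeric(temperatures),
                 reference_index = reference_index),
            class = "temp_grid")
}

#' @export
print.temp_grid <- function(x, ...) {
  cat(sprintf("Temperature grid: %d channels, %.1f-%.1f degC (reference channel %d)\n",
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              x$reference_index))
  invisible(x)
}

#' @export
length.temp_grid <- function(x) length(x$temperatures)
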