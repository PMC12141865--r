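#' Construct a growth curve
#'
#' A growth curve is one well's optical density (OD600) time series. Times
#' are in hours, strictly increasing; OD values are non-negative and raw
#' (no blank or pathlength correction — the downstream AUC statistics are
#' ratios of raw integrals).
#'
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing, all >= 0, length >= 2.
#' @param od Numeric vector of OD600 readings, same length as `times`,
#'   all >= 0.
#' @param well_id Optional text label for the well.
#' @return An object of class `growth_curve`: a list with elements
#'   `well_id`, `times`, `od`.
#' @export
#' @examples
#' gc <- growth_curve(times = seq(0, 24, by = 0.25),
#'                    od = seq(0.1, 1.1, length.out = 97))
#' trapezoid_auc(gc)
growth_curve <- function(times, od, well_id = NA_character_) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od)) {
    abort_validation("`times` and `od` must have the same length.")
  }
  if (length(times) < 2) {
    abort_validation("a growth curve needs at least 2 samples.")
  }
  if (anyNA(times) || anyNA(od)) {
    abort_validation("`times` and `od` must not contain missing values.")
  }
  if (any(diff(times) <= 0)) {
    abort_data(sprintf(
      "times must be strictly increasing%s.",
      if (is.na(well_id)) "" else paste0(" in well '", well_id, "'")
    ))
  }
  if (times[1] < 0) abort_validation("times must be >= 0.")
  if (any(od < 0)) abort_validation("OD values must be >= 0.")
  structure(list(well_id = well_id, times = times, od = od),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "<growth_curve> well %s: %d samples, %.2f-%.2f h, OD %.3f-%.3f\n",
    x$well_id, length(x$times), min(x$times), max(x$times),
    min(x$od), max(x$od)
  ))
  invisible(x)
}

#' @export
as_tibble.growth_curve <- function(x, ...) {
  tibble::tibble(well = x$well_id, time_h = x$times, od600 = x$od)
}

as_growth_curve <- function(x, well_id = NA_character_) {
  if (inherits(x, "growth_curve")) return(x)
  if (is.data.frame(x)) {
    return(growth_curve(x$time_h, x$od600, well_id = well_id))
  }
  abort_validation("cannot interpret input as a growth curve.")
}

# Linear interpolation of the curve at time t (t within the sampled range).
curve_at <- function(curve, t) {
  stats::approx(curve$times, curve$od, xout = t, method = "linear",
                rule = 1)$y
}

# Pointwise mean of curves sharing a grid (resampled to the first grid).
average_curves <- function(curves, well_id = NA_character_) {
  if (length(curves) == 1) return(curves[[1]])
  grid <- curves[[1]]$times
  mats <- vapply(curves, function(cv) {
    stats::approx(cv$times, cv$od, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  growth_curve(grid, rowMeans(mats), well_id = well_id)
}
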