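# Planktonic killing assay statistics.
#
# The lysis call for one phage-strain pair is made from the normalized
# area under the curve,
#
#   AUC_norm = AUC[0,24h](infected) / AUC[0,24h](uninfected control),
#
# with a strict cutoff: AUC_norm < 0.8 => lysis, >= 0.8 => no lysis.
# Integrals are trapezoidal on the raw OD600 series (no blank
# subtraction). The time of lysis is the first sampled time at which the
# expanding-window ratio AUC_norm[0,t] drops below the cutoff.

#' Trapezoidal area under a growth curve
#'
#' Integrates OD600 over a time window by the trapezoid rule. If the
#' window endpoints fall between samples, the curve is linearly
#' interpolated there, so the integral is exact for piecewise-linear
#' curves and invariant under grid refinement.
#'
#' @param curve A [growth_curve()].
#' @param t_start,t_end Window in hours; defaults to the sampled range.
#'   Must satisfy `t_start < t_end` and lie within the sampled range.
#' @return The integral in OD·h (>= 0).
#' @export
#' @examples
#' gc <- growth_curve(c(0, 1, 2), c(0.1, 0.1, 0.1))
#' trapezoid_auc(gc)            # 0.2
#' trapezoid_auc(gc, 0.5, 1.5)  # 0.1
trapezoid_auc <- function(curve, t_start = NULL, t_end = NULL) {
  curve <- as_growth_curve(curve)
  rng <- range(curve$times)
  t_start <- t_start %||% rng[1]
  t_end <- t_end %||% rng[2]
  if (t_start >= t_end) abort_validation("`t_start` must be < `t_end`.")
  eps <- 1e-9
  if (t_start < rng[1] - eps || t_end > rng[2] + eps) {
    abort_range(sprintf(
      "integration window [%g, %g] outside sampled range [%g, %g].",
      t_start, t_end, rng[1], rng[2]))
  }
  t_start <- max(t_start, rng[1])
  t_end <- min(t_end, rng[2])
  inner <- curve$times > t_start & curve$times < t_end
  tt <- c(t_start, curve$times[inner], t_end)
  yy <- c(curve_at(curve, t_start), curve$od[inner], curve_at(curve, t_end))
  trapz_vec(tt, yy)
}

# Clip a requested window to what both curves cover; warn when shorter.
common_window <- function(with_curve, control_curve, window) {
  last <- min(max(with_curve$times), max(control_curve$times))
  first <- max(min(with_curve$times), min(control_curve$times))
  w <- c(max(window[1], first), min(window[2], last))
  if (w[2] < window[2] - 1e-9) {
    rlang::warn(sprintf(
      "curves end at %g h; integrating over [%g, %g] instead of [%g, %g].",
      last, w[1], w[2], window[1], window[2]),
      class = "phagekit_short_window")
  }
  if (w[1] >= w[2]) abort_range("curves share no usable time window.")
  w
}

#' Normalized area under the curve
#'
#' Ratio of the infected culture's OD integral to the uninfected
#' control's over the same window (24 h by default). Dimensionless;
#' values below the lysis cutoff (0.8) indicate phage killing.
#'
#' @param with_curve Infected-well [growth_curve()].
#' @param control_curve Uninfected control [growth_curve()] for the same
#'   strain.
#' @param window Length-2 numeric, hours; default `c(0, 24)`. Clipped
#'   (with a warning) to the common sampled range when curves are
#'   shorter.
#' @return AUC_norm, a non-negative scalar.
#' @export
#' @examples
#' ctrl <- growth_curve(seq(0, 24, 0.25), 0.1 + seq(0, 24, 0.25) / 24)
#' flat <- growth_curve(seq(0, 24, 0.25), rep(0.1, 97))
#' auc_norm(flat, ctrl)  # 2.4 / 14.4
auc_norm <- function(with_curve, control_curve, window = c(0, 24)) {
  w <- common_window(with_curve, control_curve, window)
  a_ctrl <- trapezoid_auc(control_curve, w[1], w[2])
  if (a_ctrl <= 0) {
    abort_degenerate_control(
      "control integral is zero: empty or failed control well.")
  }
  trapezoid_auc(with_curve, w[1], w[2]) / a_ctrl
}

#' Classify a PKA result from its normalized AUC
#'
#' Strict threshold: lysis iff `auc_norm_value < cutoff`; the boundary
#' value itself is no lysis.
#'
#' @param auc_norm_value Non-negative scalar(s).
#' @param cutoff Lysis cutoff, default 0.8.
#' @return Character vector, `"lysis"` or `"no_lysis"`.
#' @export
#' @examples
#' classify_pka(c(0.79, 0.80, 1.3))
classify_pka <- function(auc_norm_value, cutoff = 0.8) {
  if (any(is.na(auc_norm_value)) || any(auc_norm_value < 0)) {
    abort_validation("AUC_norm values must be non-negative.")
  }
  ifelse(auc_norm_value < cutoff, "lysis", "no_lysis")
}

#' Time of lysis
#'
#' The first sampled time t > 0 at which the expanding-window ratio
#' AUC_norm over [0, t] falls below the cutoff; `NA` when the full-window
#' call is no lysis. The infected curve is resampled to the control's
#' grid by linear interpolation, so the returned time always lies on the
#' control's sampling grid.
#'
#' @inheritParams auc_norm
#' @param cutoff Lysis cutoff, default 0.8.
#' @return Time in hours, or `NA_real_` for non-lytic pairs.
#' @export
time_of_lysis <- function(with_curve, control_curve, cutoff = 0.8,
                          window = c(0, 24)) {
  w <- withCallingHandlers(
    common_window(with_curve, control_curve, window),
    phagekit_short_window = function(cnd) invokeRestart("muffleWarning"))
  ctrl <- as_growth_curve(control_curve)
  keep <- ctrl$times >= w[1] - 1e-9 & ctrl$times <= w[2] + 1e-9
  tt <- ctrl$times[keep]
  yc <- ctrl$od[keep]
  yw <- stats::approx(with_curve$times, with_curve$od, xout = tt, rule = 2)$y
  n <- length(tt)
  if (n < 2) abort_range("fewer than two control samples in the window.")
  dt <- diff(tt)
  cum_ctrl <- cumsum(dt * (yc[-1] + yc[-n]) / 2)
  cum_with <- cumsum(dt * (yw[-1] + yw[-n]) / 2)
  if (any(cum_ctrl <= 0)) {
    abort_degenerate_control(
      "control curve has a zero-area prefix; cannot form AUC_norm ratios.")
  }
  ratio <- cum_with / cum_ctrl
  if (ratio[n - 1] >= cutoff) return(NA_real_)  # 24 h call is no_lysis
  tt[-1][which(ratio < cutoff)[1]]
}

#' Run the PKA pipeline on a plate
#'
#' Joins the plate series to its map, averages replicate wells pointwise
#' per (strain, phage, MOI), and computes for each infected condition the
#' AUC pair, AUC_norm against the strain's uninfected control, the lysis
#' call, and the time of lysis.
#'
#' @param plate A `plate_data` object from [read_plate()] /
#'   [plate_data()], or a series tibble (then `map` must be given).
#' @param map Optional plate-map tibble when `plate` is a series tibble.
#' @param cutoff Lysis cutoff on AUC_norm, default 0.8.
#' @param window Integration window in hours, default `c(0, 24)`.
#' @return Tibble with one row per (phage, strain, moi): columns `phage`,
#'   `strain`, `moi`, `auc_with`, `auc_without`, `auc_norm`, `call`,
#'   `time_of_lysis`, `n_replicates`.
#' @export
#' @examples
#' truth <- tidyr::expand_grid(phage = c("P1", "P2"), strain = c("S1", "S2"))
#' truth$truth <- c("lysis", "no_lysis", "no_lysis", "lysis")
#' sim <- simulate_plate(truth, seed = 7)
#' pka_analyse(sim)
pka_analyse <- function(plate, map = NULL, cutoff = 0.8, window = c(0, 24)) {
  if (!inherits(plate, "plate_data")) plate <- plate_data(plate, map)
  joined <- dplyr::inner_join(plate$series, plate$map, by = "well")

  pooled <- joined |>
    dplyr::group_by(.data$strain, .data$phage, .data$moi, .data$role,
                    .data$time_h) |>
    dplyr::summarise(od600 = mean(.data$od600),
                     n_replicates = dplyr::n(), .groups = "drop")

  controls <- pooled |>
    dplyr::filter(.data$role == "control") |>
    (\(d) split(d, d$strain))() |>
    purrr::map(~growth_curve(.x$time_h, .x$od600, well_id = .x$strain[1]))

  infected <- pooled |> dplyr::filter(.data$role == "infected")
  if (nrow(infected) == 0) abort_validation("no infected wells on the plate.")

  infected |>
    dplyr::group_by(.data$phage, .data$strain, .data$moi) |>
    dplyr::group_modify(function(df, key) {
      ctrl <- controls[[key$strain]]
      if (is.null(ctrl)) {
        abort_validation(sprintf("no uninfected control for strain '%s'.",
                                 key$strain))
      }
      cv <- growth_curve(df$time_h, df$od600)
      an <- auc_norm(cv, ctrl, window = window)
      w <- suppressWarnings(common_window(cv, ctrl, window))
      tibble::tibble(
        auc_with = trapezoid_auc(cv, w[1], w[2]),
        auc_without = trapezoid_auc(ctrl, w[1], w[2]),
        auc_norm = an,
        call = classify_pka(an, cutoff = cutoff),
        time_of_lysis = if (an < cutoff)
          time_of_lysis(cv, ctrl, cutoff = cutoff, window = window)
        else NA_real_,
        n_replicates = max(df$n_replicates)
      )
    }) |>
    dplyr::ungroup()
}

#' Per-replicate AUC_norm dispersion diagnostics
#'
#' Computes AUC_norm for each replicate well separately (against the
#' pointwise-mean control of its strain), for inspecting replicate
#' scatter behind the pooled calls of [pka_analyse()].
#'
#' @inheritParams pka_analyse
#' @return Tibble with columns `phage`, `strain`, `moi`, `replicate`,
#'   `auc_norm`.
#' @export
pka_replicate_stats <- function(plate, map = NULL, window = c(0, 24)) {
  if (!inherits(plate, "plate_data")) plate <- plate_data(plate, map)
  joined <- dplyr::inner_join(plate$series, plate$map, by = "well")
  controls <- joined |>
    dplyr::filter(.data$role == "control") |>
    dplyr::group_by(.data$strain, .data$time_h) |>
    dplyr::summarise(od600 = mean(.data$od600), .groups = "drop") |>
    (\(d) split(d, d$strain))() |>
    purrr::map(~growth_curve(.x$time_h, .x$od600))
  joined |>
    dplyr::filter(.data$role == "infected") |>
    dplyr::group_by(.data$phage, .data$strain, .data$moi, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      cv <- growth_curve(df$time_h, df$od600)
      tibble::tibble(auc_norm = suppressWarnings(
        auc_norm(cv, controls[[key$strain]], window = window)))
    }) |>
    dplyr::ungroup()
}

#' Convert PKA results to a host-range matrix
#'
#' @param pka_tbl Output of [pka_analyse()].
#' @param strain_meta Optional named character vector of infection
#'   categories.
#' @return A two-level `host_range_matrix` with `assay = "PKA"`.
#' @export
pka_to_matrix <- function(pka_tbl, strain_meta = NULL) {
  as_host_range_matrix(
    dplyr::select(pka_tbl, "strain", "phage", "call"),
    assay = "PKA", strain_meta = strain_meta)
}
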