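# MOI-series virulence quantification (Storms-style indices).
#
# For each MOI, the local virulence index is
#
#   vi = 1 - AUC[0, T_s](infected) / AUC[0, T_s](control),
#
# where T_s is the onset of the control's stationary phase, and vi is
# clamped to [0, 1]. The global index vp is the area under the vi versus
# log10(MOI) curve (A_p) divided by its theoretical maximum A_max (the
# width of the log10-MOI range, since vi <= 1):  vp = A_p / A_max.

#' Detect the onset of stationary phase
#'
#' Scans the uninfected control for the first local maximum: the first
#' sample whose OD is not exceeded (beyond `tol`) by any of the next
#' `window` samples. At the default 15-min cadence, `window = 5` looks 75
#' minutes ahead. If no such sample exists before the trailing `window`
#' samples, the final time point is returned (a still-growing culture is
#' integrated over its full run).
#'
#' @param control A [growth_curve()] for the uninfected control.
#' @param window Forward-looking window, in samples (default 5).
#' @param tol OD tolerance: a later sample must exceed the candidate by
#'   more than `tol` to disqualify it (default 0).
#' @return Onset time in hours.
#' @export
#' @examples
#' gc <- growth_curve(seq(0, by = 0.25, length.out = 10),
#'                    c(0.1, 0.2, 0.3, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4))
#' detect_stationary_onset(gc)  # 0.75
detect_stationary_onset <- function(control, window = 5, tol = 0) {
  control <- as_growth_curve(control)
  n <- length(control$od)
  if (n < window + 1) {
    abort_validation(sprintf(
      "control needs more than %d samples for a %d-sample window.",
      window, window))
  }
  for (i in seq_len(n - window)) {
    if (control$od[i] >= max(control$od[(i + 1):(i + window)]) - tol) {
      return(control$times[i])
    }
  }
  control$times[n]
}

#' Local virulence index at one MOI
#'
#' `1 - AUC_infected / AUC_control`, both integrated from 0 h to the
#' control's stationary-phase onset, clamped to `[0, 1]`. 0 means the
#' phage did not slow growth at all; 1 means instantaneous complete
#' killing.
#'
#' @param with_curve Infected [growth_curve()].
#' @param control Uninfected control [growth_curve()].
#' @param t_stationary Stationary-phase onset in hours (see
#'   [detect_stationary_onset()]); must lie within both curves' ranges.
#' @return vi in `[0, 1]`.
#' @export
local_virulence <- function(with_curve, control, t_stationary) {
  t0 <- max(min(control$times), min(with_curve$times))
  a_ctrl <- trapezoid_auc(control, t0, t_stationary)
  if (a_ctrl <= 0) {
    abort_degenerate_control("control AUC is zero up to the stationary onset.")
  }
  a_with <- trapezoid_auc(with_curve, t0, t_stationary)
  min(1, max(0, 1 - a_with / a_ctrl))
}

#' Global virulence index over an MOI series
#'
#' Computes the local index vi at every MOI (at the control's
#' stationary-phase onset), forms the virulence curve vi versus
#' log10(MOI), and reports `vp = A_p / A_max` where `A_p` is the
#' trapezoidal area under the virulence curve and `A_max` the width of
#' the log10-MOI range (4 for the standard ladder 1 ... 1e-4).
#'
#' @param curves List of infected [growth_curve()]s, one per MOI.
#' @param mois Numeric vector of distinct positive MOIs, parallel to
#'   `curves`; at least two are required.
#' @param control Uninfected control [growth_curve()].
#' @param window,tol Passed to [detect_stationary_onset()].
#' @return A `virulence_result` object with fields `stationary_onset`,
#'   `local_vi` (tibble: `moi`, `log10_moi`, `vi`), `area_ap`,
#'   `area_amax`, `vp`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
#' @examples
#' g <- growth_params(noise_sd = 0)
#' ctrl <- simulate_control_curve(g, seed = 1)
#' mois <- 10^(0:-4)
#' curves <- lapply(mois, function(m)
#'   simulate_infected_curve(g, lysis_params(), moi = m, seed = 1))
#' glance(global_virulence(curves, mois, ctrl))
global_virulence <- function(curves, mois, control, window = 5, tol = 0) {
  if (length(curves) != length(mois)) {
    abort_validation("`curves` and `mois` must have the same length.")
  }
  if (length(mois) < 2) {
    abort_validation("vp needs at least two MOIs.")
  }
  if (any(mois <= 0) || any(!is.finite(log10(mois)))) {
    abort_validation("MOIs must be positive and representable.")
  }
  if (anyDuplicated(mois)) abort_validation("MOIs must be distinct.")
  onset <- detect_stationary_onset(control, window = window, tol = tol)
  vi <- vapply(curves, local_virulence, numeric(1),
               control = control, t_stationary = onset)
  lm <- log10(mois)
  ord <- order(lm)
  ap <- trapz_vec(lm[ord], vi[ord])
  amax <- diff(range(lm))
  structure(
    list(
      stationary_onset = onset,
      local_vi = tibble::tibble(moi = mois[ord], log10_moi = lm[ord],
                                vi = vi[ord]),
      area_ap = ap,
      area_amax = amax,
      vp = ap / amax
    ),
    class = "virulence_result"
  )
}

#' @export
print.virulence_result <- function(x, ...) {
  cat(sprintf(
    "<virulence_result> vp = %.3f (A_p %.3f / A_max %g), stationary onset %.2f h\n",
    x$vp, x$area_ap, x$area_amax, x$stationary_onset))
  cat("  vi:", paste(sprintf("%.2f@%g", x$local_vi$vi, x$local_vi$moi),
                     collapse = " "), "\n")
  invisible(x)
}

#' Tidy a virulence result
#'
#' @param x A `virulence_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-MOI tibble (`moi`, `log10_moi`, `vi`);
#'   `glance()`: a one-row tibble (`stationary_onset`, `area_ap`,
#'   `area_amax`, `vp`).
#' @export
tidy.virulence_result <- function(x, ...) {
  x$local_vi
}

#' @rdname tidy.virulence_result
#' @export
glance.virulence_result <- function(x, ...) {
  tibble::tibble(stationary_onset = x$stationary_onset, area_ap = x$area_ap,
                 area_amax = x$area_amax, vp = x$vp)
}

#' Run the virulence pipeline on an MOI-ladder plate
#'
#' For every (phage, strain) on the plate with at least two MOIs, pools
#' replicates pointwise, detects the control's stationary onset, and
#' computes vi per MOI and the global index vp.
#'
#' @inheritParams pka_analyse
#' @param window,tol Passed to [detect_stationary_onset()].
#' @return Tibble with one row per (phage, strain): `stationary_onset`,
#'   `area_ap`, `area_amax`, `vp`, and a list-column `local_vi` of
#'   per-MOI tibbles.
#' @export
virulence_analyse <- function(plate, map = NULL, window = 5, tol = 0) {
  if (!inherits(plate, "plate_data")) plate <- plate_data(plate, map)
  joined <- dplyr::inner_join(plate$series, plate$map, by = "well")
  pooled <- joined |>
    dplyr::group_by(.data$strain, .data$phage, .data$moi, .data$role,
                    .data$time_h) |>
    dplyr::summarise(od600 = mean(.data$od600), .groups = "drop")
  controls <- pooled |>
    dplyr::filter(.data$role == "control") |>
    (\(d) split(d, d$strain))() |>
    purrr::map(~growth_curve(.x$time_h, .x$od600))
  pooled |>
    dplyr::filter(.data$role == "infected") |>
    dplyr::group_by(.data$phage, .data$strain) |>
    dplyr::group_modify(function(df, key) {
      ctrl <- controls[[key$strain]]
      if (is.null(ctrl)) {
        abort_validation(sprintf("no uninfected control for strain '%s'.",
                                 key$strain))
      }
      mois <- sort(unique(df$moi), decreasing = TRUE)
      curves <- purrr::map(mois, function(m) {
        d <- df[df$moi == m, ]
        growth_curve(d$time_h, d$od600)
      })
      res <- global_virulence(curves, mois, ctrl, window = window, tol = tol)
      dplyr::mutate(glance(res), local_vi = list(tidy(res)))
    }) |>
    dplyr::ungroup()
}
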