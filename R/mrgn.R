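# EUCAST-style disc-diffusion interpretation and the German (RKI)
# 3MRGN/4MRGN multidrug-resistance classification. Four antibiotic
# classes decide the class, each through one lead substance; resistance
# to the lead of exactly three classes is 3MRGN, to all four is 4MRGN.

MRGN_DEFAULT_LEADS <- c(
  penicillins = "piperacillin",
  cephalosporins = "ceftazidime",
  carbapenems = "meropenem",
  fluoroquinolones = "ciprofloxacin"
)

#' Interpret a zone diameter against breakpoints
#'
#' S when `diameter_mm >= s_min_mm`, R when `diameter_mm < r_max_mm`, I
#' ("susceptible, increased exposure") otherwise. Vectorised.
#'
#' @param diameter_mm Zone diameter(s) in mm, >= 0.
#' @param s_min_mm Susceptible breakpoint(s): minimum diameter for S.
#' @param r_max_mm Resistant breakpoint(s): diameters strictly below are
#'   R. Must satisfy `s_min_mm >= r_max_mm`.
#' @return Character vector of `"S"`, `"I"`, `"R"`.
#' @export
#' @examples
#' interpret_zone(c(25, 18, 16), 20, 17)
interpret_zone <- function(diameter_mm, s_min_mm, r_max_mm) {
  if (any(s_min_mm < r_max_mm)) {
    abort_validation("inverted breakpoints: s_min_mm must be >= r_max_mm.")
  }
  if (any(diameter_mm < 0)) abort_validation("zone diameters must be >= 0.")
  dplyr::case_when(
    diameter_mm >= s_min_mm ~ "S",
    diameter_mm < r_max_mm ~ "R",
    .default = "I"
  )
}

#' SIR calls for an antibiogram
#'
#' Joins an antibiogram to a breakpoint table and interprets each zone
#' diameter.
#'
#' @param antibiogram Tibble with columns `strain`, `antibiotic`,
#'   `zone_mm` (see [read_antibiogram()]).
#' @param breakpoints Validated breakpoint tibble (see
#'   [read_breakpoints()]). Antibiotics without a breakpoint row are
#'   dropped with a message.
#' @return Tibble `strain`, `antibiotic`, `abx_class`, `lead`, `zone_mm`,
#'   `call`.
#' @export
sir_calls <- function(antibiogram, breakpoints) {
  antibiogram <- validate_antibiogram(antibiogram)
  breakpoints <- validate_breakpoints(breakpoints)
  unknown <- setdiff(unique(antibiogram$antibiotic), breakpoints$antibiotic)
  if (length(unknown) > 0) {
    rlang::inform(sprintf("no breakpoints for: %s (dropped).",
                          paste(unknown, collapse = ", ")))
  }
  antibiogram |>
    dplyr::inner_join(breakpoints, by = "antibiotic") |>
    dplyr::mutate(call = interpret_zone(.data$zone_mm, .data$s_min_mm,
                                        .data$r_max_mm)) |>
    dplyr::select("strain", "antibiotic", "abx_class", "lead", "zone_mm",
                  "call")
}

#' Classify strains into 3MRGN / 4MRGN
#'
#' Counts the lead antibiotic classes with an R call per strain: four
#' resistant lead classes give 4MRGN, exactly three give 3MRGN, fewer
#' give none. "I" counts as non-resistant (RKI practice) unless
#' `i_as_resistant = TRUE`. Non-lead antibiotics never influence the
#' class.
#'
#' @inheritParams sir_calls
#' @param leads Named character vector mapping the four antibiotic
#'   classes to their lead substances; the default uses piperacillin,
#'   ceftazidime, meropenem and ciprofloxacin.
#' @param i_as_resistant Treat I as resistant (sensitivity analysis flag,
#'   default `FALSE`).
#' @return Tibble `strain`, `n_resistant_leads`, `mrgn` (`"none"`,
#'   `"3MRGN"`, `"4MRGN"`), `resistant_classes` (list-column).
#' @export
#' @examples
#' bp <- synthetic_breakpoints()
#' ab <- simulate_antibiogram(5, bp, seed = 1)
#' classify_mrgn(ab, bp)
classify_mrgn <- function(antibiogram, breakpoints,
                          leads = MRGN_DEFAULT_LEADS,
                          i_as_resistant = FALSE) {
  antibiogram <- validate_antibiogram(antibiogram)
  breakpoints <- validate_breakpoints(breakpoints)
  for (ab in leads) {
    if (!ab %in% breakpoints$antibiotic) {
      abort_validation(sprintf("lead antibiotic '%s' missing from breakpoints.", ab))
    }
  }
  expected <- tidyr::expand_grid(strain = unique(antibiogram$strain),
                                 antibiotic = unname(leads))
  bad <- dplyr::anti_join(expected, antibiogram,
                          by = c("strain", "antibiotic"))
  if (nrow(bad) > 0) {
    abort_validation(sprintf(
      "missing lead antibiotic measurement(s): %s",
      paste(sprintf("%s/%s", bad$strain, bad$antibiotic), collapse = ", ")))
  }
  class_of <- stats::setNames(names(leads), leads)
  resistant_calls <- if (i_as_resistant) c("R", "I") else "R"
  sir_calls(antibiogram, breakpoints) |>
    dplyr::filter(.data$antibiotic %in% leads) |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      n_resistant_leads = sum(.data$call %in% resistant_calls),
      resistant_classes = list(unname(
        class_of[.data$antibiotic[.data$call %in% resistant_calls]])),
      .groups = "drop"
    ) |>
    dplyr::mutate(mrgn = dplyr::case_when(
      .data$n_resistant_leads == 4 ~ "4MRGN",
      .data$n_resistant_leads == 3 ~ "3MRGN",
      .default = "none"
    )) |>
    dplyr::select("strain", "n_resistant_leads", "mrgn", "resistant_classes")
}
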