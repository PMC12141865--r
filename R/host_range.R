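# Host-range coverage summaries and the six-group DPA/PKA concordance
# classification. Missing cells are excluded from every denominator.

#' Per-phage coverage summary
#'
#' Counts each call level per phage and the percentage of lysed strains
#' among non-missing cells. Both the exact percentage and its half-up
#' integer rounding are reported (reports print integers, machine output
#' keeps full precision).
#'
#' @param matrix A [host_range_matrix()].
#' @return Tibble with columns `phage`, `n_lysis`, `n_reduced`,
#'   `n_no_lysis`, `n_total`, `pct_lysis`, `pct_lysis_int`.
#' @export
#' @examples
#' m <- host_range_matrix(
#'   matrix(c("lysis", "lysis", "reduced_growth", "no_lysis"), ncol = 1,
#'          dimnames = list(paste0("S", 1:4), "P1")), assay = "DPA")
#' coverage_summary(m)
coverage_summary <- function(matrix) {
  stopifnot(inherits(matrix, "host_range_matrix"))
  if (nrow(matrix$calls) == 0 || ncol(matrix$calls) == 0) {
    abort_validation("empty host-range matrix.")
  }
  n_excluded <- sum(is.na(matrix$calls))
  if (n_excluded > 0) {
    rlang::inform(sprintf("%d missing cell(s) excluded from coverage counts.",
                          n_excluded))
  }
  tibble::as_tibble(matrix) |>
    dplyr::filter(!is.na(.data$call)) |>
    dplyr::group_by(phage = factor(.data$phage, levels = colnames(matrix$calls))) |>
    dplyr::summarise(
      n_lysis = sum(.data$call == "lysis"),
      n_reduced = sum(.data$call == "reduced_growth"),
      n_no_lysis = sum(.data$call == "no_lysis"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      phage = as.character(.data$phage),
      pct_lysis = 100 * .data$n_lysis / .data$n_total,
      pct_lysis_int = round_half_up(.data$pct_lysis)
    )
}

#' Coverage by infection category
#'
#' Percentage of lysed strains per phage within each infection category
#' (wound, urinary tract, ...). Strains without metadata are pooled under
#' `"not available"`; categories with zero strains yield `NA`.
#'
#' @param matrix A [host_range_matrix()] whose `strain_meta` maps at
#'   least one strain to a category.
#' @return Tibble with columns `phage`, `category`, `n_lysis`,
#'   `n_strains`, `pct_lysis`.
#' @export
coverage_by_category <- function(matrix) {
  stopifnot(inherits(matrix, "host_range_matrix"))
  if (is.null(matrix$strain_meta) || length(matrix$strain_meta) == 0) {
    abort_validation("`strain_meta` with infection categories is required.")
  }
  meta <- matrix$strain_meta
  tibble::as_tibble(matrix) |>
    dplyr::filter(!is.na(.data$call)) |>
    dplyr::mutate(category = dplyr::coalesce(unname(meta[.data$strain]),
                                             "not available")) |>
    dplyr::group_by(.data$phage, .data$category) |>
    dplyr::summarise(
      n_lysis = sum(.data$call == "lysis"),
      n_strains = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_lysis = ifelse(.data$n_strains > 0,
                                     100 * .data$n_lysis / .data$n_strains,
                                     NA_real_))
}

# Fixed six-group mapping of (DPA call, PKA call) pairs.
CONCORDANCE_GROUPS <- tibble::tibble(
  dpa = rep(c("no_lysis", "reduced_growth", "lysis"), times = 2),
  pka = rep(c("no_lysis", "lysis"), each = 3),
  group = c(1L, 2L, 3L, 4L, 5L, 6L)
)

#' Classify one DPA/PKA call pair into its concordance group
#'
#' The six groups: 1 = both no lysis; 2 = DPA reduced growth, PKA no
#' lysis; 3 = DPA lysis, PKA no lysis; 4 = DPA no lysis, PKA lysis; 5 =
#' DPA reduced growth, PKA lysis; 6 = both lysis. Groups 1 and 6 are the
#' concordant ones (group 2 is ambiguous, not concordant).
#'
#' @param dpa DPA call(s): `no_lysis`, `reduced_growth` or `lysis`.
#' @param pka PKA call(s): `no_lysis` or `lysis`.
#' @return Integer group(s) 1-6.
#' @export
#' @examples
#' concordance_classify("reduced_growth", "lysis")  # 5
concordance_classify <- function(dpa, pka) {
  if (any(!dpa %in% CALL_LEVELS)) {
    abort_validation("invalid DPA call level.")
  }
  if (any(!pka %in% c("no_lysis", "lysis"))) {
    abort_validation("PKA calls must be 'no_lysis' or 'lysis'.")
  }
  idx <- match(paste(dpa, pka), paste(CONCORDANCE_GROUPS$dpa,
                                      CONCORDANCE_GROUPS$pka))
  CONCORDANCE_GROUPS$group[idx]
}

#' Six-group concordance summary of DPA versus PKA host ranges
#'
#' Pairs every (strain, phage) cell of the two matrices over their common
#' strain and phage sets (with a warning when the sets differ), assigns
#' each pair its concordance group, and reports group fractions over
#' non-missing pairs. Concordance is the fraction in groups 1 and 6.
#'
#' @param dpa_matrix Three-level DPA [host_range_matrix()].
#' @param pka_matrix Two-level PKA [host_range_matrix()].
#' @param phage_meta Optional tibble with columns `name`, `genus`; when
#'   supplied a per-genus breakdown is included.
#' @return A `concordance_summary` object: list with `groups` (tibble
#'   `group`, `dpa`, `pka`, `n`, `fraction`), `concordance`, `n_pairs`,
#'   and optionally `by_genus`. [tidy()] returns the group tibble,
#'   [glance()] a one-row overview.
#' @export
concordance_summary <- function(dpa_matrix, pka_matrix, phage_meta = NULL) {
  stopifnot(inherits(dpa_matrix, "host_range_matrix"),
            inherits(pka_matrix, "host_range_matrix"))
  strains <- intersect(rownames(dpa_matrix$calls), rownames(pka_matrix$calls))
  phages <- intersect(colnames(dpa_matrix$calls), colnames(pka_matrix$calls))
  if (length(strains) == 0 || length(phages) == 0) {
    abort_validation("DPA and PKA matrices share no strains or no phages.")
  }
  if (length(strains) < max(nrow(dpa_matrix$calls), nrow(pka_matrix$calls)) ||
      length(phages) < max(ncol(dpa_matrix$calls), ncol(pka_matrix$calls))) {
    rlang::warn("matrices differ in strains/phages; using the intersection.",
                class = "phagekit_intersection_warning")
  }
  pairs <- tibble::tibble(
    strain = rep(strains, times = length(phages)),
    phage = rep(phages, each = length(strains)),
    dpa = as.vector(dpa_matrix$calls[strains, phages, drop = FALSE]),
    pka = as.vector(pka_matrix$calls[strains, phages, drop = FALSE])
  ) |>
    dplyr::filter(!is.na(.data$dpa), !is.na(.data$pka)) |>
    dplyr::mutate(group = concordance_classify(.data$dpa, .data$pka))
  if (nrow(pairs) == 0) abort_validation("no jointly observed pairs.")

  tally <- function(df) {
    CONCORDANCE_GROUPS |>
      dplyr::left_join(dplyr::count(df, .data$group), by = "group") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                    fraction = .data$n / nrow(df))
  }
  groups <- tally(pairs)
  concordance <- sum(groups$fraction[groups$group %in% c(1L, 6L)])

  by_genus <- NULL
  if (!is.null(phage_meta)) {
    require_columns(phage_meta, c("name", "genus"), "phage metadata")
    by_genus <- pairs |>
      dplyr::left_join(dplyr::select(phage_meta, phage = "name", "genus"),
                       by = "phage") |>
      dplyr::group_by(.data$genus) |>
      dplyr::group_modify(~tally(.x)) |>
      dplyr::ungroup()
  }

  structure(list(groups = groups, concordance = concordance,
                 n_pairs = nrow(pairs), by_genus = by_genus),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %d pairs, concordance %.1f%%\n",
              x$n_pairs, 100 * x$concordance))
  print(x$groups)
  invisible(x)
}

#' Tidy a concordance summary
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return `tidy()`: per-group counts and fractions; `glance()`: one row
#'   with `n_pairs`, `concordance`, `frac_lytic_concordant` (group 6) and
#'   `frac_nonlytic_concordant` (group 1).
#' @export
tidy.concordance_summary <- function(x, ...) {
  x$groups
}

#' @rdname tidy.concordance_summary
#' @export
glance.concordance_summary <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    concordance = x$concordance,
    frac_lytic_concordant = x$groups$fraction[x$groups$group == 6L],
    frac_nonlytic_concordant = x$groups$fraction[x$groups$group == 1L]
  )
}
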