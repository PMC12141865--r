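# Therapeutic-potential scoring rubric. Each phage collects points for
# its DPA host range, PKA host range, genomic safety and global
# virulence index, then phages are ranked by the total (3-10 points).
# Bin edges are half-open with inclusive lower bounds: a phage sitting
# exactly on an upper threshold gets the higher score.

score_bin <- function(x, bins) {
  findInterval(x, sort(bins)) + 1L
}

#' Score phages with the therapeutic-potential rubric
#'
#' Default bins (for a 141-strain panel): DPA lysed strains >= 42 scores
#' 3, 21-41 scores 2, < 21 scores 1; PKA lysed strains >= 63 / 31-62 /
#' < 31 score 3/2/1; global virulence vp >= 0.6 / 0.3-0.6 / < 0.3 scores
#' 3/2/1; genomically safe, strictly lytic phages get 1 safety point,
#' all others 0. Totals range 3-10 (safe phages 4-10). Bin edges scale
#' with the panel via the `*_bins` arguments.
#'
#' @param phages Data frame with columns `phage`, `dpa_lysed` (count),
#'   `pka_lysed` (count), `vp` (in `[0, 1]`), `safe` (logical).
#' @param dpa_bins,pka_bins Length-2 numeric lower bounds of the 2- and
#'   3-point bins (defaults `c(21, 42)` and `c(31, 63)`).
#' @param vp_bins Length-2 numeric lower bounds for vp (default
#'   `c(0.3, 0.6)`).
#' @return Tibble with per-category points (`pts_dpa`, `pts_pka`,
#'   `pts_safety`, `pts_vp`), `total`, and `rank`, sorted by rank.
#'   Ties in `total` are broken by (`pts_pka`, `pts_dpa`, `pts_vp`,
#'   `phage` name) for a deterministic order.
#' @export
#' @examples
#' score_phages(tibble::tibble(
#'   phage = c("A", "B"), dpa_lysed = c(63, 10), pka_lysed = c(70, 10),
#'   vp = c(0.95, 0.1), safe = c(TRUE, FALSE)))
score_phages <- function(phages, dpa_bins = c(21, 42), pka_bins = c(31, 63),
                         vp_bins = c(0.3, 0.6)) {
  require_columns(phages, c("phage", "dpa_lysed", "pka_lysed", "vp", "safe"),
                  "phage score table")
  if (any(phages$dpa_lysed < 0) || any(phages$pka_lysed < 0)) {
    abort_validation("lysed-strain counts must be >= 0.")
  }
  if (any(phages$vp < 0 | phages$vp > 1)) {
    abort_validation("vp must lie in [0, 1].")
  }
  tibble::as_tibble(phages) |>
    dplyr::mutate(
      pts_dpa = score_bin(.data$dpa_lysed, dpa_bins),
      pts_pka = score_bin(.data$pka_lysed, pka_bins),
      pts_safety = as.integer(.data$safe),
      pts_vp = score_bin(.data$vp, vp_bins),
      total = .data$pts_dpa + .data$pts_pka + .data$pts_safety + .data$pts_vp
    ) |>
    dplyr::arrange(dplyr::desc(.data$total), dplyr::desc(.data$pts_pka),
                   dplyr::desc(.data$pts_dpa), dplyr::desc(.data$pts_vp),
                   .data$phage) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Score a single phage
#'
#' Convenience scalar wrapper around [score_phages()].
#'
#' @param dpa_lysed,pka_lysed Lysed-strain counts from DPA and PKA.
#' @param vp Global virulence index in `[0, 1]`.
#' @param safe Logical: strictly lytic and free of resistance/virulence
#'   genes.
#' @param ... Bin overrides passed to [score_phages()].
#' @return One-row tibble of points and total.
#' @export
#' @examples
#' score_phage(63, 70, 0.95, TRUE)$total  # 10
score_phage <- function(dpa_lysed, pka_lysed, vp, safe, ...) {
  dplyr::select(
    score_phages(tibble::tibble(phage = "phage", dpa_lysed = dpa_lysed,
                                pka_lysed = pka_lysed, vp = vp, safe = safe),
                 ...),
    -"phage", -"rank")
}
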