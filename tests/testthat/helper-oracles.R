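# Independent oracles and fixture builders used across the suite.

# Trapezoid integral via pracma, independent of the package's
# interpolating implementation.
oracle_trapz <- function(times, od) {
  pracma::trapz(times, od)
}

# Brute-force maximum-coverage oracle: enumerates all k-subsets and
# computes coverage through set unions of strain names (a different code
# path from the package's logical-matrix row sums).
oracle_best_coverage <- function(mat, k) {
  lysed_by <- lapply(colnames(mat$calls), function(p) {
    rownames(mat$calls)[!is.na(mat$calls[, p]) & mat$calls[, p] == "lysis"]
  })
  names(lysed_by) <- colnames(mat$calls)
  subsets <- utils::combn(sort(colnames(mat$calls)), k, simplify = FALSE)
  cov <- vapply(subsets, function(set) {
    length(unique(unlist(lysed_by[set])))
  }, numeric(1))
  best <- max(cov)
  list(best = best, sets = subsets[cov == best])
}

# Closed-form noise-free vp oracle: evaluates the generator's model on
# the grid and integrates with pracma, mirroring the published formulas
# (vi at the control's stationary onset, vp = Ap / Amax) without using
# any package integration code.
oracle_vp <- function(g, l, mois) {
  grid <- g$grid
  ctrl <- phagekit:::logistic_od(grid, g$od0, g$r, g$K)
  # noise-free logistic is strictly increasing => onset falls back to 24 h
  t_s <- max(grid)
  a_ctrl <- oracle_trapz(grid, ctrl)
  vi <- vapply(mois, function(m) {
    cv <- closed_form_curve(g, l, moi = m)
    min(1, max(0, 1 - oracle_trapz(grid, cv$od) / a_ctrl))
  }, numeric(1))
  x <- sort(log10(mois))
  vi <- vi[order(log10(mois))]
  pracma::trapz(x, vi) / diff(range(x))
}

# Random small host-range matrix for optimizer property tests.
random_matrix <- function(n_phages, n_strains, p = 0.35, assay = "DPA") {
  calls <- matrix(
    sample(c("lysis", "no_lysis"), n_phages * n_strains, replace = TRUE,
           prob = c(p, 1 - p)),
    nrow = n_strains,
    dimnames = list(sprintf("s%02d", seq_len(n_strains)),
                    sprintf("p%02d", seq_len(n_phages))))
  host_range_matrix(calls, assay = assay)
}

linear_curve <- function(od_start, od_end, t_end = 24, step = 0.25) {
  tt <- seq(0, t_end, by = step)
  growth_curve(tt, od_start + (od_end - od_start) * tt / t_end)
}

write_tmp <- function(df, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  delim <- if (ext == ".csv") "," else "\t"
  readr::write_delim(df, path, delim = delim, na = "NA")
  path
}
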