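# Coverage summaries and the six-group DPA/PKA concordance analysis.

make_mat <- function(calls_by_phage, assay = "DPA", strain_meta = NULL) {
  n <- length(calls_by_phage[[1]])
  m <- do.call(cbind, calls_by_phage)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  host_range_matrix(m, assay = assay, strain_meta = strain_meta)
}

test_that("coverage summary counts call levels and rounds percent half-up", {
  m <- make_mat(list(A = c("lysis", "lysis", "reduced_growth", "no_lysis")))
  cov <- coverage_summary(m)
  expect_equal(cov$n_lysis, 2)
  expect_equal(cov$n_reduced, 1)
  expect_equal(cov$n_no_lysis, 1)
  expect_equal(cov$n_total, 4)
  expect_equal(cov$pct_lysis_int, 50)

  # panel arithmetic: 63 lysed of 141 strains reads as 45%
  big <- make_mat(list(TOP = c(rep("lysis", 63), rep("no_lysis", 78))))
  cov2 <- coverage_summary(big)
  expect_equal(cov2$pct_lysis, 100 * 63 / 141, tolerance = 1e-12)
  expect_equal(cov2$pct_lysis_int, 45)

  none <- make_mat(list(A = rep("no_lysis", 5)))
  expect_equal(coverage_summary(none)$pct_lysis_int, 0)
})

test_that("missing cells are excluded from every count with a message", {
  m <- make_mat(list(A = c("lysis", NA, "no_lysis", NA)))
  expect_message(cov <- coverage_summary(m), regexp = "2 missing")
  expect_equal(cov$n_total, 2)
  expect_equal(cov$n_lysis + cov$n_reduced + cov$n_no_lysis, cov$n_total)
  expect_equal(cov$pct_lysis, 50)
})

test_that("coverage by category pools unannotated strains under 'not available'", {
  meta <- c(s01 = "wound", s02 = "wound", s03 = "wound", s04 = "wound",
            s05 = "urinary tract")
  m <- make_mat(list(A = c("lysis", "lysis", "no_lysis", "no_lysis", "lysis"),
                     B = rep("lysis", 5)),
                strain_meta = meta[1:5])
  bc <- coverage_by_category(m)
  expect_equal(bc$pct_lysis[bc$phage == "A" & bc$category == "wound"], 50)
  expect_equal(bc$pct_lysis[bc$phage == "B" & bc$category == "wound"], 100)
  # strain without metadata
  m2 <- make_mat(list(A = c("lysis", "no_lysis")), strain_meta = c(s01 = "wound"))
  bc2 <- coverage_by_category(m2)
  expect_true("not available" %in% bc2$category)
})

test_that("the six concordance groups follow the fixed mapping", {
  cases <- tibble::tribble(
    ~dpa, ~pka, ~group,
    "no_lysis", "no_lysis", 1L,
    "reduced_growth", "no_lysis", 2L,
    "lysis", "no_lysis", 3L,
    "no_lysis", "lysis", 4L,
    "reduced_growth", "lysis", 5L,
    "lysis", "lysis", 6L
  )
  expect_identical(concordance_classify(cases$dpa, cases$pka), cases$group)
  expect_error(concordance_classify("lysis", "reduced_growth"),
               class = "phagekit_validation_error")
})

test_that("concordance summary reproduces hand-counted fractions", {
  # pairs {(L,L), (L,L), (N,N), (R,L), (L,N)}
  dpa <- make_mat(list(A = c("lysis", "lysis", "no_lysis", "reduced_growth",
                             "lysis")))
  pka <- make_mat(list(A = c("lysis", "lysis", "no_lysis", "lysis",
                             "no_lysis")), assay = "PKA")
  cs <- concordance_summary(dpa, pka)
  frac <- function(g) cs$groups$fraction[cs$groups$group == g]
  expect_equal(frac(6), 0.4)
  expect_equal(frac(1), 0.2)
  expect_equal(frac(5), 0.2)
  expect_equal(frac(3), 0.2)
  expect_equal(cs$concordance, 0.6)

  # identical all-lysis matrices are fully concordant
  all_l <- make_mat(list(A = rep("lysis", 4)))
  all_l_pka <- make_mat(list(A = rep("lysis", 4)), assay = "PKA")
  expect_equal(concordance_summary(all_l, all_l_pka)$concordance, 1)

  # group 2 (reduced vs no_lysis) is ambiguous, NOT concordant
  red <- make_mat(list(A = rep("reduced_growth", 4)))
  no <- make_mat(list(A = rep("no_lysis", 4)), assay = "PKA")
  cs2 <- concordance_summary(red, no)
  expect_equal(cs2$groups$fraction[cs2$groups$group == 2], 1)
  expect_equal(cs2$concordance, 0)
})

test_that("group fractions sum to one and survive strain/phage relabeling", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    dpa <- make_mat(list(A = sample(c("lysis", "reduced_growth", "no_lysis"),
                                    n, replace = TRUE),
                         B = sample(c("lysis", "reduced_growth", "no_lysis"),
                                    n, replace = TRUE)))
    pka <- make_mat(list(A = sample(c("lysis", "no_lysis"), n, replace = TRUE),
                         B = sample(c("lysis", "no_lysis"), n, replace = TRUE)),
                    assay = "PKA")
    cs <- concordance_summary(dpa, pka)
    expect_equal(sum(cs$groups$fraction), 1, tolerance = 1e-12)

    relabel <- function(m) {
      calls <- m$calls
      rownames(calls) <- paste0("strain_", rownames(calls))
      colnames(calls) <- paste0("phage_", colnames(calls))
      host_range_matrix(calls, assay = m$assay)
    }
    cs_rel <- concordance_summary(relabel(dpa), relabel(pka))
    expect_equal(cs_rel$concordance, cs$concordance)
    expect_equal(cs_rel$groups$fraction, cs$groups$fraction)
  }
})

test_that("per-genus fractions weighted by pair counts recompose the global ones", {
  set.seed(3)
  n <- 40
  dpa <- make_mat(list(A = sample(CALL_DPA <- c("lysis", "reduced_growth",
                                                "no_lysis"), n, TRUE),
                       B = sample(CALL_DPA, n, TRUE),
                       C = sample(CALL_DPA, n, TRUE)))
  pka <- make_mat(list(A = sample(c("lysis", "no_lysis"), n, TRUE),
                       B = sample(c("lysis", "no_lysis"), n, TRUE),
                       C = sample(c("lysis", "no_lysis"), n, TRUE)),
                  assay = "PKA")
  meta <- tibble::tibble(name = c("A", "B", "C"),
                         genus = c("g1", "g1", "g2"))
  cs <- concordance_summary(dpa, pka, phage_meta = meta)
  weights <- c(g1 = 2 * n, g2 = n) / (3 * n)
  recomposed <- cs$by_genus |>
    dplyr::mutate(weight = unname(weights[.data$genus])) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(fraction = sum(.data$fraction * .data$weight))
  expect_equal(recomposed$fraction, cs$groups$fraction, tolerance = 1e-12)
})

test_that("mismatched matrices intersect with a warning; empty intersections fail", {
  dpa <- make_mat(list(A = rep("lysis", 4), B = rep("no_lysis", 4)))
  pka_small <- host_range_matrix(
    matrix(rep("lysis", 3), ncol = 1,
           dimnames = list(c("s01", "s02", "s03"), "A")), assay = "PKA")
  expect_warning(cs <- concordance_summary(dpa, pka_small),
                 class = "phagekit_intersection_warning")
  expect_equal(cs$n_pairs, 3)
  other <- host_range_matrix(
    matrix("lysis", ncol = 1, dimnames = list("x1", "Z")), assay = "PKA")
  expect_error(suppressWarnings(concordance_summary(dpa, other)),
               class = "phagekit_validation_error")
})
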