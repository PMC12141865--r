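# Maximum-coverage phage cocktail design. A cocktail of size k covers a
# strain when at least one member lyses it; the optimizer finds the
# k-subset(s) of candidate phages maximizing the number of covered
# strains. Exhaustive enumeration (with complete listing of co-optimal
# sets) is the default at panel scale; a deterministic greedy
# (best-marginal-gain, lexicographic tie-break) handles large phage
# collections with the classical (1 - 1/e) guarantee.

# Logical strains x phages coverage matrix from a host_range_matrix.
lysis_matrix <- function(matrix, include_reduced = FALSE) {
  pos <- matrix$calls == "lysis"
  if (include_reduced) pos <- pos | matrix$calls == "reduced_growth"
  pos[is.na(pos)] <- FALSE
  pos
}

#' Strain coverage of a phage set
#'
#' Number of strains lysed by at least one member of the set. Only
#' `lysis` calls count; `reduced_growth` does not (unless
#' `include_reduced = TRUE`, a sensitivity-analysis option).
#'
#' @param matrix A [host_range_matrix()].
#' @param phages Character vector of phage names (subset of the matrix's
#'   phages); the empty set covers 0 strains.
#' @param include_reduced Count `reduced_growth` as coverage (default
#'   `FALSE`).
#' @return Integer count of covered strains.
#' @export
#' @examples
#' m <- host_range_matrix(matrix(
#'   c("lysis", "lysis", "no_lysis", "no_lysis", "lysis", "lysis"),
#'   nrow = 3, dimnames = list(c("s1", "s2", "s3"), c("A", "B"))), "DPA")
#' coverage_of_set(m, c("A", "B"))
coverage_of_set <- function(matrix, phages, include_reduced = FALSE) {
  stopifnot(inherits(matrix, "host_range_matrix"))
  unknown <- setdiff(phages, colnames(matrix$calls))
  if (length(unknown) > 0) {
    abort_validation(sprintf("unknown phage name(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  if (length(phages) == 0) return(0L)
  pos <- lysis_matrix(matrix, include_reduced)
  sum(rowSums(pos[, phages, drop = FALSE]) > 0)
}

#' Optimize a phage cocktail for maximum strain coverage
#'
#' Exhaustive mode enumerates all `choose(n, k)` subsets of candidate
#' phages and returns the global maximum together with every co-optimal
#' set (capped at `max_sets`, with an overflow flag). Greedy mode adds
#' the phage with the best marginal gain at each step, breaking ties
#' lexicographically; it is deterministic and carries the classical
#' `1 - 1/e` approximation guarantee. `method = "auto"` picks exhaustive
#' while `choose(n, k) <= 1e6`.
#'
#' @param matrix A [host_range_matrix()].
#' @param k Cocktail size, >= 1.
#' @param safe_only Restrict candidates to phages marked safe in
#'   `phage_meta` (default `FALSE`).
#' @param phage_meta Tibble with columns `name`, `safe` (and optionally
#'   `lifestyle`, `genus`); required when `safe_only = TRUE`.
#' @param method `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param include_reduced Count `reduced_growth` as coverage.
#' @param max_sets Cap on enumerated co-optimal sets (default 10000).
#' @return A `cocktail_result`: list with `k`, `best_coverage`, `pct`
#'   (exact), `pct_int` (half-up), `optimal_sets` (list of character
#'   vectors, lexicographically ordered), `n_optimal`, `overflow`,
#'   `method`, `n_strains`, `candidates`.
#' @export
#' @examples
#' m <- simulate_host_range(6, 20, seed = 3)
#' optimize_cocktail(m, k = 2)
optimize_cocktail <- function(matrix, k, safe_only = FALSE, phage_meta = NULL,
                              method = c("auto", "exhaustive", "greedy"),
                              include_reduced = FALSE, max_sets = 10000L) {
  stopifnot(inherits(matrix, "host_range_matrix"))
  method <- match.arg(method)
  if (k < 1 || k != round(k)) abort_validation("`k` must be an integer >= 1.")
  candidates <- sort(colnames(matrix$calls))
  if (safe_only) {
    if (is.null(phage_meta)) {
      abort_validation("`phage_meta` with a `safe` column is required for `safe_only`.")
    }
    require_columns(phage_meta, c("name", "safe"), "phage metadata")
    candidates <- sort(intersect(candidates,
                                 phage_meta$name[phage_meta$safe]))
  }
  if (length(candidates) < k) {
    abort_validation(sprintf("k = %d exceeds the %d candidate phage(s).",
                             k, length(candidates)))
  }
  pos <- lysis_matrix(matrix, include_reduced)[, candidates, drop = FALSE]
  n_strains <- nrow(pos)
  if (method == "auto") {
    method <- if (choose(length(candidates), k) <= 1e6) "exhaustive" else "greedy"
  }

  if (method == "exhaustive") {
    best <- -1L
    sets <- list()
    overflow <- FALSE
    # combn over sorted names emits subsets in lexicographic order
    utils::combn(candidates, k, simplify = FALSE) |>
      purrr::walk(function(set) {
        cov <- sum(rowSums(pos[, set, drop = FALSE]) > 0)
        if (cov > best) {
          best <<- cov
          sets <<- list(set)
          overflow <<- FALSE
        } else if (cov == best) {
          if (length(sets) < max_sets) sets[[length(sets) + 1L]] <<- set
          else overflow <<- TRUE
        }
      })
  } else {
    chosen <- character(0)
    covered <- rep(FALSE, n_strains)
    for (step in seq_len(k)) {
      remaining <- setdiff(candidates, chosen)
      gains <- vapply(remaining, function(p) sum(pos[, p] & !covered),
                      numeric(1))
      pick <- remaining[which.max(gains)] # which.max takes the first, i.e.
      chosen <- c(chosen, pick)           # lexicographically smallest, tie
      covered <- covered | pos[, pick]
    }
    best <- sum(covered)
    sets <- list(sort(chosen))
    overflow <- FALSE
  }

  structure(list(
    k = as.integer(k),
    best_coverage = as.integer(best),
    pct = 100 * best / n_strains,
    pct_int = round_half_up(100 * best / n_strains),
    optimal_sets = sets,
    n_optimal = if (overflow) NA_integer_ else length(sets),
    overflow = overflow,
    method = method,
    n_strains = n_strains,
    candidates = candidates
  ), class = "cocktail_result")
}

#' @export
print.cocktail_result <- function(x, ...) {
  cat(sprintf(
    "<cocktail_result> k = %d (%s): %d/%d strains (%d%%), %s co-optimal set(s)\n",
    x$k, x$method, x$best_coverage, x$n_strains, x$pct_int,
    if (x$overflow) paste0(">", length(x$optimal_sets)) else length(x$optimal_sets)))
  cat("  best:", paste(x$optimal_sets[[1]], collapse = " + "), "\n")
  invisible(x)
}

#' Tidy a cocktail result
#'
#' @param x A `cocktail_result`.
#' @param ... Unused.
#' @return `tidy()`: tibble `set_id`, `phage` over all co-optimal sets;
#'   `glance()`: one row with `k`, `best_coverage`, `pct`, `pct_int`,
#'   `n_optimal`, `method`.
#' @export
tidy.cocktail_result <- function(x, ...) {
  purrr::imap(x$optimal_sets,
              ~tibble::tibble(set_id = .y, phage = .x)) |>
    purrr::list_rbind()
}

#' @rdname tidy.cocktail_result
#' @export
glance.cocktail_result <- function(x, ...) {
  tibble::tibble(k = x$k, best_coverage = x$best_coverage, pct = x$pct,
                 pct_int = x$pct_int, n_optimal = length(x$optimal_sets),
                 overflow = x$overflow, method = x$method)
}

#' Cocktail coverage table over increasing depths
#'
#' Optimal coverage for every cocktail size 1 ... `k_max`, one row per
#' depth, mirroring a "coverage versus cocktail depth" report.
#'
#' @inheritParams optimize_cocktail
#' @param k_max Largest cocktail size.
#' @return Tibble `k`, `best_coverage`, `pct`, `pct_int`, `example_set`
#'   (first optimal set, `+`-joined), `n_optimal`, `method`.
#' @export
#' @examples
#' m <- simulate_host_range(6, 20, seed = 3)
#' coverage_table(m, k_max = 3)
coverage_table <- function(matrix, k_max, safe_only = FALSE, phage_meta = NULL,
                           method = c("auto", "exhaustive", "greedy"),
                           include_reduced = FALSE) {
  method <- match.arg(method)
  if (k_max < 1) abort_validation("`k_max` must be >= 1.")
  purrr::map(seq_len(k_max), function(k) {
    res <- optimize_cocktail(matrix, k, safe_only = safe_only,
                             phage_meta = phage_meta, method = method,
                             include_reduced = include_reduced)
    dplyr::mutate(glance(res),
                  example_set = paste(res$optimal_sets[[1]], collapse = "+"),
                  .after = "pct_int")
  }) |>
    purrr::list_rbind()
}
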