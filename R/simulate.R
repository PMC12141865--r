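# Seed-deterministic synthetic data: logistic bacterial growth with
# MOI-dependent lysis kinetics, block-structured host-range matrices,
# and antibiograms with known resistance states. The lysis model is
# phenomenological (piecewise logistic/exponential), chosen because the
# analysis pipeline only ever sees OD curves and the noise-free model
# has closed forms that serve as analytic oracles.
#
# Every generator is a pure function of (params, seed). A global seed
# fans out to per-well substreams by stable string hashing of
# (strain, phage, moi, replicate), so adding wells to a plate never
# perturbs existing wells.

#' Growth-model parameters
#'
#' Logistic growth `OD(t) = K * od0 / (od0 + (K - od0) * exp(-r t))`:
#' starts at `od0` (the protocol inoculates at OD600 0.1) and saturates
#' at the carrying capacity `K` well before 24 h with the defaults.
#' Additive Gaussian measurement noise (sd `noise_sd`) is truncated at 0.
#'
#' @param od0 Initial OD600 (> 0, default 0.1).
#' @param r Growth rate per hour (> 0, default 0.6).
#' @param K Carrying-capacity OD600 (> `od0`, default 1.2).
#' @param noise_sd Noise standard deviation in OD units (>= 0, default
#'   0.01).
#' @param grid Sampling times in hours (default 0-24 h every 15 min).
#' @return A `growth_params` list.
#' @export
growth_params <- function(od0 = 0.1, r = 0.6, K = 1.2, noise_sd = 0.01,
                          grid = seq(0, 24, by = 0.25)) {
  if (od0 <= 0 || r <= 0 || K <= od0 || noise_sd < 0) {
    abort_validation("need od0 > 0, r > 0, K > od0, noise_sd >= 0.")
  }
  structure(list(od0 = od0, r = r, K = K, noise_sd = noise_sd, grid = grid),
            class = "growth_params")
}

#' Lysis-model parameters
#'
#' After an MOI-dependent onset `t_L = max(0, t0 - tau * log10(moi))`
#' the infected culture decays exponentially from the control trajectory
#' toward a debris floor; with probability `regrow_frac` a resistant
#' subpopulation regrows logistically at rate `r2` from a random time
#' after the onset (some cultures undergo a second lysis/regrowth cycle
#' in practice).
#'
#' @param t0 Base lysis onset in hours at MOI 1 (default 2).
#' @param tau Onset shift per decade of MOI in hours (default 0.75):
#'   lower MOI means later lysis.
#' @param lam Exponential decay rate per hour (default 1.5); `lam = 0`
#'   disables lysis entirely (a null phage whose curve equals the
#'   control).
#' @param floor Debris OD the culture decays to (default 0.05).
#' @param regrow_frac Probability of resistant regrowth (default 0).
#' @param r2 Regrowth rate per hour (default 0.3).
#' @return A `lysis_params` list.
#' @export
lysis_params <- function(t0 = 2, tau = 0.75, lam = 1.5, floor = 0.05,
                         regrow_frac = 0, r2 = 0.3) {
  if (t0 < 0 || tau < 0 || lam < 0 || floor < 0 || regrow_frac < 0 ||
      regrow_frac > 1 || r2 < 0) {
    abort_validation("lysis parameters must be non-negative (regrow_frac in [0, 1]).")
  }
  structure(list(t0 = t0, tau = tau, lam = lam, floor = floor,
                 regrow_frac = regrow_frac, r2 = r2),
            class = "lysis_params")
}

logistic_od <- function(t, od0, r, K) {
  K * od0 / (od0 + (K - od0) * exp(-r * t))
}

add_noise <- function(od, noise_sd) {
  if (noise_sd == 0) return(od)
  pmax(od + stats::rnorm(length(od), sd = noise_sd), 0)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate an uninfected control growth curve
#'
#' @param params A [growth_params()] object.
#' @param seed Integer seed; identical seeds give bitwise-identical
#'   curves.
#' @param well_id Optional well label.
#' @return A [growth_curve()].
#' @export
#' @examples
#' simulate_control_curve(growth_params(noise_sd = 0), seed = 1)
simulate_control_curve <- function(params = growth_params(), seed,
                                   well_id = "control") {
  stopifnot(inherits(params, "growth_params"))
  od <- logistic_od(params$grid, params$od0, params$r, params$K)
  od <- with_seed(seed, add_noise(od, params$noise_sd))
  growth_curve(params$grid, od, well_id = well_id)
}

# Noise-free infected trajectory (exported through the closed-form
# helper below; also the test oracle's reference shape).
infected_trajectory <- function(grid, g, l, moi, regrow = FALSE,
                                t_regrow = NA_real_) {
  t_l <- max(0, l$t0 - l$tau * log10(moi))
  od <- logistic_od(grid, g$od0, g$r, g$K)
  # lam == 0 means no lysis at all (null phage): the curve is the control
  if (l$lam > 0) {
    after <- grid > t_l
    od_tl <- logistic_od(t_l, g$od0, g$r, g$K)
    od[after] <- l$floor + (od_tl - l$floor) * exp(-l$lam * (grid[after] - t_l))
  }
  if (regrow && !is.na(t_regrow)) {
    reg <- grid > t_regrow
    od_tr <- od[which(reg)[1] - 1]
    if (length(od_tr) == 0 || is.na(od_tr)) od_tr <- l$floor
    od_reg <- logistic_od(grid[reg] - t_regrow, max(od_tr, 1e-4), l$r2, g$K)
    od[reg] <- pmax(od[reg], od_reg)
  }
  od
}

#' Simulate an infected growth curve
#'
#' Follows the control's logistic trajectory until the MOI-dependent
#' lysis onset `t_L = max(0, t0 - tau * log10(moi))`, then decays
#' exponentially toward the debris floor; optional seeded resistant
#' regrowth. Noise as in [simulate_control_curve()].
#'
#' @param g A [growth_params()] object.
#' @param l A [lysis_params()] object.
#' @param moi Multiplicity of infection (> 0).
#' @param seed Integer seed.
#' @param well_id Optional well label.
#' @return A [growth_curve()].
#' @export
simulate_infected_curve <- function(g = growth_params(), l = lysis_params(),
                                    moi, seed, well_id = "infected") {
  stopifnot(inherits(g, "growth_params"), inherits(l, "lysis_params"))
  if (moi <= 0) abort_validation("`moi` must be positive.")
  with_seed(seed, {
    regrow <- l$regrow_frac > 0 && stats::runif(1) < l$regrow_frac
    t_l <- max(0, l$t0 - l$tau * log10(moi))
    t_regrow <- if (regrow) stats::runif(1, min = t_l + 2, max = 20) else NA_real_
    od <- infected_trajectory(g$grid, g, l, moi, regrow, t_regrow)
    growth_curve(g$grid, add_noise(od, g$noise_sd), well_id = well_id)
  })
}

#' Closed-form noise-free curves of the simulator
#'
#' Evaluates the generator's noise-free model on the sampling grid:
#' either the logistic control or the piecewise infected trajectory
#' (without regrowth). These are the analytic reference curves against
#' which parameter-recovery checks compare pipeline output.
#'
#' @inheritParams simulate_infected_curve
#' @param moi MOI for the infected trajectory; `NULL` (default) returns
#'   the control.
#' @return A [growth_curve()] with no noise.
#' @export
closed_form_curve <- function(g = growth_params(), l = lysis_params(),
                              moi = NULL) {
  if (is.null(moi)) {
    growth_curve(g$grid, logistic_od(g$grid, g$od0, g$r, g$K),
                 well_id = "closed_form_control")
  } else {
    growth_curve(g$grid, infected_trajectory(g$grid, g, l, moi),
                 well_id = "closed_form_infected")
  }
}

#' Simulate a full plate from a ground-truth call table
#'
#' Builds a long plate-reader series plus plate map for every
#' (phage, strain) pair in `truth`, with per-strain uninfected controls.
#' Pairs with `truth == "lysis"` use the lysis kinetics `l`; all other
#' pairs grow like the control (null phage). Per-well noise streams are
#' derived from `seed` by stable hashing of (strain, phage, moi,
#' replicate), so the same pair always gets the same curve regardless of
#' plate composition.
#'
#' @param truth Data frame with columns `phage`, `strain`, and
#'   optionally `truth` (`"lysis"` / `"no_lysis"`, default all lysis) —
#'   or a [host_range_matrix()] (any call other than `lysis` becomes a
#'   null phage).
#' @param g,l [growth_params()] and [lysis_params()].
#' @param moi MOI for every infected well (default 0.1, the host-range
#'   PKA protocol value).
#' @param replicates Wells per condition (default 1).
#' @param seed Integer global seed.
#' @return A `plate_data` object.
#' @export
#' @examples
#' truth <- tibble::tibble(phage = "P1", strain = c("S1", "S2"),
#'                         truth = c("lysis", "no_lysis"))
#' sim <- simulate_plate(truth, seed = 42)
#' pka_analyse(sim)
simulate_plate <- function(truth, g = growth_params(), l = lysis_params(),
                           moi = 0.1, replicates = 1, seed) {
  if (inherits(truth, "host_range_matrix")) {
    truth <- tibble::as_tibble(truth) |>
      dplyr::filter(!is.na(.data$call)) |>
      dplyr::mutate(truth = ifelse(.data$call == "lysis", "lysis", "no_lysis")) |>
      dplyr::select("phage", "strain", "truth")
  }
  require_columns(truth, c("phage", "strain"), "ground-truth table")
  if (!"truth" %in% names(truth)) truth$truth <- "lysis"

  null_l <- lysis_params(t0 = l$t0, tau = l$tau, lam = 0, floor = l$floor,
                         regrow_frac = 0, r2 = l$r2)
  rows <- list()
  map_rows <- list()
  well_i <- 0

  add_well <- function(curve, strain, phage, moi, replicate, role) {
    well_i <<- well_i + 1
    wid <- sprintf("W%03d", well_i)
    rows[[well_i]] <<- tibble::tibble(time_h = curve$times, well = wid,
                                      od600 = curve$od)
    map_rows[[well_i]] <<- tibble::tibble(
      well = wid, strain = strain, phage = phage, moi = moi,
      replicate = replicate, role = role)
  }

  for (s in unique(truth$strain)) {
    for (rep_i in seq_len(replicates)) {
      cs <- substream_seed(seed, paste(s, "control", rep_i, sep = "|"))
      add_well(simulate_control_curve(g, seed = cs), s, NA_character_,
               NA_real_, rep_i, "control")
    }
  }
  for (i in seq_len(nrow(truth))) {
    s <- truth$strain[i]
    p <- truth$phage[i]
    lp <- if (truth$truth[i] == "lysis") l else null_l
    for (rep_i in seq_len(replicates)) {
      ws <- substream_seed(seed, paste(s, p, moi, rep_i, sep = "|"))
      add_well(simulate_infected_curve(g, lp, moi = moi, seed = ws),
               s, p, moi, rep_i, "infected")
    }
  }
  plate_data(purrr::list_rbind(rows), purrr::list_rbind(map_rows))
}

#' Simulate an MOI-ladder plate for virulence analysis
#'
#' One strain, one phage, one infected condition per MOI of the ladder
#' (default 1, 0.1, ..., 1e-4) plus uninfected controls.
#'
#' @inheritParams simulate_plate
#' @param phage,strain Labels for the pair.
#' @param mois MOI ladder (default `10^(0:-4)`).
#' @return A `plate_data` object.
#' @export
simulate_moi_series <- function(phage = "phage", strain = "host",
                                g = growth_params(), l = lysis_params(),
                                mois = 10^(0:-4), replicates = 3, seed) {
  rows <- list()
  map_rows <- list()
  well_i <- 0
  add_well <- function(curve, moi, replicate, role) {
    well_i <<- well_i + 1
    wid <- sprintf("W%03d", well_i)
    rows[[well_i]] <<- tibble::tibble(time_h = curve$times, well = wid,
                                      od600 = curve$od)
    map_rows[[well_i]] <<- tibble::tibble(
      well = wid, strain = strain,
      phage = if (role == "control") NA_character_ else phage,
      moi = if (role == "control") NA_real_ else moi,
      replicate = replicate, role = role)
  }
  for (rep_i in seq_len(replicates)) {
    cs <- substream_seed(seed, paste(strain, "control", rep_i, sep = "|"))
    add_well(simulate_control_curve(g, seed = cs), NA_real_, rep_i, "control")
  }
  for (m in mois) {
    for (rep_i in seq_len(replicates)) {
      ws <- substream_seed(seed, paste(strain, phage, m, rep_i, sep = "|"))
      add_well(simulate_infected_curve(g, l, moi = m, seed = ws),
               m, rep_i, "infected")
    }
  }
  plate_data(purrr::list_rbind(rows), purrr::list_rbind(map_rows))
}

#' Simulate a block-structured host-range matrix
#'
#' Emulates genus-correlated host ranges: phages are partitioned into
#' genus blocks, strains round-robin into matching susceptible groups;
#' within-block cells lyse with probability `p_within`, others with
#' `p_between`. For DPA matrices a fraction of non-lysis cells becomes
#' `reduced_growth`. Optionally a `planted_set` of phages is post-edited
#' to be the unique maximum-coverage set of its size: each planted phage
#' receives a private signature strain, and every strain covered only by
#' non-planted phages is also given to a planted phage, so any other set
#' of that size misses at least one signature strain.
#'
#' @param n_phages,n_strains Matrix dimensions.
#' @param genus_blocks Integer vector of block sizes summing to
#'   `n_phages` (default: blocks of ~4).
#' @param p_within,p_between Lysis probabilities inside/outside a
#'   phage's block (defaults 0.7 / 0.1).
#' @param p_reduced Probability that a non-lysis DPA cell reads
#'   `reduced_growth` (default 0.15; forced 0 for PKA).
#' @param assay `"DPA"` or `"PKA"`.
#' @param planted_set Optional character vector of phage names (subset
#'   of `P1 ... Pn`) to plant as the unique optimum.
#' @param seed Integer seed.
#' @return A [host_range_matrix()].
#' @export
#' @examples
#' m <- simulate_host_range(8, 30, planted_set = c("P1", "P4", "P7"), seed = 1)
#' optimize_cocktail(m, k = 3, method = "exhaustive")$optimal_sets
simulate_host_range <- function(n_phages, n_strains, genus_blocks = NULL,
                                p_within = 0.7, p_between = 0.1,
                                p_reduced = 0.15, assay = c("DPA", "PKA"),
                                planted_set = NULL, seed) {
  assay <- match.arg(assay)
  if (any(c(p_within, p_between, p_reduced) < 0) ||
      any(c(p_within, p_between, p_reduced) > 1)) {
    abort_validation("probabilities must lie in [0, 1].")
  }
  genus_blocks <- genus_blocks %||%
    {
      sizes <- rep(4, n_phages %/% 4)
      left <- n_phages - sum(sizes)
      if (left > 0) sizes <- c(sizes, left)
      sizes
    }
  if (sum(genus_blocks) != n_phages) {
    abort_validation("`genus_blocks` must sum to `n_phages`.")
  }
  phages <- sprintf("P%d", seq_len(n_phages))
  strains <- sprintf("S%d", seq_len(n_strains))
  if (!is.null(planted_set)) {
    if (!all(planted_set %in% phages)) {
      abort_generation("`planted_set` must be a subset of the phage names.")
    }
    if (length(planted_set) > n_strains) {
      abort_generation("cannot plant more phages than strains (no room for signature strains).")
    }
  }
  phage_block <- rep(seq_along(genus_blocks), genus_blocks)
  strain_block <- rep_len(seq_along(genus_blocks), n_strains)

  with_seed(seed, {
    p_mat <- ifelse(outer(strain_block, phage_block, `==`), p_within, p_between)
    lys <- matrix(stats::runif(n_strains * n_phages) < p_mat,
                  nrow = n_strains, dimnames = list(strains, phages))
    calls <- ifelse(lys, "lysis", "no_lysis")
    if (assay == "DPA" && p_reduced > 0) {
      red <- !lys & matrix(stats::runif(n_strains * n_phages) < p_reduced,
                           nrow = n_strains)
      calls[red] <- "reduced_growth"
    }

    if (!is.null(planted_set)) {
      planted_idx <- match(planted_set, phages)
      # signature strains: lysed only by their planted phage
      sig <- sample(strains, length(planted_set))
      for (j in seq_along(planted_set)) {
        calls[sig[j], ] <- "no_lysis"
        calls[sig[j], planted_idx[j]] <- "lysis"
      }
      # ensure the planted union dominates: strains covered only by
      # non-planted phages are handed to the first planted phage
      lysed <- calls == "lysis"
      covered_other <- rowSums(lysed[, -planted_idx, drop = FALSE]) > 0
      covered_planted <- rowSums(lysed[, planted_idx, drop = FALSE]) > 0
      calls[covered_other & !covered_planted, planted_idx[1]] <- "lysis"
    }
    host_range_matrix(calls, assay = assay)
  })
}

#' Simulate disc-diffusion antibiograms
#'
#' Draws a resistance state per strain and breakpoint row (Bernoulli
#' with the row's antibiotic-class probability) and a zone diameter
#' uniformly inside the matching S or R range, so expected MRGN
#' fractions are computable from the probabilities. The default
#' probabilities emulate a heavily resistant clinical panel in which the
#' penicillin, cephalosporin and fluoroquinolone leads are always
#' resistant and the carbapenem lead is resistant in 61% of strains
#' (every strain at least 3MRGN, 61% expected 4MRGN).
#'
#' @param n_strains Number of strains.
#' @param breakpoints Validated breakpoint tibble.
#' @param class_resistance_probs Named numeric vector, probability of
#'   resistance per antibiotic class; classes not named use 0.5.
#' @param seed Integer seed.
#' @return Long antibiogram tibble (`strain`, `antibiotic`, `zone_mm`).
#' @export
#' @examples
#' bp <- synthetic_breakpoints()
#' ab <- simulate_antibiogram(10, bp, seed = 2)
#' dplyr::count(classify_mrgn(ab, bp), mrgn)
simulate_antibiogram <- function(n_strains,
                                 breakpoints = synthetic_breakpoints(),
                                 class_resistance_probs = c(
                                   penicillins = 1, cephalosporins = 1,
                                   fluoroquinolones = 1, carbapenems = 0.61),
                                 seed) {
  breakpoints <- validate_breakpoints(breakpoints)
  if (any(class_resistance_probs < 0) || any(class_resistance_probs > 1)) {
    abort_validation("resistance probabilities must lie in [0, 1].")
  }
  strains <- sprintf("S%d", seq_len(n_strains))
  probs <- class_resistance_probs[breakpoints$abx_class]
  probs[is.na(probs)] <- 0.5
  with_seed(seed, {
    purrr::map(strains, function(s) {
      resistant <- stats::runif(nrow(breakpoints)) < probs
      zone <- ifelse(
        resistant,
        stats::runif(nrow(breakpoints), 0, pmax(breakpoints$r_max_mm - 0.5, 0)),
        stats::runif(nrow(breakpoints), breakpoints$s_min_mm,
                     pmin(breakpoints$s_min_mm + 12, 60)))
      tibble::tibble(strain = s, antibiotic = breakpoints$antibiotic,
                     zone_mm = unname(round(zone, 1)))
    }) |>
      purrr::list_rbind()
  })
}
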