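# Synthetic-data generators: determinism, closed-form behavior, and
# validator compatibility.

test_that("control curves follow the logistic closed form without noise", {
  g <- growth_params(noise_sd = 0)
  cc <- simulate_control_curve(g, seed = 1)
  expect_equal(cc$od[1], 0.1, tolerance = 1e-12)
  fast <- growth_params(r = 3, noise_sd = 0)
  cc_fast <- simulate_control_curve(fast, seed = 1)
  expect_lt(abs(cc_fast$od[length(cc_fast$od)] - fast$K), 1e-6 * fast$K)
  # closed form agrees everywhere
  expect_equal(cc$od, closed_form_curve(g)$od, tolerance = 1e-12)
})

test_that("generators are pure functions of (params, seed)", {
  g <- growth_params(noise_sd = 0.02)
  expect_identical(simulate_control_curve(g, seed = 5)$od,
                   simulate_control_curve(g, seed = 5)$od)
  expect_false(identical(simulate_control_curve(g, seed = 5)$od,
                         simulate_control_curve(g, seed = 6)$od))
  l <- lysis_params(regrow_frac = 0.5)
  expect_identical(simulate_infected_curve(g, l, moi = 0.1, seed = 9)$od,
                   simulate_infected_curve(g, l, moi = 0.1, seed = 9)$od)
  m1 <- simulate_host_range(6, 20, seed = 3)
  m2 <- simulate_host_range(6, 20, seed = 3)
  expect_identical(m1$calls, m2$calls)
  expect_identical(simulate_antibiogram(5, seed = 4),
                   simulate_antibiogram(5, seed = 4))
})

test_that("lysis onset shifts by tau hours per decade of MOI", {
  g <- growth_params(noise_sd = 0)
  l <- lysis_params(t0 = 6, tau = 0.75, lam = 50, floor = 0)
  hi <- simulate_infected_curve(g, l, moi = 1, seed = 1)
  lo <- simulate_infected_curve(g, l, moi = 1e-4, seed = 1)
  onset_of <- function(cv) cv$times[which(diff(cv$od) < -0.01)[1]]
  expect_equal(onset_of(lo) - onset_of(hi), 4 * 0.75, tolerance = 0.3)
  # steep decay with zero floor kills the culture after onset
  late <- hi$times > 6.5
  expect_true(all(hi$od[late] < 1e-3))
})

test_that("a null phage (lam = 0, no regrowth) reproduces the control exactly", {
  g <- growth_params(noise_sd = 0)
  null_l <- lysis_params(lam = 0, regrow_frac = 0)
  infected <- simulate_infected_curve(g, null_l, moi = 0.1, seed = 2)
  control <- simulate_control_curve(g, seed = 2)
  expect_equal(infected$od, control$od, tolerance = 1e-12)
})

test_that("regrowth lifts the curve after lysis when forced on", {
  g <- growth_params(noise_sd = 0)
  l_re <- lysis_params(t0 = 1, tau = 0, lam = 5, floor = 0.02,
                       regrow_frac = 1, r2 = 0.8)
  cv <- simulate_infected_curve(g, l_re, moi = 1, seed = 13)
  post_lysis_min <- min(cv$od[cv$times > 1])
  expect_gt(cv$od[length(cv$od)], post_lysis_min + 0.1)
})

test_that("block-structured matrices honor within/between probabilities at the corners", {
  m <- simulate_host_range(6, 18, genus_blocks = c(2, 2, 2), p_within = 1,
                           p_between = 0, p_reduced = 0, seed = 8)
  tb <- tibble::as_tibble(m)
  blocks_p <- rep(1:3, each = 2)
  blocks_s <- rep_len(1:3, 18)
  tb$same_block <- blocks_s[as.integer(sub("S", "", tb$strain))] ==
    blocks_p[as.integer(sub("P", "", tb$phage))]
  expect_true(all(tb$call[tb$same_block] == "lysis"))
  expect_true(all(tb$call[!tb$same_block] == "no_lysis"))
})

test_that("PKA matrices never contain reduced_growth and planting validates", {
  m <- simulate_host_range(5, 20, assay = "PKA", seed = 2)
  expect_false(any(m$calls == "reduced_growth"))
  expect_error(simulate_host_range(4, 2, planted_set = c("P1", "P2", "P3"),
                                   seed = 1),
               class = "phagekit_generation_error")
  expect_error(simulate_host_range(4, 10, planted_set = "P9", seed = 1),
               class = "phagekit_generation_error")
})

test_that("generated tables pass every reader/validator round-trip", {
  truth <- tidyr::expand_grid(phage = c("P1", "P2"), strain = c("S1", "S2"))
  plate <- simulate_plate(truth, seed = 6, replicates = 2)
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_plate(plate, sp, mp)
  expect_no_error(read_plate(sp, mp))

  m <- simulate_host_range(6, 15, seed = 9)
  hp <- withr::local_tempfile(fileext = ".tsv")
  write_host_range(m, hp)
  expect_identical(read_host_range(hp, "DPA")$calls, m$calls)

  ab <- simulate_antibiogram(8, seed = 10)
  expect_no_error(validate_antibiogram(ab))
  expect_no_error(classify_mrgn(ab, synthetic_breakpoints()))
})

test_that("adding wells to a plate never perturbs existing wells", {
  small <- tibble::tibble(phage = "P1", strain = "S1", truth = "lysis")
  big <- tibble::tibble(phage = c("P1", "P2"), strain = c("S1", "S1"),
                        truth = c("lysis", "no_lysis"))
  g <- growth_params(noise_sd = 0.02)
  p_small <- simulate_plate(small, g = g, seed = 42)
  p_big <- simulate_plate(big, g = g, seed = 42)
  curve_for <- function(plate, phage) {
    w <- plate$map$well[!is.na(plate$map$phage) & plate$map$phage == phage]
    plate$series$od600[plate$series$well == w]
  }
  expect_identical(curve_for(p_small, "P1"), curve_for(p_big, "P1"))
})

test_that("end-to-end recovery: simulated kill and null phages give the expected calls", {
  g <- growth_params(noise_sd = 0.02)
  l_kill <- lysis_params(t0 = 0, tau = 0, lam = 10, floor = 0)
  mois <- 10^(0:-4)

  # total kill at every MOI: vp near its closed form, PKA call lysis
  plate <- simulate_moi_series(g = g, l = l_kill, seed = 3)
  vres <- virulence_analyse(plate)
  expect_gte(vres$vp, 0.75)
  vp_cf <- oracle_vp(growth_params(noise_sd = 0), l_kill, mois)
  expect_lt(abs(vres$vp - vp_cf), 0.05)

  # null phage: vp below 0.05 and PKA says no_lysis
  null_l <- lysis_params(lam = 0)
  plate0 <- simulate_moi_series(g = g, l = null_l, seed = 4)
  expect_lt(virulence_analyse(plate0)$vp, 0.05)
  truth <- tibble::tibble(phage = "Pnull", strain = "S1", truth = "no_lysis")
  pka <- pka_analyse(simulate_plate(truth, g = g, seed = 5, replicates = 3))
  expect_identical(pka$call, "no_lysis")
})
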