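# Stationary-phase detection, local virulence index vi, global index vp.

test_that("stationary onset finds the first local maximum with a 5-sample window", {
  grid10 <- seq(0, by = 0.25, length.out = 10)
  plateau <- growth_curve(grid10,
                          c(0.1, 0.2, 0.3, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4))
  expect_equal(detect_stationary_onset(plateau), 0.75)

  peak <- growth_curve(seq(0, by = 0.25, length.out = 7),
                       c(0.1, 0.5, 0.45, 0.44, 0.43, 0.42, 0.41))
  expect_equal(detect_stationary_onset(peak), 0.25)

  rising <- linear_curve(0.1, 1.1)  # strictly increasing over 24 h
  expect_equal(detect_stationary_onset(rising), 24)

  short <- growth_curve(c(0, 1, 2), c(0.1, 0.2, 0.3))
  expect_error(detect_stationary_onset(short),
               class = "phagekit_validation_error")
})

test_that("onset tolerance forgives sub-tol wobble in the plateau", {
  grid <- seq(0, by = 0.25, length.out = 12)
  od <- c(0.1, 0.2, 0.3, 0.4, 0.405, 0.402, 0.404, 0.401, 0.403, 0.4, 0.4, 0.4)
  expect_equal(detect_stationary_onset(growth_curve(grid, od), tol = 0.01),
               0.75)
  # with zero tolerance the 0.405 at index 5 wins instead
  expect_equal(detect_stationary_onset(growth_curve(grid, od), tol = 0), 1.0)
})

test_that("local virulence matches closed forms and clamps to [0, 1]", {
  ctrl <- linear_curve(0.1, 1.1)
  expect_equal(local_virulence(ctrl, ctrl, 24), 0)
  flat <- linear_curve(0.1, 0.1)
  expect_equal(local_virulence(flat, ctrl, 24), 1 - 2.4 / 14.4,
               tolerance = 1e-9)
  dead <- growth_curve(seq(0, 24, 0.25), rep(0, 97))
  expect_equal(local_virulence(dead, ctrl, 24), 1)
  overgrow <- linear_curve(0.2, 2.2)  # regrowth above control clamps at 0
  expect_equal(local_virulence(overgrow, ctrl, 24), 0)
  expect_error(local_virulence(flat, dead, 24),
               class = "phagekit_degenerate_control_error")
})

test_that("vp equals the hand-computed trapezoid of the virulence curve", {
  ctrl <- linear_curve(0.1, 1.1)
  mois <- 10^(0:-4)
  # build curves whose vi values are exactly [1, 1, 0.5, 0, 0]:
  # vi = 1 - a means the with-curve is a * control (AUC scales linearly)
  a_for_vi <- 1 - c(1, 1, 0.5, 0, 0)
  curves <- lapply(a_for_vi, function(a)
    growth_curve(ctrl$times, ctrl$od * a))
  res <- global_virulence(curves, mois, ctrl)
  expect_equal(res$area_amax, 4)
  expect_equal(res$area_ap, 2.0, tolerance = 1e-9)
  expect_equal(res$vp, 0.5, tolerance = 1e-9)
  expect_equal(res$local_vi$vi, c(0, 0, 0.5, 1, 1), tolerance = 1e-9)

  # degenerate corners: vi == 1 everywhere and vi == 0 everywhere
  all_kill <- lapply(mois, function(m) growth_curve(ctrl$times, ctrl$od * 0))
  expect_equal(global_virulence(all_kill, mois, ctrl)$vp, 1)
  all_null <- lapply(mois, function(m) ctrl)
  expect_equal(global_virulence(all_null, mois, ctrl)$vp, 0)
})

test_that("vp is invariant to MOI entry order and stays in [0, 1]", {
  ctrl <- linear_curve(0.1, 1.1)
  mois <- 10^(0:-4)
  set.seed(5)
  curves <- lapply(mois, function(m)
    growth_curve(ctrl$times, ctrl$od * runif(1, 0, 1.2)))
  ref <- global_virulence(curves, mois, ctrl)$vp
  for (i in 1:5) {
    perm <- sample(5)
    expect_equal(global_virulence(curves[perm], mois[perm], ctrl)$vp, ref,
                 tolerance = 1e-12)
  }
  expect_gte(ref, 0)
  expect_lte(ref, 1)
})

test_that("pointwise lowering any infected curve never decreases vp", {
  ctrl <- linear_curve(0.1, 1.1)
  mois <- 10^(0:-4)
  set.seed(9)
  scales <- runif(5, 0.3, 1)
  curves <- lapply(scales, function(a) growth_curve(ctrl$times, ctrl$od * a))
  base_vp <- global_virulence(curves, mois, ctrl)$vp
  for (j in 1:5) {
    lowered <- curves
    lowered[[j]] <- growth_curve(ctrl$times, curves[[j]]$od * 0.5)
    expect_gte(global_virulence(lowered, mois, ctrl)$vp, base_vp - 1e-12)
  }
})

test_that("vp rejects single or duplicate MOIs", {
  ctrl <- linear_curve(0.1, 1.1)
  expect_error(global_virulence(list(ctrl), 1, ctrl),
               class = "phagekit_validation_error")
  expect_error(global_virulence(list(ctrl, ctrl), c(1, 1), ctrl),
               class = "phagekit_validation_error")
  expect_error(global_virulence(list(ctrl, ctrl), c(1, -0.1), ctrl),
               class = "phagekit_validation_error")
})

test_that("virulence_analyse reproduces global_virulence on a simulated ladder", {
  g <- growth_params(noise_sd = 0)
  l <- lysis_params()
  plate <- simulate_moi_series(g = g, l = l, seed = 5, replicates = 1)
  res <- virulence_analyse(plate)
  expect_equal(nrow(res), 1)

  ctrl <- simulate_control_curve(g, seed = phagekit:::substream_seed(
    5, "host|control|1"))
  mois <- 10^(0:-4)
  curves <- lapply(mois, function(m) simulate_infected_curve(
    g, l, moi = m, seed = phagekit:::substream_seed(
      5, paste("host", "phage", m, 1, sep = "|"))))
  direct <- global_virulence(curves, mois, ctrl)
  expect_equal(res$vp, direct$vp, tolerance = 1e-12)
  expect_equal(res$stationary_onset, direct$stationary_onset)
  expect_equal(res$local_vi[[1]], direct$local_vi)
})

test_that("tidy and glance expose the virulence result as tibbles", {
  ctrl <- linear_curve(0.1, 1.1)
  mois <- 10^(0:-4)
  curves <- lapply(c(0, 0.2, 0.5, 0.8, 1), function(a)
    growth_curve(ctrl$times, ctrl$od * a))
  res <- global_virulence(curves, mois, ctrl)
  td <- tidy(res)
  expect_named(td, c("moi", "log10_moi", "vi"))
  expect_equal(nrow(td), 5)
  gl <- glance(res)
  expect_named(gl, c("stationary_onset", "area_ap", "area_amax", "vp"))
  expect_equal(gl$vp, res$vp)
})
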