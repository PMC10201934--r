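test_that("Frank-Tamm integral matches the constant-n closed form", {
  d <- const_dispersion(2.15)
  pref <- physical_constants()$frank_tamm_prefactor
  beta <- 0.835906
  closed <- pref * (3.8745 - 1.5498) * (1 - 1 / (beta^2 * 2.15^2))
  expect_equal(yield_per_mm(beta, d), closed, tolerance = 1e-10)
  expect_equal(closed, 59.35, tolerance = 1e-4) # independent hand evaluation
})

test_that("no yield below threshold, monotone growth above", {
  d <- bgo_fix$dispersion
  b_thr <- cherenkov_threshold(d)$beta
  expect_identical(yield_per_mm(b_thr * 0.99, d), 0)
  betas <- seq(b_thr + 0.05, 0.99, length.out = 20)
  expect_true(all(diff(yield_per_mm(betas, d)) > 0))
  expect_error(yield_per_mm(1.2, d), "beta")
})

test_that("expected photon count is invariant under step subdivision", {
  d <- bgo_fix$dispersion
  trk <- local({
    set.seed(5)
    propagate_electron(
      electron_state(0.420, c(0, 0, 5)), 0.01, bgo_tables_fix, bgo_fix,
      msc = FALSE
    )
  })
  # split every step above threshold at its path midpoint and compare
  for (i in c(1, 10, 25, 40)) {
    stp <- trk[i, ]
    if (stp$post_beta <= cherenkov_threshold(d)$beta) next
    half <- stp$length / 2
    kem <- ke_after_path(bgo_tables_fix, stp$pre_ke, half)
    bm <- kinematics(kem)$beta
    whole <- expected_photons(stp, d)
    parts <- expected_photons(
      list(length = half, pre_beta = stp$pre_beta, post_beta = bm), d
    ) + expected_photons(
      list(length = stp$length - half, pre_beta = bm, post_beta = stp$post_beta), d
    )
    expect_equal(parts, whole, tolerance = 5e-3)
  }
  # a sub-threshold step yields exactly zero
  sub <- synthetic_step(beta_pre = 0.3, beta_post = 0.2)
  expect_identical(expected_photons(sub, d), 0)
})

test_that("a coarse range-length step expects fewer photons than fine stepping", {
  d <- bgo_fix$dispersion
  set.seed(6)
  coarse <- propagate_electron(
    electron_state(0.420, c(0, 0, 5)), NULL, bgo_tables_fix, bgo_fix
  )
  fine <- propagate_electron(
    electron_state(0.420, c(0, 0, 5)), 4e-4, bgo_tables_fix, bgo_fix
  )
  expect_lt(
    sum(expected_photons(coarse, d)),
    0.75 * sum(expected_photons(fine, d))
  )
})

test_that("photons are emitted exactly on the Cerenkov cone", {
  d <- bgo_fix$dispersion
  step <- synthetic_step(beta_pre = 0.9, length = 0.5, dir = c(0, 0, 1))
  set.seed(8)
  ph <- emit_cherenkov(step, d)
  expect_gt(nrow(ph), 10)
  n_e <- refractive_index(d, ph$energy)
  cos_expected <- 1 / (0.9 * n_e)
  cos_actual <- ph$dir_z # step direction is +z
  expect_equal(cos_actual, cos_expected, tolerance = 1e-9)
  # threshold consistency: local beta * n(e) > 1 for every photon
  expect_true(all(0.9 * n_e > 1))
  # energies stay in the optical window
  expect_true(all(ph$energy >= min(d$energy) & ph$energy <= max(d$energy)))
  # emission order is the time order
  expect_true(all(diff(ph$time) >= 0))
  expect_identical(ph$order, seq_len(nrow(ph)))
})

test_that("sub-threshold steps emit nothing", {
  step <- synthetic_step(beta_pre = 0.35, beta_post = 0.3)
  set.seed(9)
  expect_identical(nrow(emit_cherenkov(step, bgo_fix$dispersion)), 0L)
})

test_that("per-step counts are Poisson distributed", {
  d <- bgo_fix$dispersion
  steps <- do.call(rbind, replicate(10000, synthetic_step(0.9, length = 0.05),
    simplify = FALSE
  ))
  set.seed(10)
  ph <- emit_cherenkov(steps, d)
  counts <- tabulate(ph$step, nbins = nrow(steps))
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
  expect_equal(mean(counts), expected_photons(steps[1, ], d), tolerance = 0.05)
})

test_that("pre-step yield mode biases long threshold-crossing steps down", {
  d <- bgo_fix$dispersion
  # one range-length step: pre-yield expectation thinned by the local
  # sub-threshold discard lands below the fine-step total
  set.seed(12)
  coarse <- propagate_electron(
    electron_state(0.420, c(0, 0, 5)), NULL, bgo_tables_fix, bgo_fix
  )
  n_pre <- mean(replicate(200, nrow(emit_cherenkov(coarse, d, beta_mode = "pre"))))
  fine_total <- 16.0 # trapezoid integral over a finely stepped track
  expect_lt(n_pre, fine_total)
  expect_gt(n_pre, 0.6 * fine_total)
})

test_that("scintillation photons are isotropic and exponentially delayed", {
  set.seed(11)
  trk <- propagate_electron(
    electron_state(0.420, c(0, 0, 5)), NULL, bgo_tables_fix, bgo_fix
  )
  ph <- emit_scintillation(trk, bgo_fix$dispersion, decimation = 1)
  expect_gt(nrow(ph), 2000)
  delay <- ph$time - min(trk$pre_time)
  expect_equal(mean(delay), 300, tolerance = 0.05)
  expect_lt(abs(mean(ph$dir_z)), 3 / sqrt(nrow(ph)))
  expect_true(all(ph$energy >= min(bgo_fix$dispersion$energy) &
    ph$energy <= max(bgo_fix$dispersion$energy)))
  # no energy deposited, no photons
  still <- trk[1, ]
  still$post_ke <- still$pre_ke
  expect_identical(nrow(emit_scintillation(still, bgo_fix$dispersion)), 0L)
})
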