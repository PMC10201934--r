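test_that("kinematics reproduces beta and gamma", {
  expect_equal(kinematics(0)$beta, 0)
  expect_equal(kinematics(0)$gamma, 1)
  # direct evaluation for the 0.420 MeV photoelectron
  k <- kinematics(0.420)
  expect_equal(k$beta, 0.83591, tolerance = 1e-5)
  expect_equal(k$gamma, 1.82192, tolerance = 1e-5)
  kes <- seq(0.01, 2, length.out = 50)
  b <- kinematics(kes)$beta
  expect_true(all(diff(b) > 0))
  expect_true(all(b < 1))
})

test_that("interaction depths are exponential and forced into the crystal", {
  mu <- photoelectric_mu(bgo_fix)
  expect_equal(mu, 0.056 * 7.13 / 10, tolerance = 1e-12) # 0.0399 /mm
  set.seed(42)
  d <- sample_interaction_depth(5000, mu, 20)
  expect_true(all(d > 0 & d <= 20))
  # with a crystal much longer than 1/mu the truncation is negligible and
  # the sample mean approaches 1/mu
  set.seed(43)
  d2 <- sample_interaction_depth(2e4, 1, 1e6)
  expect_equal(mean(d2), 1, tolerance = 0.03)
})

test_that("photoelectron energy is the gamma energy minus the K edge", {
  bgo_k <- make_bgo(k_shell_prob = 1)
  e <- make_photoelectron(0.511, bgo_k, depth = 5)
  expect_equal(e$ke, 0.420, tolerance = 1e-12)
  e2 <- make_photoelectron(1.000, bgo_k, depth = 5)
  expect_equal(e2$ke, 0.909, tolerance = 1e-12)
  expect_error(make_photoelectron(0.05, bgo_k, depth = 5), "exceed")
  # clock starts at the gamma flight time (source 10 mm upstream)
  expect_equal(e$time, (10 + 5) / physical_constants()$c_mm_ns, tolerance = 1e-12)
})

test_that("photoelectrons are emitted preferentially forward", {
  set.seed(7)
  z <- replicate(2000, make_photoelectron(0.511, bgo_fix, depth = 5)$direction[3])
  expect_gt(mean(z), 0.3)
})

test_that("the velocity-limited step follows the delta-gamma rule", {
  st <- electron_state(0.420)
  # independent evaluation: beta_f = beta(1 - 0.1), dKE = m dgamma = 0.15535
  len <- limited_step_length(st, 0.1, bgo_tables_fix, beta_threshold = 0.4237)
  dke <- len * collision_stopping_power(bgo_fix, 0.420)
  expect_equal(dke, 0.15535, tolerance = 2e-3)
  dx <- csda_range(bgo_tables_fix, 0.420) - csda_range(bgo_tables_fix, 0.01)
  # large velocity change: the range-based default step wins
  for (db in c(0.3, 0.5, 0.9)) {
    expect_equal(
      limited_step_length(st, db, bgo_tables_fix, beta_threshold = 0.4237), dx
    )
  }
  expect_equal(
    limited_step_length(st, NULL, bgo_tables_fix, beta_threshold = 0.4237), dx
  )
  # below the Cerenkov threshold the limit does not apply
  low <- electron_state(0.02)
  expect_equal(
    limited_step_length(low, 1e-4, bgo_tables_fix, beta_threshold = 0.4237),
    limited_step_length(low, NULL, bgo_tables_fix, beta_threshold = 0.4237)
  )
  expect_error(limited_step_length(st, 0, bgo_tables_fix), "delta_beta")
  expect_error(limited_step_length(st, 1.5, bgo_tables_fix), "delta_beta")
})

test_that("multiple scattering widths follow the Highland sqrt(x) scaling", {
  k <- kinematics(0.42)
  t_small <- highland_theta0(k$beta, k$gamma, 2e-4, bgo_fix$x0_mm)
  t_large <- highland_theta0(k$beta, k$gamma, 0.2, bgo_fix$x0_mm)
  expect_equal(t_large / t_small, sqrt(1000), tolerance = 1e-9)
  # Gaussian small-angle oracle: E[cos theta] = exp(-theta0^2/2)
  st <- electron_state(0.42)
  step <- 0.001
  theta0 <- highland_theta0(st$beta, st$gamma, step, bgo_fix$x0_mm)
  set.seed(9)
  cosd <- replicate(10000, sum(scatter_direction(st, step, bgo_fix) * st$direction))
  expect_equal(mean(cosd), exp(-theta0^2 / 2), tolerance = 0.02)
  expect_error(scatter_direction(st, 0, bgo_fix), "positive")
})

test_that("default stepping gives two steps with a range-length first step", {
  set.seed(21)
  trk <- propagate_electron(
    electron_state(0.420, c(0, 0, 5)), NULL, bgo_tables_fix, bgo_fix
  )
  expect_equal(nrow(trk), 2)
  expect_equal(trk$length[1], 0.348, tolerance = 0.15)
  expect_lt(trk$length[2], 0.005) # terminal step of a few microns
  # the first step agrees with the standalone step rule
  st <- electron_state(0.420, c(0, 0, 5))
  thr <- cherenkov_threshold(bgo_fix$dispersion)$beta
  expect_equal(
    trk$length[1],
    limited_step_length(st, NULL, bgo_tables_fix, beta_threshold = thr),
    tolerance = 1e-9
  )
})

test_that("strong velocity limiting yields thousands of sub-micron steps", {
  set.seed(22)
  trk <- propagate_electron(
    electron_state(0.420, c(0, 0, 5)), 4e-4, bgo_tables_fix, bgo_fix
  )
  expect_gt(nrow(trk), 1400)
  expect_lt(nrow(trk), 2000)
  expect_equal(mean(trk$length) * 1000, 0.2, tolerance = 0.3)
})

test_that("tracks conserve energy and are geometrically contiguous", {
  set.seed(23)
  for (db in list(NULL, 0.1, 4e-4)) {
    trk <- propagate_electron(
      electron_state(0.420, c(0, 0, 5)), db, bgo_tables_fix, bgo_fix
    )
    n <- nrow(trk)
    # telescoping energy bookkeeping
    expect_equal(sum(trk$pre_ke - trk$post_ke), 0.420 - trk$post_ke[n],
      tolerance = 1e-6
    )
    expect_true(all(trk$post_ke < trk$pre_ke))
    expect_true(all(trk$length > 0))
    # contiguity: post position of step i is pre position of step i+1
    if (n > 1) {
      post_x <- trk$pre_x + trk$length * trk$dir_x
      post_z <- trk$pre_z + trk$length * trk$dir_z
      expect_equal(post_x[-n], trk$pre_x[-1], tolerance = 1e-9)
      expect_equal(post_z[-n], trk$pre_z[-1], tolerance = 1e-9)
    }
    # time advances with the pre-step velocity
    expect_equal(
      trk$post_time - trk$pre_time,
      trk$length / (trk$pre_beta * physical_constants()$c_mm_ns),
      tolerance = 1e-12
    )
    # path length never exceeds the CSDA range
    expect_lte(sum(trk$length), csda_range(bgo_tables_fix, 0.420) * (1 + 1e-6))
  }
})

test_that("track length does not depend on the velocity limit", {
  lens <- vapply(list(NULL, 0.1, 1e-3), function(db) {
    set.seed(31)
    trk <- propagate_electron(
      electron_state(0.420, c(0, 0, 5)), db, bgo_tables_fix, bgo_fix
    )
    sum(trk$length)
  }, numeric(1))
  expect_equal(max(lens) - min(lens), 0, tolerance = 1e-6)
})
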