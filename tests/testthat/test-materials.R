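test_that("BGO composition matches the stoichiometry of Bi4Ge3O12", {
  # independent oracle: weight fractions from standard atomic masses
  mw <- 4 * 208.980 + 3 * 72.630 + 12 * 15.999
  expect_equal(bgo_fix$density, 7.13)
  w <- setNames(bgo_fix$elements$w, bgo_fix$elements$symbol)
  expect_equal(unname(w["Bi"]), 4 * 208.980 / mw, tolerance = 1e-3)
  expect_equal(unname(w["Ge"]), 3 * 72.630 / mw, tolerance = 1e-3)
  expect_equal(unname(w["O"]), 12 * 15.999 / mw, tolerance = 1e-3)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(bgo_fix$shells$binding[bgo_fix$shells$shell == "K"], 0.091)
  lm <- bgo_fix$shells$binding[bgo_fix$shells$shell == "LM"]
  expect_true(lm > 0.001 && lm < 0.016)
})

test_that("TlBr has the stoichiometric fractions and 440-800 nm window", {
  tlbr <- make_tlbr()
  mw <- 204.38 + 79.904
  expect_equal(tlbr$elements$w[tlbr$elements$symbol == "Tl"],
    204.38 / mw,
    tolerance = 1e-3
  )
  expect_equal(tlbr$elements$w[tlbr$elements$symbol == "Br"],
    79.904 / mw,
    tolerance = 1e-3
  )
  expect_equal(nm_from_energy(max(tlbr$dispersion$energy)), 440, tolerance = 1e-6)
  expect_equal(nm_from_energy(min(tlbr$dispersion$energy)), 800, tolerance = 1e-6)
  # mid-band index near the published ~2.5
  mid <- refractive_index(tlbr$dispersion, mean(range(tlbr$dispersion$energy)))
  expect_equal(mid, 2.5, tolerance = 0.05)
})

test_that("BGO dispersion runs from 2.36 at 320 nm to 2.07 at 800 nm", {
  d <- bgo_fix$dispersion
  expect_equal(refractive_index(d, energy_from_nm(320)), 2.36, tolerance = 1e-9)
  expect_equal(refractive_index(d, energy_from_nm(800)), 2.07, tolerance = 1e-9)
  expect_true(all(diff(d$n) > 0)) # monotone in energy (normal dispersion)
})

test_that("refractive_index interpolates linearly and rejects out-of-window", {
  d <- bgo_fix$dispersion
  i <- 5
  expect_identical(refractive_index(d, d$energy[i]), d$n[i])
  mid_e <- (d$energy[i] + d$energy[i + 1]) / 2
  expect_equal(refractive_index(d, mid_e), (d$n[i] + d$n[i + 1]) / 2,
    tolerance = 1e-12
  )
  expect_error(refractive_index(d, 0.5), "window")
  expect_error(refractive_index(d, 10), "window")
})

test_that("group index follows n + e dn/de", {
  expect_equal(group_index(const_dispersion(2.15), 2.5), 2.15, tolerance = 1e-12)
  # two-point linear dispersion: closed-form derivative
  d2 <- structure(
    list(energy = c(2, 3), n = c(2.0, 2.2), absorption_mm = c(3000, 3000)),
    class = "cer_dispersion"
  )
  expect_equal(group_index(d2, 2.5), 2.1 + 2.5 * 0.2, tolerance = 1e-12)
  # BGO has normal dispersion: group index exceeds phase index mid-band
  e_mid <- mean(range(bgo_fix$dispersion$energy))
  expect_gt(
    group_index(bgo_fix$dispersion, e_mid),
    refractive_index(bgo_fix$dispersion, e_mid)
  )
})

test_that("Cerenkov threshold follows 1/max(n) and falls as n rises", {
  thr <- cherenkov_threshold(bgo_fix$dispersion)
  expect_equal(thr$beta, 1 / 2.36, tolerance = 1e-12)
  expect_equal(thr$ke_mev, 0.0531, tolerance = 1e-2)
  # nearly index-matched medium: threshold just below 1
  thin <- const_dispersion(1.0001)
  expect_gt(cherenkov_threshold(thin)$beta, 0.999)
  # raising n lowers the kinetic threshold
  hi <- const_dispersion(2.8)
  expect_lt(cherenkov_threshold(hi)$ke_mev, thr$ke_mev)
})

test_that("mean excitation energy follows Bragg additivity", {
  # single element degenerates to that element's I-value
  one <- data.frame(symbol = "Ge", w = 1)
  expect_equal(mean_excitation_energy(one), 350, tolerance = 1e-9)
  # BGO lands on the accepted ~534 eV
  expect_equal(mean_excitation_energy(bgo_fix$elements), 534.1, tolerance = 1e-2)
  # symmetric under permutation of the element list
  perm <- bgo_fix$elements[c(3, 1, 2), ]
  expect_equal(
    mean_excitation_energy(perm),
    mean_excitation_energy(bgo_fix$elements)
  )
  expect_error(mean_excitation_energy(data.frame(symbol = "Xx", w = 1)), "unknown")
})

test_that("materials round-trip through JSON and YAML", {
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_material(bgo_fix, path)
    back <- read_material(path)
    expect_equal(back$density, bgo_fix$density)
    expect_equal(back$i_ev, bgo_fix$i_ev, tolerance = 1e-9)
    expect_equal(back$dispersion$n, bgo_fix$dispersion$n, tolerance = 1e-12)
    expect_equal(back$shells$prob, bgo_fix$shells$prob)
    unlink(path)
  }
})
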