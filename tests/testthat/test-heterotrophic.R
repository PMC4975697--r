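test_that("nitrogenase switches have the stated values and supports", {
  # fN vanishes identically above the 100 mg/L nitrate threshold
  expect_identical(switch_fN(c(100, 150, 200, 1000)), rep(0, 4))
  expect_equal(switch_fN(0), 100 / sqrt(100^2 + 0.1))       # ~0.999995
  expect_true(all(switch_fN(seq(0, 300, 0.5)) >= 0 &
                  switch_fN(seq(0, 300, 0.5)) <= 1))
  expect_identical(switch_fO(0), 1)
  expect_equal(switch_fO(10), 1 - 10 / sqrt(10^2 + 0.1))    # ~5e-4
  expect_equal(switch_fO(0.1), 1 - 0.1 / sqrt(0.1^2 + 0.1)) # ~0.6985
  expect_error(switch_fN(-1), "non-negative")
  expect_error(switch_fO(-1), "non-negative")
})

test_that("stationary/decay-phase reduction of the derivatives holds term by
           term", {
  hp <- heterotrophic_params()
  o <- lab_optics()
  lc <- lab_light(I0 = 457)
  st <- culture_state(X = 3.5, N = 0, q = hp$kq, C = 50, O2 = 0)
  d <- rhs_heterotrophic(st, hp, o, lc)
  hbar <- depth_averaged_response(3.5, o, lc, h2_resp())
  expect_equal(d[["X"]], -hp$mu_d_h * 3.5^2)
  expect_identical(d[["N"]], 0)
  expect_identical(d[["q"]], 0)
  expect_equal(d[["C"]], -hp$Y_C * 3.5)
  expect_identical(d[["O2"]], 0)   # fO(0) = 1 kills the decay consumption
  expect_equal(d[["H2"]], hp$Y_HX * hbar * 3.5 * switch_fN(0))
})

test_that("without biomass only the quota can move", {
  hp <- heterotrophic_params()
  d <- rhs_heterotrophic(culture_state(X = 0, N = 200, q = hp$kq, C = 30),
                         hp, lab_optics(), lab_light())
  expect_identical(unname(d[c("X", "N", "C", "O2", "H2")]), rep(0, 5))
  expect_gt(d[["q"]], 0)   # at the quota floor, uptake replenishes q
})

test_that("the degenerate K_C = 0 Monod term makes growth independent of the
           glycerol level while C > 0", {
  hp <- heterotrophic_params()     # K_C = 0
  o <- lab_optics(); lc <- lab_light()
  d50 <- rhs_heterotrophic(culture_state(0.5, 300, 0.8, 50), hp, o, lc)
  d05 <- rhs_heterotrophic(culture_state(0.5, 300, 0.8, 0.5), hp, o, lc)
  expect_equal(d50[["X"]], d05[["X"]])
  expect_equal(d50[["q"]], d05[["q"]])
  # exhausted glycerol stops growth and its own consumption
  dd <- het_derivs(c(X = 0.5, N = 300, q = 0.8, C = 0, O2 = 0, H2 = 0),
                   hp, o, lc)
  expect_lt(dd[["X"]], 0)          # only decay remains
  expect_identical(dd[["C"]], 0)
  expect_error(rhs_heterotrophic(c(X = 1, N = 1, q = 0, C = 1, O2 = 0,
                                   H2 = 0), hp, o, lc), "positive")
})

test_that("a nutrient-replete batch runs through the expected phases", {
  hp <- heterotrophic_params()
  tr <- simulate_heterotrophic(replete_state(), seq(0, 150, 1), hp,
                               lab_optics(), lab_light())
  # nitrate falls monotonically to depletion
  expect_true(all(diff(tr$N) <= 1e-9))
  expect_lt(tr$N[nrow(tr)], 1e-6)
  # hydrogen stays off while nitrate is above the switch threshold
  expect_true(all(tr$H2[tr$N > 100] < 1e-9))
  expect_gt(tr$H2[nrow(tr)], 10)
  # hydrogen is cumulative, hence non-decreasing
  expect_true(all(diff(tr$H2) >= -1e-9))
  # oxygen rises during nitrate uptake, then collapses to ~0
  expect_gt(max(tr$O2), 0.01)
  expect_lt(tr$O2[nrow(tr)], 1e-6)
  # the quota never falls below its minimum
  expect_true(all(tr$q >= hp$kq - 1e-9))
  # glycerol is consumed but never exhausted in this design
  expect_true(all(diff(tr$C) <= 1e-9))
  expect_gt(tr$C[nrow(tr)], 10)
})

test_that("cumulative hydrogen is exactly proportional to its yield", {
  hp <- heterotrophic_params()
  hp2 <- heterotrophic_params(Y_HX = 2 * 14.20)
  times <- seq(0, 150, 10)
  ctl <- solver_control(rtol = 1e-10, atol = 1e-12)
  h1 <- simulate_heterotrophic(replete_state(), times, hp, lab_optics(),
                               lab_light(), ctl)$H2
  h2 <- simulate_heterotrophic(replete_state(), times, hp2, lab_optics(),
                               lab_light(), ctl)$H2
  on <- h1 > 1e-6
  expect_equal(h2[on] / h1[on], rep(2, sum(on)), tolerance = 1e-6)
})

test_that("fixed-step RK4 reproduces the stiff solver through the
           nitrate-depletion transient", {
  hp <- heterotrophic_params()
  times <- seq(0, 60, 5)
  r4 <- simulate_heterotrophic(replete_state(), times, hp, lab_optics(),
                               lab_light(), solver_control("rk4", dt = 1e-3))
  rl <- simulate_heterotrophic(replete_state(), times, hp, lab_optics(),
                               lab_light(),
                               solver_control(rtol = 1e-10, atol = 1e-12))
  m4 <- as.matrix(r4[, -1]); ml <- as.matrix(rl[, -1])
  scale <- apply(abs(ml), 2, max)
  expect_lt(max(t(abs(m4 - ml)) / scale), 1e-5)
})

test_that("collocation stepping agrees with the stiff solver", {
  hp <- heterotrophic_params()
  times <- seq(0, 150, 5)
  ctl <- solver_control("collocation")
  cc <- simulate_heterotrophic(replete_state(), times, hp, lab_optics(),
                               lab_light(), ctl)
  rl <- simulate_heterotrophic(replete_state(), times, hp, lab_optics(),
                               lab_light(),
                               solver_control(rtol = 1e-12, atol = 1e-14))
  expect_lt(max(abs(as.matrix(cc[, -1]) - as.matrix(rl[, -1]))), 5e-4)
})

test_that("average hydrogen productivity is H2(T)/T and vanishes without
           light", {
  hp <- heterotrophic_params()
  o <- lab_optics()
  lc <- light_config(457, 0.025)
  pr <- average_h2_productivity(duration = 240, params = hp, optics = o,
                                light = lc)
  tr <- simulate_heterotrophic(stationary_phase_state(), c(0, 240), hp, o, lc)
  expect_equal(pr, tr$H2[2] / 240)
  expect_gt(pr, 1)                       # order of magnitude sanity
  dark <- average_h2_productivity(duration = 240, params = hp, optics = o,
                                  light = light_config(0, 0.025))
  expect_equal(dark, 0)
})
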