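test_that("the hydrogen yield has unit normalized sensitivity wherever
           hydrogen is present", {
  # H2 enters no other balance, so H2(t) is exactly linear in Y_HX and
  # S(H2 wrt Y_HX) = 1 analytically; evaluate at reference integration
  # accuracy so solver error stays far below the identity
  s <- normalized_sensitivity("H2", "Y_HX", times = seq(0, 150, 5),
                              params = heterotrophic_params(),
                              state0 = replete_state(),
                              optics = lab_optics(), light = lab_light(),
                              control = solver_control(rtol = 1e-11,
                                                       atol = 1e-13))
  on <- !is.na(s$S)
  expect_gt(sum(on), 10)
  expect_equal(s$S[on], rep(1, sum(on)), tolerance = 1e-6)
})

test_that("sensitivity signs match the physiology during growth", {
  args <- list(times = seq(0, 40, 5), params = heterotrophic_params(),
               state0 = replete_state(), optics = lab_optics(),
               light = lab_light())
  s_mu <- do.call(normalized_sensitivity, c(list("X", "mu_max_h"), args))
  s_kq <- do.call(normalized_sensitivity, c(list("X", "kq"), args))
  grow <- s_mu$t >= 10
  expect_true(all(s_mu$S[grow] > 0))   # faster growth, more biomass
  expect_true(all(s_kq$S[grow] < 0))   # higher quota floor, earlier arrest
})

test_that("central differences are consistent across perturbation sizes", {
  run <- function(d)
    normalized_sensitivity("X", "mu_max_h", perturbation = d,
                           times = seq(0, 60, 10),
                           params = heterotrophic_params(),
                           state0 = replete_state(), optics = lab_optics(),
                           light = lab_light())$S
  s1 <- run(0.01); s2 <- run(0.002)
  expect_equal(s1[-1], s2[-1], tolerance = 1e-3)
})

test_that("outputs below the floor are flagged undefined, never NaN", {
  # hydrogen is identically zero while nitrate is high: restrict to the
  # pre-depletion window
  s <- normalized_sensitivity("H2", "mu_max_h", times = seq(0, 20, 5),
                              params = heterotrophic_params(),
                              state0 = replete_state(),
                              optics = lab_optics(), light = lab_light())
  expect_true(all(is.na(s$S)))
  expect_false(any(is.nan(s$S)))
  expect_identical(attr(s, "undefined_outputs"), "H2")
})

test_that("autotrophic sensitivities work through the same interface", {
  s <- normalized_sensitivity("X", "mu_max_a", times = seq(0, 100, 20),
                              model = "autotrophic",
                              params = autotrophic_params(), state0 = 0.1,
                              optics = lab_optics(),
                              light = light_config(457, 0.025))
  expect_true(all(s$S[-1] > 0))
  expect_error(
    normalized_sensitivity("X", "bogus", times = c(0, 10),
                           model = "autotrophic",
                           params = autotrophic_params(), state0 = 0.1,
                           optics = lab_optics(),
                           light = light_config(457, 0.025)),
    "unknown")
})

test_that("the mutant transform rescales exactly the light-coupled
           parameters", {
  id <- mutant_transform(autotrophic_params(), lab_optics(),
                         mutant_scenario(0))
  expect_equal(id$params, autotrophic_params())
  expect_equal(id$optics, lab_optics())

  m <- mutant_transform(heterotrophic_params(), lab_optics(),
                        mutant_scenario(0.3))
  expect_equal(m$params$growth_response$ks, 165 / 0.7)   # ~235.7
  expect_equal(m$params$growth_response$ki, 457 / 0.7)   # ~652.9
  expect_equal(m$params$h2_response$ks, 140 / 0.7)
  expect_equal(m$params$h2_response$ki, 457 / 0.7)
  expect_equal(m$optics$tau_c, 0.126 * 0.7)              # 0.0882
  expect_equal(m$params$mu_max_h, 0.332)                 # kinetics untouched
  expect_error(mutant_scenario(1), "\\[0, 1\\)")
  expect_error(mutant_scenario(-0.1), "\\[0, 1\\)")
})

test_that("reduced absorption wins in a wide reactor: mutant depth-averaged
           response and biomass ceiling at least match the wild type", {
  lc <- light_config(457, 0.2)
  m <- mutant_transform(autotrophic_params(), lab_optics(),
                        mutant_scenario(0.3))
  for (X in c(0.5, 1, 2, 4, 8)) {
    expect_gte(
      depth_averaged_response(X, m$optics, lc, m$params$growth_response),
      depth_averaged_response(X, lab_optics(), lc, growth_resp()))
  }
  expect_gte(steady_state_cmax(m$params, m$optics, lc),
             steady_state_cmax(autotrophic_params(), lab_optics(), lc))
})

test_that("scale-up sweeps label rows by design key and isolate failures", {
  specs <- list(reactor_spec(457, 1, 0.025), reactor_spec(457, 1, 0.10),
                reactor_spec(0, 1, 0.025))
  tab <- suppressMessages(scaleup_sweep(specs, mode = "cmax"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$key, c("457-1-0.025", "457-1-0.1", "0-1-0.025"))
  expect_true(all(is.finite(tab$value[1:2])))
  expect_gt(tab$value[1], tab$value[2])
  expect_true(is.na(tab$value[3]))     # dark reactor has no growth balance
  h2 <- scaleup_sweep(list(reactor_spec(457, 1, 0.025)), mode = "h2")
  expect_equal(h2$metric, "h2")
  expect_gt(h2$value, 0)
})

test_that("reactor keys parse back into design points", {
  sp <- parse_reactor_key("914-2-0.2")
  expect_equal(sp$I0, 914)
  expect_equal(sp$n_surfaces, 2L)
  expect_equal(sp$d, 0.2)
  expect_error(parse_reactor_key("914-2"), "I0-n-d")
})
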