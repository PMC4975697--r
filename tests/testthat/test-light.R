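test_that("Aiba photoresponse has the right values, optimum and limits", {
  p <- growth_resp()
  expect_identical(photoresponse(0, p), 0)
  # direct arithmetic: I = ki makes the denominator I + ks + I
  expect_equal(photoresponse(457, p), 457 / (457 + 165 + 457))
  # closed-form optimum at sqrt(ks*ki), checked against numerical argmax
  opt <- stats::optimize(function(I) photoresponse(I, p),
                         c(0, 5000), maximum = TRUE)$maximum
  expect_equal(opt, sqrt(165 * 457), tolerance = 1e-4)
  # vanishes in both limits, stays in [0, 1)
  expect_lt(photoresponse(1e9, p), 1e-3)
  I <- seq(0, 3000, 10)
  expect_true(all(photoresponse(I, p) >= 0 & photoresponse(I, p) < 1))
  expect_error(photoresponse(-1, p), "non-negative")
})

test_that("extinction coefficient = cell absorption (g/m^3) + bubble term", {
  o <- lab_optics()
  expect_equal(attenuation_coefficient(0, o), 3 * 0.0067 / 0.002)    # 10.05
  a05 <- attenuation_coefficient(0.5, o)
  expect_equal(a05, 0.126 * 500 + 10.05)                             # 73.05
  # cell term dominates bubble scattering ~6-7x already at 0.5 g/L
  expect_gt((a05 - 10.05) / 10.05, 6)
  expect_lt((a05 - 10.05) / 10.05, 7)
  expect_equal(attenuation_coefficient(12, o), 1512 + 10.05)
  expect_error(attenuation_coefficient(-0.1, o), "non-negative")
})

test_that("local light intensity decays exponentially and mirrors for
           two-sided illumination", {
  o <- lab_optics()
  lc1 <- lab_light(I0 = 92)
  expect_equal(local_intensity(0, 1, o, lc1), 92)
  expect_equal(local_intensity(0.025, 1, o, lc1),
               92 * exp(-(0.126 * 1000 + 10.05) * 0.025))   # ~3.07
  lc2 <- lab_light(I0 = 92, n_surfaces = 2)
  z <- c(0, 0.005, 0.011)
  expect_equal(local_intensity(z, 0.8, o, lc2),
               local_intensity(0.025 - z, 0.8, o, lc2))
  expect_error(local_intensity(0.03, 1, o, lc1), "within")
  expect_error(local_intensity(-1e-9, 1, o, lc1), "within")
})

test_that("depth average reduces to the surface response in a transparent
           medium and decreases with biomass", {
  lc <- lab_light(I0 = 92)
  kb <- depth_averaged_response(5, clear_optics(), lc, growth_resp())
  expect_equal(kb, photoresponse(92, growth_resp()), tolerance = 1e-9)
  # self-shading: strictly decreasing in biomass (one-sided)
  o <- lab_optics()
  for (I0 in c(92, 457)) {
    ks <- vapply(c(0.5, 1.0, 1.8, 5, 12), depth_averaged_response,
                 numeric(1), optics = o, light = lab_light(I0 = I0),
                 response = growth_resp())
    expect_strictly_decreasing(ks)
  }
})

test_that("depth average never exceeds the response at the optimal
           intensity", {
  o <- lab_optics()
  kmax <- photoresponse(sqrt(165 * 457), growth_resp())
  for (X in c(0, 0.3, 1, 4, 12))
    expect_lte(depth_averaged_response(X, o, lab_light(I0 = 457),
                                       growth_resp()), kmax)
})

test_that("20-interval trapezoid stays within 10% of a high-resolution
           reference even at 12 g/L", {
  o <- lab_optics()
  lc <- light_config(I0 = 457, L = 0.025)
  k20 <- depth_averaged_response(12, o, lc, growth_resp(), n_steps = 20)
  kref <- depth_averaged_response(12, o, lc, growth_resp(), n_steps = 1e4)
  expect_lt(abs(k20 - kref) / kref, 0.10)
})

test_that("trapezoid average converges to the substitution-rule integral", {
  # u = I0 exp(-a z) turns (1/L) int k(I(z)) dz into
  # (1/(a L)) int_{I(L)}^{I0} du / (u + ks + u^2/ki) for one-sided light
  o <- lab_optics()
  for (X in c(0.5, 2, 8)) {
    lc <- light_config(I0 = 457, L = 0.025)
    a <- attenuation_coefficient(X, o)
    IL <- 457 * exp(-a * lc$L)
    oracle <- stats::integrate(function(u) 1 / (u + 165 + u^2 / 457),
                               IL, 457, rel.tol = 1e-10)$value / (a * lc$L)
    k <- depth_averaged_response(X, o, lc, growth_resp(), n_steps = 2e4)
    expect_equal(k, oracle, tolerance = 1e-6)
  }
})

test_that("sub-inhibitory two-sided illumination outperforms one-sided at
           equal per-surface intensity", {
  # guaranteed only when local intensities stay below the optimum
  # sqrt(ks*ki) ~ 275, where the response is monotone in I
  o <- lab_optics()
  for (L in c(0.025, 0.2)) for (X in c(0.01, 0.5, 2, 12)) {
    k1 <- depth_averaged_response(X, o, light_config(92, L, 1),
                                  growth_resp())
    k2 <- depth_averaged_response(X, o, light_config(92, L, 2),
                                  growth_resp())
    expect_gte(k2, k1)
  }
})

test_that("adaptive refinement only engages at large optical depth and
           matches the converged quadrature there", {
  o <- lab_optics()
  # lab scale, low biomass: adaptive result identical to the base 20 steps
  lc_lab <- light_config(92, 0.025, adaptive = TRUE)
  expect_identical(
    depth_averaged_response(1, o, lc_lab, growth_resp()),
    depth_averaged_response(1, o, lc_lab, growth_resp(), n_steps = 20))
  # thick plate, dense culture: adaptive tracks the reference, fixed-20 not
  lc_big <- light_config(457, 0.2, adaptive = TRUE)
  kad <- depth_averaged_response(3, o, lc_big, growth_resp())
  kref <- depth_averaged_response(3, o, lc_big, growth_resp(),
                                  n_steps = 5e4)
  k20 <- depth_averaged_response(3, o, lc_big, growth_resp(), n_steps = 20)
  # half-attenuation-length steps keep the quadrature within ~1% here,
  # an order of magnitude below the fixed-20 error
  expect_equal(kad, kref, tolerance = 0.01)
  expect_gt(abs(k20 - kref) / kref, 10 * abs(kad - kref) / kref)
})

test_that("constructors reject invalid optics and geometry", {
  expect_error(optical_params(tau_c = -1), "positive")
  expect_error(light_config(I0 = -5, L = 0.025), "non-negative")
  expect_error(light_config(I0 = 92, L = 0), "positive")
  expect_error(light_config(I0 = 92, L = 0.025, n_surfaces = 3), "1 or 2")
  expect_error(light_config(I0 = 92, L = 0.025, n_steps = 1), ">= 2")
  expect_error(photo_response(0, 457), "positive")
})
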