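# Shared fixtures: the laboratory flat plate and standard batch conditions.

lab_optics <- function() optical_params()

lab_light <- function(I0 = 92, L = 0.025, ...) light_config(I0 = I0, L = L, ...)

growth_resp <- function() photo_response(165, 457)

h2_resp <- function() photo_response(140, 457)

replete_state <- function() culture_state(X = 0.2, N = 500, q = 1, C = 50)

# near-transparent medium: drives attenuation to ~0 so the light field is
# uniform at I0 (constructors require strictly positive optics)
clear_optics <- function() optical_params(tau_c = 1e-12, alpha_g = 1e-12,
                                          d_b = 1)

expect_strictly_decreasing <- function(x) {
  expect_true(all(diff(x) < 0),
              label = paste0("values (", paste(signif(x, 5), collapse = ", "),
                             ") strictly decreasing"))
}

expect_strictly_increasing <- function(x) {
  expect_true(all(diff(x) > 0),
              label = paste0("values (", paste(signif(x, 5), collapse = ", "),
                             ") strictly increasing"))
}
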