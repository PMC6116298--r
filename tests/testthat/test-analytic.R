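# Frozen scalar reference values, computed by hand from the default
# parameters before the solvers were written:
#   q        = (1 - 0.1) * 1e10 * 2.4e7            = 2.16e17 W/m3
#   rise(a)  = q a^2 ln(100) / (2 * 0.567)         = 21.92933 K
#   T(a)     = 37 + 21.92933                       = 58.92933 C
#   T(0)-T(a)= q a^2 / (4 * 3000)                  = 4.5e-4 K
#   q(0)/q   = exp(-2.4e7 * 5e-9)                  = exp(-0.12)
REF_Q <- 2.16e17
REF_RISE <- 2.16e17 * (5e-9)^2 * log(100) / (2 * 0.567)
REF_EXCESS <- 4.5e-4

test_that("heating function matches the Beer-Lambert form at the surface and axis", {
  spec <- default_model_spec()
  a <- spec$geometry$cnt_radius
  expect_equal(constant_heating(spec$laser), REF_Q)
  expect_equal(heating_function(a, spec$laser, spec$geometry), REF_Q)
  expect_equal(heating_function(0, spec$laser, spec$geometry),
               REF_Q * exp(-0.12))
  # fully reflective or dark absorber deposits nothing
  expect_equal(constant_heating(laser_source(1e10, 2.4e7, 1)), 0)
  expect_equal(constant_heating(laser_source(0, 2.4e7, 0.1)), 0)
  expect_error(heating_function(2 * a, spec$laser, spec$geometry), "domain")
})

test_that("steady closed form reproduces the hand-computed reference state", {
  spec <- default_model_spec()
  a <- spec$geometry$cnt_radius; b <- spec$geometry$far_radius
  expect_equal(K_to_C(interface_temperature(spec)), 37 + REF_RISE,
               tolerance = 1e-12)
  expect_equal(interface_temperature(spec), steady_temperature(a, spec))
  expect_equal(center_excess(spec), REF_EXCESS, tolerance = 1e-12)
  expect_equal(steady_temperature(b, spec), spec$geometry$far_temperature)
  # no source -> uniform body temperature
  expect_equal(steady_temperature(c(0, a, b / 2, b), spec, q = 0),
               rep(spec$geometry$far_temperature, 4))
  expect_error(steady_temperature(2 * b, spec), "domain")
  expect_error(steady_temperature(-1e-9, spec), "domain")
})

test_that("profile is monotone, pinned at Tb, and samples 0, a, b exactly", {
  spec <- default_model_spec()
  a <- spec$geometry$cnt_radius; b <- spec$geometry$far_radius
  p <- steady_profile(spec, n_points = 101L)
  expect_true(all(diff(p$T_K) <= 0))
  expect_equal(p$T_C[nrow(p)], 37)
  expect_true(all(c(0, a, b) %in% p$r_m))
  expect_identical(p$region[p$r_m == a], "interface")
  p3 <- steady_profile(spec, n_points = 3L)
  expect_equal(p3$r_m, c(0, a, b))
  plog <- steady_profile(spec, n_points = 51L, spacing = "log-outside")
  expect_true(all(c(0, a, b) %in% plog$r_m))
  expect_error(steady_profile(spec, n_points = 2L), "n_points")
})

test_that("doubling the radius at fixed b/a quadruples the rise and kt scales inversely", {
  spec <- default_model_spec()
  Tb <- spec$geometry$far_temperature
  rise <- function(s) interface_temperature(s) - Tb
  double_a <- model_spec(spec$cnt, spec$tissue, spec$laser,
                         geometry(1e-8, far_temperature = Tb))
  expect_equal(rise(double_a) / rise(spec), 4, tolerance = 1e-14)
  half_kt <- model_spec(spec$cnt, material(0.567 / 2), spec$laser,
                        spec$geometry)
  expect_equal(rise(half_kt) / rise(spec), 2, tolerance = 1e-14)
})

test_that("closed form satisfies axis, interface and far-field conditions for random parameters", {
  set.seed(7)
  for (i in 1:50) {
    spec <- random_spec()
    a <- spec$geometry$cnt_radius; b <- spec$geometry$far_radius
    kc <- spec$cnt$thermal_conductivity
    kt <- spec$tissue$thermal_conductivity
    expect_identical(steady_gradient(0, spec), 0)
    Tin <- steady_temperature(a, spec)
    Tout <- spec$geometry$far_temperature +
      constant_heating(spec$laser) * a^2 / (2 * kt) * log(b / a)
    expect_equal(Tin, Tout, tolerance = 1e-13)
    expect_equal(kc * steady_gradient(a, spec, side = "inside"),
                 kt * steady_gradient(a, spec, side = "outside"),
                 tolerance = 1e-13)
    expect_equal(steady_temperature(b, spec), spec$geometry$far_temperature)
  }
})

test_that("quadrature solver agrees with the closed form for a constant source", {
  spec <- default_model_spec()
  p <- general_steady_solve(source_field(spec, "constant"), spec)
  cf <- steady_temperature(p$r_m, spec)
  expect_lt(max(abs(p$T_K - cf) / abs(cf)), 1e-10)
  # zero source: flat profile at Tb
  dark <- model_spec(spec$cnt, spec$tissue, laser_source(0, 2.4e7, 0.1),
                     spec$geometry)
  pz <- general_steady_solve(source_field(dark, "constant"), dark)
  expect_equal(pz$T_K, rep(dark$geometry$far_temperature, nrow(pz)))
})

test_that("exponential source lowers the interior temperature below the constant-source bound", {
  spec <- default_model_spec()
  pe <- general_steady_solve(source_field(spec, "exponential"), spec)
  cf <- steady_temperature(pe$r_m, spec)
  expect_true(all(pe$T_K <= cf + 1e-9))
  expect_lt(pe$T_K[1L], center_temperature(spec))
})

test_that("custom source fields are validated and clipped to the absorber", {
  spec <- default_model_spec()
  a <- spec$geometry$cnt_radius
  src <- source_field(spec, "custom", fun = function(r) 1e17 * (r / a))
  expect_equal(src$fun(2 * a), 0)
  expect_equal(src$fun(a), 1e17)
  expect_error(source_field(spec, "custom", fun = function(r) r - a),
               "nonnegative")
})

test_that("profile CSV round-trips values at full precision", {
  spec <- default_model_spec()
  p <- steady_profile(spec, n_points = 21L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile(p, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("r_m", "r_over_a", "T_C", "region"))
  expect_equal(back$T_C, p$T_C, tolerance = 1e-15)
  expect_equal(back$r_m, p$r_m, tolerance = 1e-15)
})
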