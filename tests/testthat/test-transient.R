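test_that("grids conform to the interface and honour the requested spacing", {
  spec <- default_model_spec()
  a <- spec$geometry$cnt_radius; b <- spec$geometry$far_radius
  g <- build_grid(spec, n_inside = 2L, n_outside = 2L,
                  outside_spacing = "uniform")
  expect_equal(g$edges, c(0, a / 2, a, (a + b) / 2, b))
  gg <- build_grid(spec, n_inside = 20L, n_outside = 60L)
  expect_true(a %in% gg$edges)               # edge at a, bit-equal
  expect_equal(gg$edges[length(gg$edges)], b)
  w <- diff(gg$edges[gg$edges >= a])
  ratios <- w[-1L] / w[-length(w)]
  expect_equal(ratios, rep(ratios[1L], length(ratios)), tolerance = 1e-9)
  # refinement halves every width and keeps the interface edge
  gr <- refine_grid(gg)
  expect_true(a %in% gr$edges)
  expect_equal(length(gr$centers), 2L * length(gg$centers))
  expect_error(build_grid(spec, n_inside = 1L), "n_inside")
})

test_that("uniform body temperature with no source is a fixed point of the step", {
  spec <- default_model_spec()
  dark <- model_spec(spec$cnt, spec$tissue, laser_source(0, 2.4e7, 0.1),
                     spec$geometry)
  grid <- build_grid(dark, 20L, 40L)
  Tb <- dark$geometry$far_temperature
  state <- rep(Tb, length(grid$centers))
  out <- step(state, dt = 1e-6, dark, source_field(dark, "constant"), grid)
  expect_equal(out, state, tolerance = 1e-12)
  # and solve_to_steady converges immediately
  sol <- solve_to_steady(dark, grid = grid)
  expect_equal(sol$steps, 1L)
  expect_equal(sol$final_K, state)
})

test_that("the analytic steady profile is (nearly) stationary under the discrete step", {
  spec <- default_model_spec()
  grid <- build_grid(spec, 50L, 150L)
  src <- source_field(spec, "constant")
  state <- steady_temperature(grid$centers, spec)
  out <- step(state, dt = 1e-5, spec, src, grid)
  rise <- interface_temperature(spec) - spec$geometry$far_temperature
  expect_lt(max(abs(out - state)) / rise, 5e-3)
})

test_that("implicit stepping keeps temperatures at or above the Dirichlet floor", {
  spec <- default_model_spec()
  grid <- build_grid(spec, 20L, 40L)
  src <- source_field(spec, "constant")
  Tb <- spec$geometry$far_temperature
  state <- rep(Tb, length(grid$centers))
  for (dt in c(1e-9, 1e-6, 1)) {     # wildly different steps: all stable
    out <- state
    for (i in 1:5) out <- step(out, dt, spec, src, grid)
    expect_true(all(is.finite(out)))
    expect_gte(min(out), Tb - 1e-9)
  }
})

test_that("the march converges to the closed-form steady state", {
  spec <- default_model_spec()
  sol <- solve_to_steady(spec, grid = build_grid(spec, 50L, 150L),
                         store_every = 100L)
  Ti <- interface_temperature(spec)
  rise <- Ti - spec$geometry$far_temperature
  expect_true(sol$converged)
  expect_lt(abs(fv_interface_temperature(sol) - Ti) / rise, 1e-2)
  cf <- steady_temperature(sol$grid$centers, spec)
  expect_lt(max(abs(sol$final_K - cf)) / rise, 1e-2)
  # first stored profile is the uniform initial condition
  expect_equal(sol$profiles[[1L]]$T_K,
               rep(spec$geometry$far_temperature, length(sol$grid$centers)))
  # residual history decays overall (loose: endpoint vs start)
  rh <- sol$residual_history
  expect_lt(rh[length(rh)], rh[1L])
})

test_that("non-convergence inside the step budget raises a diagnostic error", {
  spec <- default_model_spec()
  expect_error(solve_to_steady(spec, grid = build_grid(spec, 20L, 40L),
                               max_steps = 3L),
               "non-convergence")
})

test_that("transient solver refuses specs without thermal mass", {
  spec <- default_model_spec()
  steady_only <- model_spec(material(3000), material(0.567), spec$laser,
                            spec$geometry)
  expect_error(solve_to_steady(steady_only), "density")
})

test_that("transient snapshots serialize as long-format CSV", {
  spec <- default_model_spec()
  sol <- solve_to_steady(spec, grid = build_grid(spec, 10L, 20L),
                         store_every = 200L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_transient(sol, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("t_s", "r_m", "T_C"))
  expect_equal(nrow(back), length(sol$times) * length(sol$grid$centers))
})
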