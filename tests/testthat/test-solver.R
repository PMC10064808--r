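test_that("constant forcing at the initial temperature stays at equilibrium", {
  fc <- build_forcing_curve(fire_forcing_params(t_max = 20, t_decay = 300))
  fld <- simulate_heat_transfer(fc, thermal_properties())
  expect_lt(max(abs(fld$temps - 20)), 1e-9)
})

test_that("half-space oracle matches its closed form and limits", {
  expect_equal(halfspace_step_oracle(0, 100, 2e-6, 20, 120), 120)
  expect_equal(halfspace_step_oracle(1, 1, 2e-6, 20, 120), 20, tolerance = 1e-12)
  expect_equal(halfspace_step_oracle(0.02, 600, 2e-6, 20, 120), 88.3,
               tolerance = 1e-3)
  expect_error(halfspace_step_oracle(0.02, 0, 2e-6, 20, 120), "t")
  expect_error(halfspace_step_oracle(-1, 10, 2e-6, 20, 120), "z")
})

test_that("solver matches the half-space erfc oracle within 2%", {
  # 30 cm column so the bottom boundary stays out of play over 600 s
  fc <- step_forcing(120, duration = 600)
  props <- thermal_properties(0.03, heat_capacity = 1.5)  # alpha = 2e-6
  grid <- simulation_grid(dz = 0.1, depth_total = 30)
  fld <- simulate_heat_transfer(fc, props, grid)
  zs <- seq(0.5, 10, by = 0.5)   # cm
  ts <- seq(60, 600, by = 60)    # s
  rel_err <- sapply(zs, function(zc) {
    sim <- field_slice(fld, zc)[match(ts, fld$times)]
    ana <- halfspace_step_oracle(zc / 100, ts, 2e-6, 20, 120)
    max(abs(sim - ana) / (120 - 20))
  })
  expect_lt(max(rel_err), 0.02)
  # spot check of the spec's worked example at 2 cm, 600 s
  sim_2cm <- field_slice(fld, 2)[fld$times == 600]
  expect_equal(sim_2cm, 88.3, tolerance = 0.02 * 100 / 88.3)
})

test_that("maximum principle holds for the default burn", {
  fld <- default_600_field()
  expect_gte(min(fld$temps), 20 - 1e-9)
  expect_lte(max(fld$temps), 600 + 1e-9)
  # surface row reproduces the forcing, first column the initial condition
  fc <- build_forcing_curve(fire_forcing_params(600))
  expect_equal(fld$temps[1, ], fc$temps, tolerance = 1e-12)
  expect_true(all(fld$temps[-1, 1] == 20))
})

test_that("peak temperature attenuates monotonically with depth", {
  fld <- default_600_field()
  peaks <- apply(fld$temps, 1, max)
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("halving dz and dt changes the 3 cm peak by under 1%", {
  fld <- default_600_field()
  peak_coarse <- max(field_slice(fld, 3))
  fc <- build_forcing_curve(fire_forcing_params(600))
  fine <- simulate_heat_transfer(fc, thermal_properties(),
                                 simulation_grid(dz = 0.05), n_substeps = 2L)
  peak_fine <- max(field_slice(fine, 3))
  expect_lt(abs(peak_fine - peak_coarse) / (peak_coarse - 20), 0.01)
})

test_that("discrete enthalpy change balances boundary heat flux", {
  fc <- build_forcing_curve(fire_forcing_params(450, t_decay = 600))
  props <- thermal_properties()
  fld <- simulate_heat_transfer(fc, props, simulation_grid())
  dz_m <- fld$dz / 100
  C_J <- props$heat_capacity * 1e6
  k_SI <- 0.03 * 100
  nz <- nrow(fld$temps)
  interior <- 2:(nz - 1)
  d_enthalpy <- C_J * dz_m * sum(fld$temps[interior, ncol(fld$temps)] - 20)
  # Crank-Nicolson-consistent fluxes: time-averaged gradients at both ends
  tbar <- (fld$temps[, -1] + fld$temps[, -ncol(fld$temps)]) / 2
  q_top <- k_SI * (tbar[1, ] - tbar[2, ]) / dz_m
  q_bot <- k_SI * (tbar[nz, ] - tbar[nz - 1, ]) / dz_m
  flux_integral <- fld$dt_out * sum(q_top + q_bot)
  expect_equal(d_enthalpy, flux_integral,
               tolerance = 0.01 * abs(flux_integral) / abs(d_enthalpy))
})

test_that("zero-flux bottom boundary retains heat relative to the sand sink", {
  fc <- build_forcing_curve(fire_forcing_params(450, t_decay = 300))
  props <- thermal_properties()
  dir_f <- simulate_heat_transfer(fc, props)
  neu_f <- simulate_heat_transfer(fc, props, bottom = "neumann")
  nd <- nrow(dir_f$temps)
  expect_gte(neu_f$temps[nd, ncol(neu_f$temps)],
             dir_f$temps[nd, ncol(dir_f$temps)])
})

test_that("latent-heat sink delays and caps heating at depth", {
  fc <- build_forcing_curve(fire_forcing_params(600, t_decay = 600))
  props <- thermal_properties()
  dry <- simulate_heat_transfer(fc, props)
  wet <- simulate_heat_transfer(fc, props, latent_heat = TRUE, theta = 0.10)
  peak_dry <- max(field_slice(dry, 5))
  peak_wet <- max(field_slice(wet, 5))
  expect_lte(peak_wet, peak_dry + 1e-9)
})

test_that("invalid grids are rejected with the offending field named", {
  expect_error(simulation_grid(dz = 0), "dz")
  expect_error(simulation_grid(depth_total = 5), "depth_total")
  expect_error(simulation_grid(dt_out = -1), "dt_out")
})

test_that("field CSV writers emit the documented schemas", {
  fc <- build_forcing_curve(fire_forcing_params(450, t_ramp = 60, t_hold = 10,
                                                t_decay = 60, dt = 10))
  fld <- simulate_heat_transfer(fc, thermal_properties(),
                                simulation_grid(dz = 1, dt_out = 10))
  long_path <- tempfile(fileext = ".csv")
  mat_path <- tempfile(fileext = ".csv")
  write_field_csv(fld, long_path)
  write_field_csv(fld, mat_path, format = "matrix")
  long_df <- readr::read_csv(long_path, show_col_types = FALSE)
  expect_named(long_df, c("time_s", "depth_cm", "temp_C"))
  expect_equal(nrow(long_df), length(fld$times) * length(fld$depths))
  mat_df <- readr::read_csv(mat_path, show_col_types = FALSE)
  expect_equal(nrow(mat_df), length(fld$times))
  unlink(c(long_path, mat_path))
})
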