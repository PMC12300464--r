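test_that("phantom generation is deterministic and respects the spec", {
  p1 <- generate_phantom(blob_spec(seed = 5))
  p2 <- generate_phantom(blob_spec(seed = 5))
  expect_identical(p1$absorptivity_map, p2$absorptivity_map)
  expect_identical(p1$truth_mask, p2$truth_mask)
  expect_error(blob_spec(radius_mm = c(0, 0)))
})

test_that("a single circular lobe covers ~ pi r^2 of surface", {
  sp <- blob_spec(seed = 2, n_lobes = 1, radius_mm = c(8, 8),
                  center_jitter_mm = 0)
  ph <- generate_phantom(sp)
  area <- sum(ph$truth_mask) * ph$res_mm^2
  # pixelation error is bounded by one cell band around the perimeter
  expect_lt(abs(area - pi * 64), 2 * pi * 8 * ph$res_mm)
})

test_that("default blobs stay inside the treatment field", {
  for (s in 1:10) {
    ph <- generate_phantom(blob_spec(seed = s))
    n <- ph$n_cells
    expect_equal(sum(ph$truth_mask[c(1, n), ]) + sum(ph$truth_mask[, c(1, n)]),
                 0)
    expect_gt(sum(ph$truth_mask), 0)
  }
})

test_that("cycle-averaged fluence conserves commanded power", {
  ph <- uniform_phantom()
  path <- plan_raster(matrix(1, 30, 30), 1)
  m <- deposit_cycle_fluence(path, laser_beam(power_fraction = 1), ph)
  expect_equal(sum(m), 2)                     # all power absorbed at a = 1
  m0 <- deposit_cycle_fluence(path, laser_beam(power_fraction = 0), ph)
  expect_equal(sum(abs(m0)), 0)

  # single dwell: normalization of the discrete Gaussian spot
  one <- matrix(0, 30, 30); one[15, 15] <- 1
  m1 <- deposit_cycle_fluence(plan_raster(one, 1),
                              laser_beam(power_fraction = 0.5), ph)
  expect_equal(sum(m1), 2 * 0.5)

  # absorptivity < 1 bounds the absorbed power below the commanded power
  ph2 <- generate_phantom(blob_spec(1))      # 0.9 / 0.1 map
  m2 <- deposit_cycle_fluence(path, laser_beam(), ph2)
  expect_lt(sum(m2), 2)
})

test_that("full-grid scan gives uniform interior exposure", {
  ph <- uniform_phantom()
  m <- deposit_cycle_fluence(plan_raster(matrix(1, 30, 30), 1),
                             laser_beam(), ph)
  interior <- m[16:45, 16:45]                # > 1 spot diameter from edges
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.05)
})

test_that("heat stepper preserves equilibrium and rejects unstable steps", {
  ph <- uniform_phantom(n_cells = 20)
  f <- ambient_field(ph)
  f2 <- step_heat(f, NULL, ph, 0.1)
  expect_equal(f2$temps, f$temps)
  expect_error(step_heat(f, NULL, ph, 1e3), "explicit bound")
})

test_that("insulated lossless diffusion conserves mean temperature", {
  ph <- uniform_phantom(n_cells = 20, h_conv = 0)
  set.seed(1)
  f <- temperature_field(matrix(runif(400, 20, 60), 20, 20))
  m0 <- mean(f$temps)
  for (i in 1:1000) f <- step_heat(f, NULL, ph, 0.2)
  expect_lt(abs(mean(f$temps) - m0), 1e-10)
})

test_that("maximum principle: source-free peak temperature never rises", {
  ph <- uniform_phantom(n_cells = 20, h_conv = 0)
  set.seed(2)
  f <- temperature_field(matrix(runif(400, 20, 60), 20, 20))
  peaks <- numeric(50)
  for (i in 1:50) { f <- step_heat(f, NULL, ph, 0.2); peaks[i] <- max(f$temps) }
  expect_true(all(diff(c(60, peaks)) <= 1e-12))
})

test_that("uniform heating follows exact energy bookkeeping", {
  ph <- uniform_phantom(n_cells = 20, h_conv = 0)
  q <- matrix(0.005, 20, 20)                  # 2 W total
  f <- ambient_field(ph)
  dt <- 0.2
  for (i in 1:100) f <- step_heat(f, q, ph, dt)
  rc_v <- ph$density * ph$heat_capacity *
    (ph$res_mm / 1000)^2 * (ph$thickness_mm / 1000)
  expect_equal(mean(f$temps) - ph$ambient_c, 0.005 * 100 * dt / rc_v)
})

test_that("enthalpy change equals absorbed energy for a nonuniform source", {
  ph <- uniform_phantom(n_cells = 30, h_conv = 0)
  path <- plan_raster({m <- matrix(0, 30, 30); m[10:20, 12:18] <- 1; m}, 1)
  q <- deposit_cycle_fluence(path, laser_beam(), ph, grid_spec())
  f <- ambient_field(ph)
  n_steps <- 200; dt <- 0.5
  for (i in seq_len(n_steps)) f <- step_heat(f, q, ph, dt)
  rc_v <- ph$density * ph$heat_capacity *
    (ph$res_mm / 1000)^2 * (ph$thickness_mm / 1000)
  enthalpy <- sum(f$temps - ph$ambient_c) * rc_v
  absorbed <- sum(q) * n_steps * dt
  expect_lt(abs(enthalpy - absorbed) / absorbed, 1e-6)
})

test_that("lumped steady state and time constant are recovered", {
  # high conductivity -> near-uniform slab, lumped model applies:
  # T_ss - T_amb = P / (h A), tau = rho c L / h
  ph <- uniform_phantom(n_cells = 12, conductivity = 50)
  q <- matrix(2 / 144, 12, 12)
  f <- ambient_field(ph)
  ts <- numeric(40); Ts <- numeric(40)
  for (i in 1:40) {
    f <- advance_heat(f, q, ph, 25)
    ts[i] <- f$time_s; Ts[i] <- mean(f$temps)
  }
  dT_pred <- 2 / (ph$h_conv * 0.05^2)
  f_ss <- f
  for (i in 1:60) f_ss <- advance_heat(f_ss, q, ph, 50)  # ~ 7 tau total
  expect_lt(abs((mean(f_ss$temps) - ph$ambient_c) - dT_pred) / dT_pred, 0.05)

  tau_true <- ph$density * ph$heat_capacity * (ph$thickness_mm / 1000) /
    ph$h_conv
  tau_fit <- -1 / coef(lm(log(1 - (Ts - ph$ambient_c) / dT_pred) ~ ts))[["ts"]]
  expect_lt(abs(tau_fit - tau_true) / tau_true, 0.02)
})

test_that("cycle-averaged deposition matches the moving spot", {
  gs <- grid_spec(10, 10, pitch_mm = 5)
  mask <- matrix(0, 10, 10); mask[4:7, 4:7] <- 1
  path <- plan_raster(mask, dt_ms = 1)
  ph <- generate_phantom(blob_spec(1), n_cells = 20)
  f0 <- ambient_field(ph)
  beam <- laser_beam()
  f_mov <- advance_heat_moving(f0, path, beam, ph, gs, n_cycles = 5)
  q <- deposit_cycle_fluence(path, beam, ph, gs)
  f_avg <- advance_heat(f0, q, ph, 5 * path$cycle_time_ms / 1000)
  rise <- max(f_mov$temps) - ph$ambient_c
  expect_lt(max(abs(f_mov$temps - f_avg$temps)) / rise, 0.02)
})
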