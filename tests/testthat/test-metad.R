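# Toy metadynamics engine: bias bookkeeping, walls, Langevin sampling,
# free-energy recovery and reweighting.

dw_params <- function() wtmetad_params(bias_factor = 10, pace = 2,
                                       initial_height = 0.25, widths = 0.2)

dw_walls <- function() list(wall_spec(1, 1.8, "upper", kappa = 100, rescale = 0.2),
                            wall_spec(1, -1.8, "lower", kappa = 100, rescale = 0.2))

test_that("bias value and force are exact", {
  st0 <- bias_state(helixcv:::empty_hills(1), dw_params())
  expect_equal(bias_value_and_force(st0, 0), list(value = 0, force = 0))

  h1 <- data.frame(time = 2, center.1 = 0.3, sigma.1 = 0.2, height = 0.25)
  st1 <- bias_state(h1, dw_params())
  at_center <- bias_value_and_force(st1, 0.3)
  expect_equal(at_center$value, 0.25)
  expect_equal(at_center$force, 0)
  off <- bias_value_and_force(st1, 0.5)   # one sigma from the center
  expect_equal(off$value, 0.25 * exp(-0.5))
  num <- (bias_value_and_force(st1, 0.5 + 1e-6)$value -
          bias_value_and_force(st1, 0.5 - 1e-6)$value) / 2e-6
  expect_equal(off$force, -num, tolerance = 1e-8)
})

test_that("well-tempered heights follow the rescaling law", {
  p <- dw_params()
  h <- data.frame(time = 2, center.1 = 0, sigma.1 = 0.2, height = 0.25)
  st <- bias_state(h, p)
  expect_equal(next_hill_height(st, 5), 0.25, tolerance = 1e-10) # V ~ 0 there
  # V = kB dT ln 2 at the center requires stacking hills; check the law
  # directly through the formula at the hill center (V = 0.25)
  expect_equal(next_hill_height(st, 0),
               0.25 * exp(-0.25 / (kB * p$delta_T)))
  # monotone decreasing in V: stack more hills at one point
  hh <- do.call(rbind, replicate(30, h, simplify = FALSE))
  hh$time <- seq(2, by = 2, length.out = 30)
  heights <- vapply(1:30, function(k)
    next_hill_height(bias_state(hh[1:k, ], p), 0), 0)
  expect_true(all(diff(heights) < 0))
})

test_that("wall energy is zero inside and polynomial outside", {
  w <- wall_spec(1, at = 1.2, side = "upper", kappa = 7, rescale = 0.1,
                 exponent = 4)
  expect_identical(wall_energy(w, 1.0), 0)            # exactly zero inside
  expect_identical(wall_energy(w, 1.2), 0)
  expect_equal(wall_energy(w, 1.3), 7)                # s0 + r -> kappa
  expect_equal(wall_energy(w, 1.4), 16 * 7)           # s0 + 2r, e = 4
  lower <- wall_spec(1, at = -1.4, side = "lower", kappa = 7, rescale = 0.1)
  expect_identical(wall_energy(lower, -1.2), 0)
  expect_equal(wall_energy(lower, -1.5), 7)
  expect_error(wall_spec(1, 0, "upper", exponent = 3), "exponent")
})

test_that("free energy recovery applies the well-tempered scale factor", {
  p <- dw_params()
  h <- data.frame(time = 2, center.1 = 0, sigma.1 = 0.2, height = 0.9)
  st <- bias_state(h, p)
  axes <- fes_grid(-1, 1, 201)
  fes <- free_energy_from_bias(st, axes)
  # single hill: an inverted, gamma/(gamma-1)-scaled Gaussian
  x <- axes[[1]]
  expected <- (10 / 9) * (0.9 - 0.9 * exp(-x^2 / (2 * 0.2^2)))
  expect_equal(fes$values, expected, tolerance = 1e-9)
  expect_equal(min(fes$values), 0)
  expect_error(free_energy_from_bias(bias_state(helixcv:::empty_hills(1), p),
                                     axes), "no hills")
})

test_that("the bias offset reduces to V for a flat bias", {
  p <- dw_params()
  # near-uniform bias over the grid: one very wide hill
  h <- data.frame(time = 2, center.1 = 0, sigma.1 = 1e4, height = 0.8)
  st <- bias_state(h, p)
  cc <- suppressWarnings(bias_offset_c_of_t(st, fes_grid(-1, 1, 101)))
  expect_equal(cc$c, 0.8, tolerance = 1e-6)
})

test_that("Langevin propagation is deterministic, stable and Boltzmann", {
  hs <- toy_system("harmonic", k = 1)
  # zero temperature, zero force: the particle stays put
  frozen <- langevin_propagate(toy_system("harmonic", k = 0), x0 = 0.7,
                               dt = 0.01, friction = 2, temperature = 1e-12,
                               n_steps = 1000, seed = 1)
  expect_equal(frozen$x1, rep(0.7, nrow(frozen)), tolerance = 1e-6)
  # bit-identical re-run under a fixed seed
  a <- langevin_propagate(hs, 0, 0.01, 2, 298, 2000, seed = 42)
  bb <- langevin_propagate(hs, 0, 0.01, 2, 298, 2000, seed = 42)
  expect_identical(a, bb)
  # equipartition: <x^2> = kB T / k within 3 percent
  tr <- langevin_propagate(hs, 0, 0.01, 2, 298, 1e6, seed = 7,
                           record_stride = 10)
  expect_equal(mean(tr$x1^2), kB * 298, tolerance = 0.03)
  expect_error(langevin_propagate(hs, 0, dt = 0.1, friction = 2,
                                  temperature = 298, n_steps = 10), "unstable")
})

test_that("a short well-tempered run deposits decaying hills and replays exactly", {
  sys <- toy_system("double_well", a = 5)
  axes <- fes_grid(-2.6, 2.6, 521)
  run <- run_well_tempered_metadynamics(sys, dw_params(), dw_walls(),
                                        x0 = -1, n_steps = 4e5, dt = 0.002,
                                        friction = 5, seed = 3, axes = axes)
  st <- run$state
  expect_equal(nrow(st$hills), 400)  # every 2 ps over 800 ps
  expect_true(all(diff(st$hills$time) > 0))
  # heights are non-increasing wherever the trajectory revisits a CV
  # point (up to the small center mismatch of "revisits" within 0.02)
  ctr <- st$hills$center.1
  for (x0 in seq(-1.4, 1.4, by = 0.4)) {
    near <- which(abs(ctr - x0) < 0.02)
    if (length(near) > 2) {
      hts <- st$hills$height[near]
      expect_true(all(diff(hts) < 0.05 * hts[-length(hts)]))
    }
  }
  # replay from the hills table is bit-identical to the in-run bias
  fes <- free_energy_from_bias(st, axes)
  expect_identical(fes$bias_grid, run$grid_values)
  # and survives the HILLS text round-trip exactly
  tmp <- tempfile(fileext = ".hills")
  write_hills(st, tmp, seed = 3)
  st2 <- read_hills(tmp, temperature = 298)
  expect_identical(free_energy_from_bias(st2, axes)$bias_grid, run$grid_values)
})

test_that("the recovered surface error shrinks with run length", {
  sys <- toy_system("double_well", a = 5)
  axes <- fes_grid(-2.6, 2.6, 261)
  x <- axes[[1]]
  Fa <- 5 * (x^2 - 1)^2
  sel <- Fa < 10 & abs(x) < 1.7
  rms_at <- function(n_steps) {
    run <- run_well_tempered_metadynamics(sys, dw_params(), dw_walls(),
                                          x0 = -1, n_steps = n_steps,
                                          dt = 0.002, friction = 5, seed = 11,
                                          axes = axes)
    fes <- free_energy_from_bias(run$state, axes)
    err <- fes$values[sel] - Fa[sel]
    sqrt(mean((err - mean(err))^2))
  }
  errs <- vapply(c(5e5, 2e6, 8e6), rms_at, 0)
  expect_lt(errs[3], errs[1])       # longer runs do better
  expect_lt(errs[3], 0.5)
})

test_that("reweighting recovers unbiased averages of a biased harmonic well", {
  hs <- toy_system("harmonic", k = 1)
  params <- wtmetad_params(bias_factor = 10, pace = 2, initial_height = 0.25,
                           widths = 0.4)
  walls <- list(wall_spec(1, 6, "upper", kappa = 50, rescale = 0.5),
                wall_spec(1, -6, "lower", kappa = 50, rescale = 0.5))
  axes <- fes_grid(-8, 8, 401)
  run <- run_well_tempered_metadynamics(hs, params, walls, x0 = 0,
                                        n_steps = 1e6, dt = 0.002,
                                        friction = 5, seed = 5, axes = axes,
                                        record_stride = 50)
  cv <- run$colvar[, c("time", "x1")]
  rw <- reweight_frames(run$state, cv, axes)
  expect_equal(mean(rw$weights), 1)
  ms <- sum(rw$weights * cv$x1^2) / sum(rw$weights)
  expect_equal(ms, kB * 298, tolerance = 0.05)
  # with no bias all weights are equal
  st0 <- bias_state(helixcv:::empty_hills(1), params)
  rw0 <- reweight_frames(st0, cv, axes)
  expect_equal(rw0$weights, rep(1, nrow(cv)))
  # misaligned times are rejected
  shifted <- cv; shifted$time <- shifted$time + 1e6
  expect_error(reweight_frames(run$state, shifted, axes), "align")
})
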