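test_that("computational-unit conversions match the defining formulas", {
  expect_equal(convert_computational_permeability(1, 0.01, 5, 0.05), 0.04)
  expect_equal(convert_computational_diffusion(1, 0.01, 5, 0.05), 1e-4)
  # halving the time step doubles the physical permeability
  expect_equal(convert_computational_permeability(1, 0.01, 5, 0.025),
               2 * convert_computational_permeability(1, 0.01, 5, 0.05))
  # round trips
  expect_equal(convert_computational_permeability(
    convert_computational_permeability(0.37, inverse = FALSE),
    inverse = TRUE), 0.37)
  expect_equal(convert_computational_diffusion(
    convert_computational_diffusion(0.21), inverse = TRUE), 0.21)
  expect_true(is.finite(convert_computational_diffusion(1, N = 2)))
  expect_error(convert_computational_diffusion(1, N = 1), "N")

  # the computational velocity relation maps onto the continuous one
  # under the conversion pair
  N <- 5; dt <- 0.05; L <- 0.01
  for (pars in list(c(0.1, 0.005, 0.5), c(0.05, 0, 1.2))) {
    pc <- pars[1]; qc <- pars[2]; Dc <- pars[3]
    v_comp <- 1 / (1 / pc + (N - 1) / (2 * Dc) * (1 + 2 * qc / pc))
    v_phys <- velocity_with_diffusion(
      convert_computational_permeability(pc, L, N, dt),
      convert_computational_permeability(qc, L, N, dt),
      L, convert_computational_diffusion(Dc, L, N, dt))
    expect_equal(convert_computational_permeability(v_comp, L, N, dt),
                 v_phys, tolerance = 1e-12)
  }
})

test_that("a closed system conserves mass and stays nonnegative", {
  model <- small_single_channel(n_cells = 50)
  set.seed(5)
  A0 <- matrix(runif(50 * model$N), ncol = 1)
  init <- concentration_field(model, A0)
  m0 <- total_mass(init)
  # uniform random mass reaches the basal cell, which is fine here
  traj <- suppressWarnings(
    simulate_pulse(model, loading_protocol("instantaneous", amount = 0),
                   t_end = 5400, record_times = 5400,
                   initial = init))                    # > 1e5 steps
  f <- traj$fields[[1]]
  expect_lt(abs(total_mass(f) - m0) / m0, 1e-9)
  expect_true(all(f$amounts >= 0))

  # two-channel model with lateral coupling conserves mass too
  model2 <- tissue_model(
    list(channel_spec(linear_flux_params(1.4e-3, 0)),
         channel_spec(linear_flux_params(0, 0))),
    couplings = list(7.1e-6), n_cells = 40)
  A0 <- matrix(runif(40 * model2$N * 2), ncol = 2)
  init2 <- concentration_field(model2, A0)
  traj2 <- suppressWarnings(
    simulate_pulse(model2, loading_protocol("instantaneous", amount = 0),
                   t_end = 600, record_times = 600, initial = init2))
  expect_lt(abs(total_mass(traj2$fields[[1]]) - total_mass(init2)) /
              total_mass(init2), 1e-11)
})

test_that("a single polar face transfers p * a * area * dt per step", {
  model <- tissue_model(list(channel_spec(linear_flux_params(2e-4, 0),
                                          D = 1e-12)),
                        n_cells = 2, N = 2)
  A0 <- matrix(0, 4, 1)
  A0[2, 1] <- 1e-6                      # basal compartment of cell 1
  state <- concentration_field(model, A0)
  nxt <- step_field(state, model)
  vol <- state$volumes[1]
  area <- model$channels[[1]]$width * model$depth
  expected <- 2e-4 * (1e-6 / vol) * area * model$delta_t
  expect_equal(nxt$amounts[3, 1], expected, tolerance = 1e-12)
  expect_equal(sum(nxt$amounts), 1e-6, tolerance = 1e-15)
})

test_that("uniform concentration is a fixed point up to polar advection", {
  # purely diffusive symmetric model: uniform state must not change
  model <- tissue_model(list(channel_spec(linear_flux_params(0, 5e-4))),
                        n_cells = 20)
  vol <- (model$cell_L / model$N) * model$channels[[1]]$width * model$depth
  A0 <- matrix(vol * 2.5, 20 * model$N, 1)      # uniform concentration 2.5
  state <- concentration_field(model, A0)
  nxt <- step_field(state, model)
  expect_equal(nxt$amounts, state$amounts, tolerance = 1e-14)
})

test_that("stability guard aborts with a diagnostic on violent time steps", {
  expect_error(
    tissue_model(list(channel_spec(linear_flux_params(0.05, 0))),
                 n_cells = 10, delta_t = 1),
    "stability guard")
  expect_error(
    tissue_model(list(channel_spec(linear_flux_params(0, 0)),
                      channel_spec(linear_flux_params(0, 0))),
                 couplings = list(0.1), n_cells = 10, delta_t = 1,
                 lateral_split = "never"),
    "lateral")
})

test_that("zero loading produces an all-zero trajectory", {
  model <- small_single_channel(n_cells = 20)
  traj <- simulate_pulse(model, loading_protocol("instantaneous",
                                                 amount = 0),
                         t_end = 60, record_times = c(30, 60))
  expect_true(all(sapply(traj$fields, function(f) all(f$amounts == 0))))
})

test_that("grid refinement leaves velocity and spreading nearly unchanged", {
  kin <- lapply(c(5, 10), function(N) {
    model <- small_single_channel(n_cells = 220, N = N)
    traj <- goldsmith_protocol(model)
    trajectory_kinetics(traj, "moments")
  })
  expect_lt(rel_err(kin[[2]]$v, kin[[1]]$v), 0.03)
  expect_lt(rel_err(kin[[2]]$rho, kin[[1]]$rho), 0.03)
})

test_that("identical coupled channels stay exactly symmetric", {
  model <- tissue_model(
    list(channel_spec(linear_flux_params(6e-4, 1e-5)),
         channel_spec(linear_flux_params(6e-4, 1e-5))),
    couplings = list(5e-6), n_cells = 150)
  traj <- goldsmith_protocol(model)
  for (f in traj$fields)
    expect_equal(f$amounts[, 1], f$amounts[, 2], tolerance = 1e-12)
})

test_that("binned profiles preserve mass and localize point masses", {
  model <- small_single_channel(n_cells = 100)
  nr <- 100 * model$N
  A0 <- matrix(0, nr, 1)
  A0[123, 1] <- 3.7
  state <- concentration_field(model, A0)
  prof <- bin_profile(state, 2)
  expect_equal(sum(prof$amount), 3.7)
  expect_equal(sum(prof$amount > 0), 1)
  # compartment 123 center at (123 - 0.5) * 0.02 mm = 2.45 mm -> bin 2
  expect_equal(which(prof$amount > 0), 2L)
  # uniform field gives equal bins (stem is an exact multiple of 2 mm)
  stateu <- concentration_field(model, matrix(1, nr, 1))
  profu <- bin_profile(stateu, 2)
  expect_equal(profu$amount, rep(100, 5 * 100 / 100))
  expect_equal(max(abs(profu$amount - profu$amount[1])), 0)
})

test_that("the classic loading protocol starts apical and is normalized", {
  model <- small_single_channel(n_cells = 150)
  traj <- goldsmith_protocol(model)
  expect_equal(traj$times, c(1800, 3600))
  for (f in traj$fields) expect_equal(total_mass(f), 1, tolerance = 1e-9)
  # zero-time pulse sits near the apical end
  expect_lt(field_moments(traj$fields[[1]])[["mean"]], 8)
})

test_that("a pulse reaching the basal boundary triggers a warning", {
  model <- small_single_channel(p = 1e-3, q = 0, D = 1e-5, n_cells = 60)
  expect_warning(
    simulate_pulse(model, loading_protocol("instantaneous", amount = 1),
                   t_end = 3600, record_times = 3600),
    "basal boundary")
})

test_that("randomized permeability and cell length barely change rho", {
  sc <- scenario_fig3_single_channel(n_cells = 200)
  rho0 <- trajectory_kinetics(run_scenario(sc), "moments")$rho
  rhos <- sapply(1:3, function(seed) {
    m <- perturb_model(sc$model, p_cv = 0.2, length_cv = 0.2, seed = seed)
    traj <- simulate_pulse(m, sc$loading, 3600, c(1800, 3600),
                           normalize = TRUE)
    trajectory_kinetics(traj, "moments")$rho
  })
  # the measured spreading rates (10-26 mm^2/hr) are an order of
  # magnitude above the single-channel rho (~1); the perturbations move
  # rho by far less than that factor and the deficit persists
  expect_true(all(abs(rhos / rho0 - 1) < 0.5))
  expect_true(all(rhos < 5))
})
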