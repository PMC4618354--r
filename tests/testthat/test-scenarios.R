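test_that("single-channel scenario shows the spreading deficit", {
  sc <- scenario_fig3_single_channel(n_cells = 250)
  expect_equal(sc$meta$qp_ratio, 0.052)
  traj <- run_scenario(sc)
  k <- trajectory_kinetics(traj, "maximal")
  v_pred <- cms_to_mmhr(velocity_with_diffusion(4e-4, 2.08e-5, 0.01, 5e-6))
  expect_lt(rel_err(k$v, v_pred), 0.03)
  expect_lt(k$rho, 5)
})

test_that("two-channel regimes: synchronized, broadened, split", {
  sync <- run_scenario(scenario_fig5_minimal(1e-3, n_cells = 250))
  v <- sapply(1:2, function(ch)
    diff(sapply(sync$fields, peak_position, channel = ch)) /
      diff(sync$times) * 3600)
  expect_lt(abs(v[1] - v[2]) / max(v), 0.05)

  split <- run_scenario(scenario_fig5_minimal(1e-7, n_cells = 250))
  vs <- sapply(1:2, function(ch)
    diff(sapply(split$fields, peak_position, channel = ch)) /
      diff(split$times) * 3600)
  expect_lt(vs[2], 0.1 * vs[1])

  mid <- run_scenario(scenario_fig5_minimal(7.1e-6, n_cells = 250))
  k <- trajectory_kinetics(mid, "moments")
  expect_gt(k$rho, 5)                      # far above the single channel
  expect_lt(k$rho, 40)
})

test_that("scaled models with matched lateral coupling give similar pulses", {
  vars <- sapply(c(2, 6, 21), function(n) {
    sc <- scenario_fig6_scaled(n, n_cells = 200)
    traj <- run_scenario(sc)
    profile_moments(bin_profile(traj$fields[[2]]))[["variance"]]
  })
  expect_lt(max(vars) / min(vars), 2)
  # analytic effective diffusion for the n = 2 and n = 21 rows
  expect_equal(signif(effective_diffusion(5e-6, 2e-3, 7.1e-6), 2), 1.4e-8)
  expect_equal(signif(effective_diffusion(5e-6, 2e-3, 1.4e-3), 2), 1.8e-6)
})

test_that("polarity-ratio models lose spreading as channels equalize", {
  sc1 <- scenario_fig7_polarity_ratio(1)
  expect_equal(sc1$model$channels[[2]]$axial$p, 0)   # reduces to minimal
  # at a common coupling in the coherent regime, the fitted spreading
  # rate decreases as the two polarities approach each other
  rhos <- sapply(c(1, 0.9, 0.8, 0.7), function(a) {
    traj <- run_scenario(scenario_fig7_polarity_ratio(a, p = 1.44e-3,
                                                      s = 1e-5,
                                                      n_cells = 250))
    trajectory_kinetics(traj, "maximal")$rho
  })
  expect_true(all(diff(rhos) < 0))
  # 0.7:0.3 with its best-achievable coupling: the pulse splits
  traj <- run_scenario(scenario_fig7_polarity_ratio(0.7, n_cells = 250))
  prof <- bin_profile(traj$fields[[2]])
  a <- prof$amount
  peaks <- which(diff(sign(diff(a))) == -2) + 1L   # interior local maxima
  peaks <- peaks[a[peaks] > 0.15 * max(a)]
  expect_gte(length(peaks), 2)
})

test_that("vacuole coupling equilibrates and broadens as expected", {
  vb <- vacuole_broadening(passive = TRUE, n_cells = 250)
  expect_gt(vb$contribution, 0)
  # the best-fit (width-rescaled) tonoplast values reproduce the
  # minimal-model broadening
  vb_best <- vacuole_broadening(passive = FALSE, n_cells = 250)
  mid <- run_scenario(scenario_fig5_minimal(7.1e-6, n_cells = 250))
  rho_min <- trajectory_kinetics(mid, "moments")$rho
  single <- tissue_model(list(channel_spec(linear_flux_params(1.4e-3, 0))),
                         n_cells = 250)
  rho_single <- trajectory_kinetics(goldsmith_protocol(single),
                                    "moments")$rho
  expect_lt(rel_err(vb_best$contribution, rho_min - rho_single), 0.10)
  # passive coupling excludes auxin from the vacuole
  expect_lt(vb$contribution, 0.7 * vb_best$contribution)

  sc <- scenario_vacuole(TRUE, n_cells = 250)
  traj <- run_scenario(sc)
  frac <- total_mass(traj$fields[[2]], channel = 2)
  # equilibrium vacuole share: (s_cyt/s_vac) * (volume ratio 9)
  r <- (1.2e-7 / 5.6e-6) * 9
  expect_equal(frac, r / (1 + r), tolerance = 0.05)

  # no entry permeability, no broadening
  m0 <- tissue_model(
    list(channel_spec(linear_flux_params(1.4e-3, 0), width = um_to_cm(1)),
         channel_spec(linear_flux_params(0, 0), width = um_to_cm(9))),
    couplings = list(asymmetric_lateral_params(0, 5.6e-6)),
    n_cells = 250)
  t0 <- goldsmith_protocol(m0, channels = 1L)
  rho0 <- trajectory_kinetics(t0, "moments")$rho
  single1 <- tissue_model(
    list(channel_spec(linear_flux_params(1.4e-3, 0), width = um_to_cm(1))),
    n_cells = 250)
  rho1 <- trajectory_kinetics(goldsmith_protocol(single1), "moments")$rho
  expect_equal(rho0, rho1, tolerance = 1e-6)
})

test_that("saturating-lateral and saturating-axial models diverge", {
  runs <- list()
  for (site in c("lateral", "axial")) {
    for (u in c(0.45, 95.9)) {
      sc <- scenario_fig10_brewer(site, u, n_cells = 300, t_end = 7200)
      traj <- run_scenario(sc)
      f <- traj$fields[[1]]
      w <- rowSums(f$amounts)
      x <- cm_to_mm(f$positions)
      runs[[paste(site, u)]] <- c(apical = sum(w[x <= 10]) / sum(w),
                                  peak = peak_position(f))
    }
  }
  lat_build <- runs[["lateral 95.9"]]["apical"] -
    runs[["lateral 0.45"]]["apical"]
  ax_build <- runs[["axial 95.9"]]["apical"] - runs[["axial 0.45"]]["apical"]
  lat_shift <- runs[["lateral 0.45"]]["peak"] - runs[["lateral 95.9"]]["peak"]
  ax_shift <- runs[["axial 0.45"]]["peak"] - runs[["axial 95.9"]]["peak"]
  expect_gt(lat_build, 0)               # apical build-up with high uptake
  expect_gt(lat_build, ax_build)        # ... specific to lateral saturation
  expect_gt(ax_shift, lat_shift)        # axial saturation displaces peaks

  # linear limit: at tiny uptake the saturating-lateral model matches a
  # fully linear twin within 5%
  sc_small <- scenario_fig10_brewer("lateral", 1e-4, n_cells = 250,
                                    t_end = 3600)
  lin_model <- tissue_model(
    c(list(channel_spec(linear_flux_params(3.2e-3, 0)),
           channel_spec(linear_flux_params(4e-4, 0))),
      replicate(4, channel_spec(linear_flux_params(0, 8e-3)),
                simplify = FALSE)),
    couplings = c(rep(list(2.4e-5), 4), list(4e-7)),
    n_cells = 250, delta_t = 0.04)
  tr_sat <- run_scenario(sc_small)
  tr_lin <- simulate_pulse(lin_model, sc_small$loading, 3600,
                           record_times = 3600)
  p_sat <- bin_profile(tr_sat$fields[[1]])
  p_lin <- bin_profile(tr_lin$fields[[1]])
  expect_lt(max(abs(p_sat$amount - p_lin$amount)) / max(p_lin$amount),
            0.05)
})

test_that("scenario configs round-trip through YAML", {
  for (sc in list(scenario_fig10_brewer("lateral", 4.9, n_cells = 50),
                  scenario_vacuole(TRUE, n_cells = 50),
                  scenario_fig5_minimal(7.1e-6, n_cells = 50))) {
    txt <- write_scenario_config(sc)
    back <- read_scenario_config(text = txt)
    expect_equal(back$model[names(back$model) != "channels"],
                 sc$model[names(sc$model) != "channels"],
                 tolerance = 1e-12)
    expect_equal(back$model$channels, sc$model$channels,
                 tolerance = 1e-12)
    expect_equal(back$loading, sc$loading)
    expect_equal(back$record_times, sc$record_times)
  }
})

test_that("scenario runs are deterministic and the registry resolves", {
  expect_true("fig3_single_channel" %in% list_scenarios())
  expect_error(get_scenario("nope"), "unknown scenario")
  sc <- get_scenario("fig5_minimal", s = 7.1e-6, n_cells = 60)
  a <- run_scenario(sc, record_times = 900)
  b <- run_scenario(sc, record_times = 900)
  expect_identical(a$fields[[1]]$amounts, b$fields[[1]]$amounts)
})

test_that("the command-line wrapper exposes analyze and fit", {
  script <- system.file("scripts", "auxinpulse.R", package = "auxinpulse")
  expect_true(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(script, "analyze", "--v", "10.7",
                            "--rho", "26.0", "--L", "0.1"),
                 stdout = TRUE, stderr = TRUE)
  qp_line <- grep("^q/p = ", out, value = TRUE)
  expect_length(qp_line, 1)
  expect_equal(as.numeric(sub("q/p = ", "", qp_line)),
               infer_qp(10.7, 26.0, 0.1), tolerance = 1e-3)
  lst <- system2(rscript, c(script, "list-scenarios"), stdout = TRUE)
  expect_true("fig3_single_channel" %in% lst)
  # fit on a written fixture reproduces the in-session fit
  fx <- goldsmith_like_fixture(seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_profiles(fx$profiles[[4]], path)
  json <- system2(rscript, c(script, "fit", "--method", "maximal", path),
                  stdout = TRUE, stderr = FALSE)
  parsed <- jsonlite::fromJSON(paste(json, collapse = ""))
  ref <- maximal_fit(fx$profiles[[4]])
  expect_equal(parsed$fits$mean, ref$mean, tolerance = 1e-8)
  expect_equal(parsed$fits$variance, ref$variance, tolerance = 1e-8)
})
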