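# Named scenario presets reproducing the model configurations of the
# single-channel, minimal two-channel, scaled multi-channel, polarity-
# ratio, vacuole and saturating-lateral computations, plus structured-
# text (YAML) config serialization.

new_scenario <- function(name, model, loading, t_end, record_times,
                         normalize = TRUE, meta = list()) {
  structure(list(name = name, model = model, loading = loading,
                 t_end = t_end, record_times = record_times,
                 normalize = normalize, meta = meta),
            class = "scenario")
}

#' Run a scenario
#'
#' @param scenario a `"scenario"` object from one of the `scenario_*()`
#'   constructors.
#' @param record_times optional override of the recording times (s).
#' @return a `pulse_trajectory` (see [simulate_pulse()]).
#' @export
run_scenario <- function(scenario, record_times = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(record_times)) record_times <- scenario$record_times
  simulate_pulse(scenario$model, scenario$loading,
                 t_end = max(record_times, scenario$t_end),
                 record_times = record_times,
                 normalize = scenario$normalize)
}

# amount of auxin that fills one computational compartment of a
# 20-micron-wide channel at unit concentration; used to express uptakes
# on the computational concentration scale used for the saturating runs
unit_compartment_amount <- function(cell_L = 0.01, N = 5,
                                    width = um_to_cm(20),
                                    depth = um_to_cm(20)) {
  (cell_L / N) * width * depth
}

#' Single-channel scenario (realistic permeabilities)
#'
#' One polar channel with `p = 4e-4` cm/s, `q = 2.08e-5` cm/s
#' (`q/p = 0.052`) and intracellular `D = 5e-6` cm^2/s, run under the
#' classic loading protocol. Demonstrates the single-channel spreading
#' deficit: the fitted spreading rate falls far below measured values.
#'
#' @param n_cells stem length in cells (default 300).
#' @return a `"scenario"`.
#' @export
scenario_fig3_single_channel <- function(n_cells = 300) {
  model <- tissue_model(
    list(channel_spec(linear_flux_params(4e-4, 2.08e-5), name = "polar")),
    n_cells = n_cells)
  new_scenario("fig3_single_channel", model,
               loading_protocol("constant_rate", 900, 1),
               t_end = 3600, record_times = c(1800, 3600),
               meta = list(qp_ratio = 2.08e-5 / 4e-4))
}

#' Minimal two-channel scenario (polar + apolar, lateral coupling s)
#'
#' Polar channel `p = 1.4e-3` cm/s, `q = 0`; apolar channel
#' `p = q = 0`; both `D = 5e-6` cm^2/s; symmetric lateral permeability
#' `s`. For large `s` the channels synchronize into one sharp pulse; for
#' small `s` the peaks separate; at intermediate `s` the pulse broadens
#' while staying roughly gaussian.
#'
#' @param s symmetric lateral permeability (cm/s); `7.1e-6` reproduces
#'   the classic-data fit.
#' @param n_cells stem length in cells (default 300).
#' @param delta_t time step (s); default adapts to the stability guard.
#' @return a `"scenario"`.
#' @export
scenario_fig5_minimal <- function(s = 7.1e-6, n_cells = 300,
                                  delta_t = 0.05) {
  model <- tissue_model(
    list(channel_spec(linear_flux_params(1.4e-3, 0), name = "polar"),
         channel_spec(linear_flux_params(0, 0), name = "apolar")),
    couplings = list(s), n_cells = n_cells, delta_t = delta_t)
  new_scenario(sprintf("fig5_minimal_s%g", s), model,
               loading_protocol("constant_rate", 900, 1),
               t_end = 3600, record_times = c(1800, 3600),
               meta = list(s = s))
}

#' Scaled multi-channel scenario (n coupled channels)
#'
#' A group of polar channels adjacent to a group of apolar channels,
#' with the lateral permeability that matches the classic data for each
#' channel count: `n = 2` (1 polar, `s = 7.1e-6`, `p = 1.4e-3`), `n = 6`
#' (2 polar, `s = 8e-5`, `p = 6e-3`), `n = 21` (7 polar, `s = 1.4e-3`,
#' `p = 6.4e-3`), `n = 30` (10 polar, `s = 1.2e-2`, `p = 8.8e-3`).
#' Polar channels have `q = 0`; apolar channels have `p = 0`,
#' `q = s` (uniform permeability on all faces).
#'
#' @param n channel count: one of 2, 6, 21, 30.
#' @param n_cells stem length in cells (default 300).
#' @return a `"scenario"`.
#' @export
scenario_fig6_scaled <- function(n = c(2, 6, 21, 30), n_cells = 300) {
  n <- match.arg(as.character(n[1]), c("2", "6", "21", "30"))
  cfg <- switch(n,
    "2" = list(n = 2L, polar = 1L, p = 1.4e-3, s = 7.1e-6, dt = 0.05),
    "6" = list(n = 6L, polar = 2L, p = 6e-3, s = 8e-5, dt = 0.05),
    "21" = list(n = 21L, polar = 7L, p = 6.4e-3, s = 1.4e-3, dt = 0.04),
    "30" = list(n = 30L, polar = 10L, p = 8.8e-3, s = 1.2e-2, dt = 0.0125))
  channels <- c(
    replicate(cfg$polar,
              channel_spec(linear_flux_params(cfg$p, 0), name = "polar"),
              simplify = FALSE),
    replicate(cfg$n - cfg$polar,
              channel_spec(linear_flux_params(0, cfg$s), name = "apolar"),
              simplify = FALSE))
  model <- tissue_model(channels,
                        couplings = rep(list(cfg$s), cfg$n - 1L),
                        n_cells = n_cells, delta_t = cfg$dt)
  new_scenario(sprintf("fig6_scaled_n%s", n), model,
               loading_protocol("constant_rate", 900, 1),
               t_end = 3600, record_times = c(1800, 3600),
               meta = cfg)
}

#' Two polar channels with polarity ratio alpha : 1 - alpha
#'
#' Both channels are polar (`q = 0`) with `p_left = alpha * p` and
#' `p_right = (1 - alpha) * p`, coupled by symmetric `s`. The maximal
#' achievable spreading rate decreases as the polarities become more
#' similar; at `alpha = 1` this reduces to the minimal model.
#'
#' @param alpha polarity fraction of the stronger channel, in (0.5, 1].
#' @param p total polar permeability (cm/s); default from the best-fit
#'   values for `alpha` in `{1, 0.8, 0.7}`, else `1.44e-3`.
#' @param s lateral permeability (cm/s); defaults as for `p`.
#' @param n_cells stem length in cells (default 300).
#' @return a `"scenario"`.
#' @export
scenario_fig7_polarity_ratio <- function(alpha, p = NULL, s = NULL,
                                         n_cells = 300) {
  stopifnot(alpha > 0.5, alpha <= 1)
  defaults <- list("1" = c(p = 1.44e-3, s = 1.4e-5),
                   "0.8" = c(p = 9.6e-4, s = 9.6e-6),
                   "0.7" = c(p = 8.8e-4, s = 4.0e-7))
  key <- as.character(alpha)
  if (is.null(p)) p <- if (key %in% names(defaults))
    defaults[[key]][["p"]] else 1.44e-3
  if (is.null(s)) s <- if (key %in% names(defaults))
    defaults[[key]][["s"]] else 1e-5
  model <- tissue_model(
    list(channel_spec(linear_flux_params(alpha * p, 0), name = "strong"),
         channel_spec(linear_flux_params((1 - alpha) * p, 0),
                      name = "weak")),
    couplings = list(s), n_cells = n_cells)
  new_scenario(sprintf("fig7_alpha%g", alpha), model,
               loading_protocol("constant_rate", 900, 1),
               t_end = 3600, record_times = c(1800, 3600),
               meta = list(alpha = alpha, p = p, s = s))
}

#' Cytosol/vacuole two-compartment scenario
#'
#' The cytosol (width 1 micron, polar channel of the minimal model) is
#' coupled through the tonoplast to the vacuole half-width channel
#' (9 micron, no axial permeability) by the asymmetric lateral flux
#' `s_cyt * a_cyt - s_vac * a_vac`. With `passive = TRUE` the tonoplast
#' permeabilities are the passive chemiosmotic values
#' (`s_cyt = 1.2e-7`, `s_vac = 5.6e-6` cm/s); otherwise the
#' width-rescaled best-fit values (`3.6e-7`, `3.2e-6` cm/s).
#'
#' @param passive use passive-diffusion tonoplast permeabilities.
#' @param p polar permeability of the cytosol channel (cm/s).
#' @param n_cells stem length in cells (default 300).
#' @return a `"scenario"`.
#' @export
scenario_vacuole <- function(passive = TRUE, p = 1.4e-3, n_cells = 300) {
  s <- if (passive) c(cyt = 1.2e-7, vac = 5.6e-6)
       else c(cyt = 3.6e-7, vac = 3.2e-6)
  model <- tissue_model(
    list(channel_spec(linear_flux_params(p, 0), width = um_to_cm(1),
                      name = "cytosol"),
         channel_spec(linear_flux_params(0, 0), width = um_to_cm(9),
                      name = "vacuole")),
    couplings = list(asymmetric_lateral_params(s[["cyt"]], s[["vac"]])),
    n_cells = n_cells)
  new_scenario(if (passive) "vacuole_passive" else "vacuole_bestfit",
               model,
               loading_protocol("constant_rate", 900, 1, channels = 1L),
               t_end = 3600, record_times = c(1800, 3600),
               meta = list(passive = passive, s_cyt = s[["cyt"]],
                           s_vac = s[["vac"]], p = p))
}

#' Spreading-rate contribution of vacuole coupling
#'
#' Runs the cytosol/vacuole scenario and the corresponding uncoupled
#' single cytosol channel, estimates each spreading rate from the exact
#' field variances at 30 and 60 minutes, and returns the difference:
#' the broadening contributed by exchange with the vacuole.
#'
#' @inheritParams scenario_vacuole
#' @return a list with `rho_coupled`, `rho_uncoupled` and `contribution`
#'   (all mm^2/hr).
#' @export
vacuole_broadening <- function(passive = TRUE, p = 1.4e-3, n_cells = 300) {
  sc <- scenario_vacuole(passive = passive, p = p, n_cells = n_cells)
  traj <- run_scenario(sc)
  rho_c <- (field_moments(traj$fields[[2]])[["variance"]] -
              field_moments(traj$fields[[1]])[["variance"]]) /
    diff(traj$times) * 3600
  single <- tissue_model(
    list(channel_spec(linear_flux_params(p, 0), width = um_to_cm(1),
                      name = "cytosol")),
    n_cells = n_cells)
  traj0 <- goldsmith_protocol(single)
  rho_u <- (field_moments(traj0$fields[[2]])[["variance"]] -
              field_moments(traj0$fields[[1]])[["variance"]]) /
    diff(traj0$times) * 3600
  list(rho_coupled = rho_c, rho_uncoupled = rho_u,
       contribution = rho_c - rho_u)
}

#' Single-channel scenario with saturating axial transport
#'
#' One channel whose axial flux follows Michaelis-Menten kinetics
#' (`kappa1 = 1e-6`, `kappa2 = 0`, `Km = 1e-3`, `q = 0`,
#' `D = 5e-6` cm^2/s), loaded instantaneously with a given uptake.
#' Saturation holds back the high-concentration part of the pulse while
#' the dilute front runs ahead: fronts of different uptakes align while
#' the peaks lag, producing the characteristic stretched pulse with an
#' abrupt apical edge.
#'
#' @param uptake total auxin uptake on the computational concentration
#'   scale (compartment volumes of a 20-micron channel at unit
#'   concentration); classic values 0.3, 1, 2.
#' @param n_cells stem length in cells (default 300).
#' @param t_end run time in seconds (default 90 min).
#' @return a `"scenario"`.
#' @export
scenario_fig4_saturation <- function(uptake = 1, n_cells = 300,
                                     t_end = 5400) {
  model <- tissue_model(
    list(channel_spec(saturating_flux_params(1e-6, 0, Km = 1e-3),
                      name = "saturating")),
    n_cells = n_cells)
  amt <- uptake * unit_compartment_amount(model$cell_L, model$N,
                                          model$channels[[1]]$width,
                                          model$depth)
  new_scenario(sprintf("fig4_saturation_u%g", uptake), model,
               loading_protocol("instantaneous", amount = amt),
               t_end = t_end, record_times = t_end, normalize = FALSE,
               meta = list(uptake = uptake))
}

#' Six-channel scenario with saturating lateral transport
#'
#' The six-channel model (channel 1 `p = 3.2e-3`, channel 2 `p = 4e-4`,
#' channels 3-6 `p = 0`, `q = 8e-3` cm/s; `D = 5e-6` cm^2/s) with
#' Michaelis-Menten lateral couplings `kappa1 = kappa2 = Km * s`
#' (`Km = 1e-4`; `s = 2.4e-5` cm/s between channels 1-5 and a weaker
#' `4e-7` cm/s between channels 5 and 6). Loading is instantaneous into
#' channels 2-6. With `saturation_site = "lateral"`, large uptakes
#' saturate the lateral carriers and residual auxin builds up near the
#' apical end; with `"axial"` the saturation is moved to the axial polar
#' carriers of channels 1-2 (`kappa1 = Km * p`, `kappa2 = 0`, lateral
#' couplings linear), which instead shifts the peak positions.
#'
#' @param saturation_site `"lateral"` or `"axial"`.
#' @param uptake uptake in ng (classic values 0.45, 4.9, 26.5, 95.9).
#' @param calibration model concentration units per ng (default 1e-3,
#'   chosen so the classic uptakes span the linear-to-saturated
#'   transition of `Km = 1e-4`).
#' @param n_cells stem length in cells (default 600, a 60 mm stem).
#' @param t_end run time in seconds (default 4 hr).
#' @return a `"scenario"`.
#' @export
scenario_fig10_brewer <- function(saturation_site = c("lateral", "axial"),
                                  uptake = 4.9, calibration = 1e-3,
                                  n_cells = 600, t_end = 14400) {
  saturation_site <- match.arg(saturation_site)
  Km <- 1e-4
  s_green <- 2.4e-5
  s_red <- 4e-7
  p1 <- 3.2e-3
  p2 <- 4e-4
  q_apolar <- 8e-3
  axial1 <- if (saturation_site == "axial")
    saturating_flux_params(Km * p1, 0, Km = Km) else
    linear_flux_params(p1, 0)
  axial2 <- if (saturation_site == "axial")
    saturating_flux_params(Km * p2, 0, Km = Km) else
    linear_flux_params(p2, 0)
  channels <- c(list(channel_spec(axial1, name = "ch1"),
                     channel_spec(axial2, name = "ch2")),
                replicate(4, channel_spec(linear_flux_params(0, q_apolar),
                                          name = "apolar"),
                          simplify = FALSE))
  lat <- function(s) {
    if (saturation_site == "lateral")
      saturating_flux_params(Km = Km, s = s) else s
  }
  couplings <- c(rep(list(lat(s_green)), 4), list(lat(s_red)))
  model <- tissue_model(channels, couplings, n_cells = n_cells,
                        delta_t = 0.04)
  amt <- uptake * calibration *
    unit_compartment_amount(model$cell_L, model$N,
                            um_to_cm(20), model$depth)
  new_scenario(sprintf("fig10_%s_u%g", saturation_site, uptake), model,
               loading_protocol("instantaneous", amount = amt,
                                channels = 2:6),
               t_end = t_end, record_times = t_end, normalize = FALSE,
               meta = list(saturation_site = saturation_site,
                           uptake_ng = uptake, Km = Km,
                           calibration = calibration))
}

#' Four-channel saturating-lateral variant
#'
#' An alternative model for the apical build-up: channel 1 `p = 8e-4`,
#' channel 2 `p = 1e-4`, channels 3-4 `p = 0`, `q = 2e-3` cm/s;
#' `D = 3e-6` cm^2/s; saturating lateral couplings with `Km = 1e-4` and
#' `s = 2e-6` cm/s except a weak `5e-7` cm/s between channels 2 and 3.
#'
#' @inheritParams scenario_fig10_brewer
#' @return a `"scenario"`.
#' @export
scenario_s6_four_channel <- function(uptake = 4.9, calibration = 1e-3,
                                     n_cells = 600, t_end = 14400) {
  Km <- 1e-4
  D <- 3e-6
  channels <- list(
    channel_spec(linear_flux_params(8e-4, 0), D = D, name = "ch1"),
    channel_spec(linear_flux_params(1e-4, 0), D = D, name = "ch2"),
    channel_spec(linear_flux_params(0, 2e-3), D = D, name = "apolar"),
    channel_spec(linear_flux_params(0, 2e-3), D = D, name = "apolar"))
  couplings <- list(saturating_flux_params(Km = Km, s = 2e-6),
                    saturating_flux_params(Km = Km, s = 5e-7),
                    saturating_flux_params(Km = Km, s = 2e-6))
  model <- tissue_model(channels, couplings, n_cells = n_cells)
  amt <- uptake * calibration *
    unit_compartment_amount(model$cell_L, model$N, um_to_cm(20),
                            model$depth)
  new_scenario(sprintf("s6_four_channel_u%g", uptake), model,
               loading_protocol("instantaneous", amount = amt,
                                channels = 2:4),
               t_end = t_end, record_times = t_end, normalize = FALSE,
               meta = list(uptake_ng = uptake, Km = Km,
                           calibration = calibration))
}

#' List the named scenarios
#' @return character vector of scenario constructor names.
#' @export
list_scenarios <- function() {
  c("fig3_single_channel", "fig4_saturation", "fig5_minimal",
    "fig6_scaled", "fig7_polarity_ratio", "vacuole", "fig10_brewer",
    "s6_four_channel")
}

#' Build a named scenario
#'
#' @param name one of [list_scenarios()].
#' @param ... arguments passed to the scenario constructor.
#' @return a `"scenario"`.
#' @export
get_scenario <- function(name, ...) {
  fns <- list(
    fig3_single_channel = scenario_fig3_single_channel,
    fig4_saturation = scenario_fig4_saturation,
    fig5_minimal = scenario_fig5_minimal,
    fig6_scaled = scenario_fig6_scaled,
    fig7_polarity_ratio = scenario_fig7_polarity_ratio,
    vacuole = scenario_vacuole,
    fig10_brewer = scenario_fig10_brewer,
    s6_four_channel = scenario_s6_four_channel)
  if (!name %in% names(fns))
    stop("unknown scenario: ", name, "; see list_scenarios()",
         call. = FALSE)
  fns[[name]](...)
}

## ---- config serialization ------------------------------------------------

law_to_config <- function(law) {
  if (inherits(law, "linear_flux_params"))
    return(list(type = "linear", p = law$p, q = law$q))
  if (inherits(law, "saturating_flux_params"))
    return(list(type = "saturating", kappa1 = law$kappa1,
                kappa2 = law$kappa2, Km = law$Km))
  if (inherits(law, "asymmetric_lateral_params"))
    return(list(type = "asymmetric", s_fwd = law$s_fwd, s_rev = law$s_rev))
  if (is.numeric(law) && length(law) == 1)
    return(list(type = "symmetric", s = law))
  stop("unsupported law for serialization", call. = FALSE)
}

law_from_config <- function(cfg) {
  switch(cfg$type,
    linear = linear_flux_params(cfg$p, cfg$q),
    saturating = saturating_flux_params(cfg$kappa1, cfg$kappa2,
                                        Km = cfg$Km),
    asymmetric = asymmetric_lateral_params(cfg$s_fwd, cfg$s_rev),
    symmetric = cfg$s,
    stop("unknown law type: ", cfg$type, call. = FALSE))
}

#' Serialize a tissue model to a plain-list config
#' @param model a [tissue_model()].
#' @return a nested list suitable for [yaml::as.yaml()].
#' @export
model_to_config <- function(model) {
  list(
    cell_L = model$cell_L, n_cells = model$n_cells, N = model$N,
    delta_t = model$delta_t, depth = model$depth,
    lateral_split = model$lateral_split,
    split_threshold = model$split_threshold,
    channels = lapply(model$channels, function(ch)
      list(name = ch$name, width = ch$width, D = ch$D,
           axial = law_to_config(ch$axial))),
    couplings = lapply(model$couplings, law_to_config))
}

#' Rebuild a tissue model from a config list
#' @param cfg a list as produced by [model_to_config()].
#' @return a [tissue_model()].
#' @export
model_from_config <- function(cfg) {
  channels <- lapply(cfg$channels, function(ch)
    channel_spec(law_from_config(ch$axial), width = ch$width, D = ch$D,
                 name = ch$name))
  tissue_model(channels, couplings = lapply(cfg$couplings,
                                            law_from_config),
               cell_L = cfg$cell_L, n_cells = cfg$n_cells, N = cfg$N,
               delta_t = cfg$delta_t, depth = cfg$depth,
               lateral_split = cfg$lateral_split,
               split_threshold = cfg$split_threshold)
}

#' Serialize a scenario to YAML text or file
#' @param scenario a `"scenario"`.
#' @param path optional file to write; when `NULL` the YAML text is
#'   returned.
#' @return YAML text (invisibly when written to `path`).
#' @export
write_scenario_config <- function(scenario, path = NULL) {
  cfg <- list(
    name = scenario$name,
    model = model_to_config(scenario$model),
    loading = list(mode = scenario$loading$mode,
                   duration = scenario$loading$duration,
                   amount = scenario$loading$amount,
                   channels = scenario$loading$channels,
                   extent = scenario$loading$extent),
    t_end = scenario$t_end,
    record_times = scenario$record_times,
    normalize = scenario$normalize)
  txt <- yaml::as.yaml(cfg, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a scenario back from a YAML config
#' @param path file path, or raw YAML text via `text =`.
#' @param text optional YAML text instead of a file.
#' @return a `"scenario"`.
#' @export
read_scenario_config <- function(path = NULL, text = NULL) {
  cfg <- if (!is.null(text)) yaml::yaml.load(text)
         else yaml::read_yaml(path)
  loading <- loading_protocol(cfg$loading$mode,
                              duration = cfg$loading$duration,
                              amount = cfg$loading$amount,
                              channels = cfg$loading$channels,
                              extent = cfg$loading$extent)
  new_scenario(cfg$name, model_from_config(cfg$model), loading,
               t_end = cfg$t_end, record_times = unlist(cfg$record_times),
               normalize = cfg$normalize)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d channel(s), t_end = %g s\n", x$name,
              length(x$model$channels), x$t_end))
  invisible(x)
}
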