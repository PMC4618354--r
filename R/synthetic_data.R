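# Generation of noisy segment-count pulse experiments with the
# statistical structure of classic pulse-labelling data: 2 mm segment
# bins, one profile per transport time, count-like (Poisson) noise, and
# an optional slow "trailing" component behind the main pulse.

#' Design of a synthetic pulse-labelling experiment
#'
#' The expected profile at transport time `t` is either computed from a
#' generating [tissue_model()] or taken as the parametric gaussian with
#' mean `mu0 + v t` and variance `sigma0sq + rho t` (the closed-form
#' shape of a single-channel pulse). Profiles are scaled to expected
#' counts, optionally contaminated with a trailing exponential component,
#' and noised with Poisson counting noise.
#'
#' @param v pulse velocity (mm/hr) for the parametric form.
#' @param rho spreading rate (mm^2/hr) for the parametric form.
#' @param mu0 pulse mean at time 0 (mm, default 3).
#' @param sigma0sq pulse variance at time 0 (mm^2, default 2).
#' @param model optional generating [tissue_model()]; when given, `v`,
#'   `rho`, `mu0`, `sigma0sq` are ignored and profiles come from
#'   [simulate_pulse()] under the classic loading protocol.
#' @param times transport times in hours.
#' @param segment_length segment bin length (mm, default 2).
#' @param stem_length stem length (mm, default 30).
#' @param counts_scale expected total counts per profile (default 1e4).
#' @param noise `"none"` or `"poisson"`.
#' @param contamination trailing-component mass fraction in `[0, 1)`.
#' @param decay_length trailing-component exponential decay length (mm).
#' @param replicates profiles per time point (default 1).
#' @param seed integer seed making the experiment reproducible.
#' @return an object of class `"experiment_design"`.
#' @export
experiment_design <- function(v = 10.7, rho = 26.0, mu0 = 3, sigma0sq = 2,
                              model = NULL, times = seq(0, 2, by = 0.4),
                              segment_length = 2, stem_length = 30,
                              counts_scale = 1e4,
                              noise = c("poisson", "none"),
                              contamination = 0, decay_length = 4,
                              replicates = 1, seed = 0) {
  noise <- match.arg(noise)
  stopifnot(all(times >= 0), counts_scale > 0, segment_length > 0,
            stem_length > 0, contamination >= 0, contamination < 1,
            decay_length > 0, replicates >= 1)
  structure(list(v = v, rho = rho, mu0 = mu0, sigma0sq = sigma0sq,
                 model = model, times = times,
                 segment_length = segment_length, stem_length = stem_length,
                 counts_scale = counts_scale, noise = noise,
                 contamination = contamination, decay_length = decay_length,
                 replicates = replicates, seed = seed),
            class = "experiment_design")
}

# expected (noise-free) profile at time t (hours), total mass 1
expected_profile <- function(design, t) {
  nbins <- ceiling(design$stem_length / design$segment_length)
  edges <- (0:nbins) * design$segment_length
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  mu <- design$mu0 + design$v * t
  s2 <- design$sigma0sq + design$rho * t
  mass <- diff(pnorm(edges, mean = mu, sd = sqrt(s2)))
  mass <- mass / sum(mass)
  pulse_profile(mids, mass, bin_width = design$segment_length,
                time = t * 3600)
}

#' Generate synthetic pulse profiles
#'
#' For each transport time and replicate, computes the expected profile,
#' mixes in the trailing component, scales to `counts_scale` expected
#' counts, and (for `noise = "poisson"`) draws independent Poisson counts
#' per segment. Deterministic for a given seed.
#'
#' @param design an [experiment_design()].
#' @return a list with fields `profiles` (list of [pulse_profile()]),
#'   `times` (hours, one per profile), `replicate`, and `design`.
#' @export
generate_profiles <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (!is.null(design$model)) {
    traj <- goldsmith_protocol(design$model,
                               record_times = 1800 + design$times * 3600)
    expected <- lapply(traj$fields, bin_profile,
                       bin_width = design$segment_length)
  } else {
    expected <- lapply(design$times, expected_profile, design = design)
  }
  profiles <- list()
  times <- numeric(0)
  reps <- integer(0)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(design$seed)
  for (i in seq_along(expected)) {
    base <- expected[[i]]
    if (design$contamination > 0)
      base <- add_trailing_component(base, design$contamination,
                                     design$decay_length)
    lambda <- base$amount / sum(base$amount) * design$counts_scale
    for (r in seq_len(design$replicates)) {
      amt <- if (design$noise == "poisson") rpois(length(lambda), lambda)
             else lambda
      profiles[[length(profiles) + 1L]] <-
        pulse_profile(base$position, amt,
                      bin_width = design$segment_length,
                      time = attr(base, "time"))
      times <- c(times, design$times[i])
      reps <- c(reps, r)
    }
  }
  list(profiles = profiles, times = times, replicate = reps,
       design = design)
}

#' Mix a trailing component into a profile
#'
#' Replaces a mass fraction `fraction` of the profile with an exponential
#' tail decaying away from the apical end (position 0), emulating the
#' slow-moving or immobile label that trails behind the main pulse in
#' real experiments. Total mass is preserved.
#'
#' @param profile a [pulse_profile()].
#' @param fraction trailing mass fraction in `[0, 1)`.
#' @param decay_length exponential decay length in mm.
#' @return the contaminated [pulse_profile()].
#' @export
add_trailing_component <- function(profile, fraction, decay_length = 4) {
  stopifnot(fraction >= 0, fraction < 1, decay_length > 0)
  if (fraction == 0) return(profile)
  tot <- sum(profile$amount)
  tail_shape <- exp(-profile$position / decay_length)
  tail_shape <- tail_shape / sum(tail_shape)
  out <- profile
  out$amount <- (1 - fraction) * profile$amount + fraction * tot * tail_shape
  out
}

#' A classic six-time-point pulse experiment fixture
#'
#' Parametric pulses with velocity 10.7 mm/hr and spreading rate
#' 26 mm^2/hr (the least-squares estimates for the classic coleoptile
#' data) at six times spanning 0-2 hr, 2 mm segments, 10% trailing
#' contamination and Poisson counting noise. Used as the test bed for
#' the full fit-then-regress pipeline.
#'
#' @param seed integer seed.
#' @param counts_scale expected counts per profile (default 1e4).
#' @return as [generate_profiles()].
#' @export
goldsmith_like_fixture <- function(seed = 0, counts_scale = 1e4) {
  design <- experiment_design(v = 10.7, rho = 26.0, mu0 = 3, sigma0sq = 2,
                              times = seq(0, 2, by = 0.4),
                              stem_length = 40,
                              counts_scale = counts_scale,
                              noise = "poisson", contamination = 0.1,
                              decay_length = 4, seed = seed)
  generate_profiles(design)
}
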