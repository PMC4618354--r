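# Explicit-time-step simulation of auxin concentration on a grid of axial
# compartments (within cells) across laterally coupled channels.
#
# Geometry: each channel is a file of `n_cells` cells of length `cell_L`,
# `N` axial compartments per cell, width `d` and a common depth. Strong
# lateral coupling triggers a width-wise split of each compartment into
# two sub-columns, with intracellular lateral diffusion between them.
# The forward-Euler update is implemented in C++ (`sim_core`); all
# transfers are antisymmetric, so closed-system mass is conserved to
# rounding error.

#' Convert between computational and physical permeability
#'
#' A permeability with computational value `p'` (fraction of a
#' compartment's content transferred per step) corresponds to
#' `p = p' * L / (N * delta_t)` in cm/s, where `L` is the cell length, `N`
#' the number of compartments per cell and `delta_t` the time step.
#'
#' @param x permeability to convert (computational, or cm/s when
#'   `inverse = TRUE`).
#' @param L cell length (cm, default 100 micron).
#' @param N compartments per cell (default 5).
#' @param delta_t time step (s, default 1/20).
#' @param inverse if `TRUE` convert physical -> computational.
#' @return converted permeability.
#' @export
convert_computational_permeability <- function(x, L = 0.01, N = 5,
                                               delta_t = 0.05,
                                               inverse = FALSE) {
  stopifnot(L > 0, N >= 1, delta_t > 0)
  if (inverse) x * N * delta_t / L else x * L / (N * delta_t)
}

#' Convert between computational and physical diffusion constant
#'
#' The computational diffusion parameter `D'` maps to
#' `D = D' * L^2 / (N (N-1) delta_t)` in cm^2/s. Under this pair of
#' conversions the computational velocity relation
#' `1/v' = 1/p' + (N-1)/(2 D') (1 + 2 q'/p')` coincides with the
#' continuous relation implemented in [velocity_with_diffusion()].
#'
#' @inheritParams convert_computational_permeability
#' @return converted diffusion constant.
#' @export
convert_computational_diffusion <- function(x, L = 0.01, N = 5,
                                            delta_t = 0.05,
                                            inverse = FALSE) {
  stopifnot(L > 0, delta_t > 0)
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (inverse) x * N * (N - 1) * delta_t / L^2 else x * L^2 / (N * (N - 1) * delta_t)
}

#' Specify one transport channel (cell file or subcellular compartment)
#'
#' @param axial flux law for the apical/basal cell faces: a
#'   [linear_flux_params()] or [saturating_flux_params()] object.
#' @param width channel width (cm, default 20 micron).
#' @param D intracellular diffusion constant (cm^2/s, default 5e-6).
#' @param name optional channel label.
#' @return an object of class `"channel_spec"`.
#' @export
channel_spec <- function(axial = linear_flux_params(0, 0),
                         width = um_to_cm(20), D = 5e-6, name = NULL) {
  stopifnot(width > 0, D > 0)
  if (!inherits(axial, c("linear_flux_params", "saturating_flux_params")))
    stop("axial must be linear_flux_params or saturating_flux_params",
         call. = FALSE)
  structure(list(axial = axial, width = width, D = D, name = name),
            class = "channel_spec")
}

# normalize a lateral coupling given as a number (symmetric s) or a
# params object into a uniform record used by the C++ core
lateral_record <- function(coupling) {
  if (is.numeric(coupling) && length(coupling) == 1) {
    if (!is.finite(coupling) || coupling < 0)
      stop("symmetric lateral permeability must be finite and >= 0",
           call. = FALSE)
    return(list(type = 0L, sf = coupling, sr = coupling,
                k1 = 0, k2 = 0, Km = 1, s_max = coupling))
  }
  if (inherits(coupling, "asymmetric_lateral_params"))
    return(list(type = 0L, sf = coupling$s_fwd, sr = coupling$s_rev,
                k1 = 0, k2 = 0, Km = 1,
                s_max = max(coupling$s_fwd, coupling$s_rev)))
  if (inherits(coupling, "saturating_flux_params"))
    return(list(type = 1L, sf = 0, sr = 0, k1 = coupling$kappa1,
                k2 = coupling$kappa2, Km = coupling$Km,
                s_max = max(coupling$kappa1, coupling$kappa2) / coupling$Km))
  if (inherits(coupling, "linear_flux_params"))
    return(list(type = 0L, sf = coupling$p + coupling$q, sr = coupling$q,
                k1 = 0, k2 = 0, Km = 1,
                s_max = max(coupling$p + coupling$q, coupling$q)))
  stop("unsupported lateral coupling specification", call. = FALSE)
}

axial_record <- function(law) {
  if (inherits(law, "linear_flux_params"))
    return(list(type = 0L, p = law$p, q = law$q, k1 = 0, k2 = 0, Km = 1,
                out_down = law$p + law$q, out_up = law$q))
  if (inherits(law, "saturating_flux_params"))
    return(list(type = 1L, p = 0, q = 0, k1 = law$kappa1, k2 = law$kappa2,
                Km = law$Km, out_down = law$kappa1 / law$Km,
                out_up = law$kappa2 / law$Km))
  stop("unsupported axial flux law", call. = FALSE)
}

#' Assemble a multi-channel tissue model
#'
#' Orders a set of channels side by side with lateral couplings between
#' adjacent channels and fixes the discretization (cells per channel,
#' compartments per cell, time step). Boundary conditions are no-flux at
#' both stem ends; the default stem (300 cells of 100 micron) is long
#' enough that simulated pulses do not reach the basal end.
#'
#' When a lateral coupling is strong (`width * s > split_threshold * D`
#' for an adjacent channel), each compartment of that channel is split
#' width-wise into two sub-columns coupled by intracellular lateral
#' diffusion, so that the lateral concentration gradient within cells is
#' resolved (`lateral_split = "auto"`; use `"never"`/`"always"` to
#' override).
#'
#' @param channels list of [channel_spec()] objects (at least one).
#' @param couplings list of lateral couplings between adjacent channels
#'   (length `length(channels) - 1`); each element a single number
#'   (symmetric permeability s in cm/s), an [asymmetric_lateral_params()],
#'   a [saturating_flux_params()] or a [linear_flux_params()] object.
#' @param cell_L cell length (cm, default 100 micron).
#' @param n_cells cells per channel (default 300, a 30 mm stem).
#' @param N axial compartments per cell (default 5).
#' @param delta_t time step (s, default 1/20).
#' @param depth out-of-plane cell depth (cm, default 20 micron).
#' @param lateral_split `"auto"`, `"never"` or `"always"`.
#' @param split_threshold threshold for the auto split rule (default 0.1).
#' @return an object of class `"tissue_model"`.
#' @export
tissue_model <- function(channels, couplings = list(), cell_L = 0.01,
                         n_cells = 300, N = 5, delta_t = 0.05,
                         depth = um_to_cm(20),
                         lateral_split = c("auto", "never", "always"),
                         split_threshold = 0.1) {
  lateral_split <- match.arg(lateral_split)
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  stopifnot(length(channels) >= 1, cell_L > 0, n_cells >= 1, N >= 2,
            delta_t > 0, depth > 0)
  if (!all(vapply(channels, inherits, TRUE, "channel_spec")))
    stop("channels must be channel_spec objects", call. = FALSE)
  if (length(couplings) != length(channels) - 1)
    stop("need exactly length(channels) - 1 lateral couplings", call. = FALSE)
  lat <- lapply(couplings, lateral_record)

  # decide the width-wise split per channel
  nch <- length(channels)
  split <- rep(lateral_split == "always", nch)
  if (lateral_split == "auto" && nch > 1) {
    for (i in seq_len(nch)) {
      adj <- lat[unique(pmax(1, pmin(length(lat), c(i - 1, i))))]
      smax <- max(vapply(adj, `[[`, 0, "s_max"))
      split[i] <- channels[[i]]$width * smax > split_threshold * channels[[i]]$D
    }
  }

  # build the column table
  cols <- list()
  lat_faces <- list()
  for (i in seq_len(nch)) {
    ch <- channels[[i]]
    nsub <- if (split[i]) 2L else 1L
    ax <- axial_record(ch$axial)
    for (k in seq_len(nsub)) {
      cols[[length(cols) + 1L]] <-
        list(channel = i, width = ch$width / nsub, D = ch$D, ax = ax)
    }
    if (nsub == 2L) {
      # intracellular lateral diffusion between the two sub-columns:
      # sub-column centers are width/2 apart
      s_intra <- 2 * ch$D / ch$width
      lat_faces[[length(lat_faces) + 1L]] <-
        list(type = 0L, sf = s_intra, sr = s_intra, k1 = 0, k2 = 0, Km = 1,
             s_max = s_intra)
    }
    if (i < nch) lat_faces[[length(lat_faces) + 1L]] <- lat[[i]]
  }

  m <- structure(list(
    channels = channels, couplings = couplings, split = split,
    cols = cols, lat_faces = lat_faces,
    cell_L = cell_L, n_cells = n_cells, N = N, delta_t = delta_t,
    depth = depth, stem_length = cell_L * n_cells,
    lateral_split = lateral_split, split_threshold = split_threshold
  ), class = "tissue_model")
  check_stability(m)
  m
}

# worst-case fractional outflow per compartment per step must stay < 0.5,
# otherwise the forward-Euler update can go unstable / negative
check_stability <- function(model) {
  ell <- model$cell_L / model$N
  dt <- model$delta_t
  ncol <- length(model$cols)
  for (c in seq_len(ncol)) {
    col <- model$cols[[c]]
    Pdiff <- col$D * (model$N - 1) / model$cell_L
    contrib <- c(
      axial_down = max(Pdiff, col$ax$out_down) * dt / ell,
      axial_up = max(Pdiff, col$ax$out_up) * dt / ell
    )
    if (c > 1) {
      f <- model$lat_faces[[c - 1]]
      out <- if (f$type == 0L) f$sr else f$k2 / f$Km
      contrib <- c(contrib, lateral_left = out * dt / col$width)
    }
    if (c < ncol) {
      f <- model$lat_faces[[c]]
      out <- if (f$type == 0L) f$sf else f$k1 / f$Km
      contrib <- c(contrib, lateral_right = out * dt / col$width)
    }
    if (sum(contrib) >= 0.5) {
      worst <- names(contrib)[which.max(contrib)]
      stop(sprintf(paste0(
        "stability guard: column %d (channel %d) would lose %.2f of its ",
        "content per step (worst face: %s); reduce delta_t or the ",
        "offending permeability"), c, col$channel, sum(contrib), worst),
        call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Loading protocol for a simulation
#'
#' Auxin enters the apical-most `extent` axial compartments of the target
#' channels, either at a constant rate over `duration` seconds or
#' instantaneously (deposited in the initial computational cycle). The
#' per-channel amount is spread uniformly over the loaded compartments
#' (and across sub-columns in proportion to their volume).
#'
#' @param mode `"constant_rate"` or `"instantaneous"`.
#' @param duration loading duration in seconds (constant-rate mode;
#'   default 900 s = 15 min).
#' @param amount total amount of auxin taken up (model units).
#' @param channels integer indices of target channels (`NULL` = all).
#' @param extent number of apical axial compartments loaded per column
#'   (`NULL` = one cell, i.e. `N` compartments).
#' @return an object of class `"loading_protocol"`.
#' @export
loading_protocol <- function(mode = c("constant_rate", "instantaneous"),
                             duration = 900, amount = 1, channels = NULL,
                             extent = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant_rate" && duration <= 0)
    stop("constant_rate loading requires duration > 0", call. = FALSE)
  stopifnot(amount >= 0)
  structure(list(mode = mode, duration = duration, amount = amount,
                 channels = channels, extent = extent),
            class = "loading_protocol")
}

# per-column loading amounts (total over the whole loading period)
loading_columns <- function(model, loading) {
  ncol <- length(model$cols)
  ch_of <- vapply(model$cols, `[[`, 0L, "channel")
  targets <- loading$channels
  if (is.null(targets)) targets <- seq_along(model$channels)
  if (!all(targets %in% seq_along(model$channels)))
    stop("loading targets unknown channel index", call. = FALSE)
  per_channel <- loading$amount / length(targets)
  out <- numeric(ncol)
  for (i in targets) {
    idx <- which(ch_of == i)
    w <- vapply(model$cols[idx], `[[`, 0, "width")
    out[idx] <- per_channel * w / sum(w)
  }
  out
}

#' Concentration field (simulation state)
#'
#' Amounts of auxin per (axial compartment, column). Constructed by the
#' simulator; build one directly to set up a custom initial state.
#'
#' @param model a [tissue_model()].
#' @param amounts numeric matrix `(n_cells * N) x n_columns` of amounts
#'   (model units); defaults to all zero.
#' @param time timestamp in seconds.
#' @return an object of class `"concentration_field"`.
#' @export
concentration_field <- function(model, amounts = NULL, time = 0) {
  nrow <- model$n_cells * model$N
  ncol <- length(model$cols)
  if (is.null(amounts)) amounts <- matrix(0, nrow, ncol)
  stopifnot(is.matrix(amounts), nrow(amounts) == nrow, ncol(amounts) == ncol,
            all(amounts >= 0))
  ell <- model$cell_L / model$N
  structure(list(
    amounts = amounts, time = time,
    positions = (seq_len(nrow) - 0.5) * ell,          # cm, axial centers
    volumes = vapply(model$cols, function(co) ell * co$width * model$depth, 0),
    col_channel = vapply(model$cols, `[[`, 0L, "channel"),
    cell_L = model$cell_L, N = model$N
  ), class = "concentration_field")
}

#' Total auxin mass of a field
#' @param state a [concentration_field()].
#' @param channel optional channel index to restrict to.
#' @return total amount (model units).
#' @export
total_mass <- function(state, channel = NULL) {
  A <- state$amounts
  if (!is.null(channel)) A <- A[, state$col_channel == channel, drop = FALSE]
  sum(A)
}

#' Axial mean and variance of a field
#'
#' Mass-weighted mean and variance of axial position, from the exact
#' compartment amounts (not binned profiles).
#'
#' @param state a [concentration_field()].
#' @param channel optional channel index to restrict to.
#' @return named vector `c(mean, variance)` in mm and mm^2.
#' @export
field_moments <- function(state, channel = NULL) {
  A <- state$amounts
  if (!is.null(channel)) A <- A[, state$col_channel == channel, drop = FALSE]
  w <- rowSums(A)
  tot <- sum(w)
  if (tot <= 0) stop("field has zero mass", call. = FALSE)
  x <- cm_to_mm(state$positions)
  m <- sum(w * x) / tot
  v <- sum(w * (x - m)^2) / tot
  c(mean = m, variance = v)
}

run_core <- function(model, A0, nsteps, record_steps, load_per_step,
                     load_steps, load_rows) {
  cols <- model$cols
  lat <- model$lat_faces
  getn <- function(lst, f) vapply(lst, `[[`, 0, f)
  geti <- function(lst, f) vapply(lst, `[[`, 0L, f)
  ax <- lapply(cols, `[[`, "ax")
  if (length(lat) == 0)
    lat <- list(list(type = 0L, sf = 0, sr = 0, k1 = 0, k2 = 0, Km = 1))[0]
  sim_core(A0, as.integer(nsteps), as.integer(record_steps),
           model$delta_t, as.integer(model$N), as.integer(model$n_cells),
           model$cell_L, model$depth,
           getn(cols, "width"), getn(cols, "D"),
           geti(ax, "type"), getn(ax, "p"), getn(ax, "q"),
           getn(ax, "k1"), getn(ax, "k2"), getn(ax, "Km"),
           if (length(lat)) geti(lat, "type") else integer(0),
           getn(lat, "sf"), getn(lat, "sr"),
           getn(lat, "k1"), getn(lat, "k2"), getn(lat, "Km"),
           load_per_step, as.integer(load_steps), as.integer(load_rows),
           if (is.null(model$ax_scale)) matrix(0, 0, 0) else model$ax_scale,
           if (is.null(model$diff_scale)) matrix(0, 0, 0) else
             model$diff_scale)
}

#' Randomize per-cell permeabilities and cell lengths of a model
#'
#' Attaches multiplicative perturbations to a tissue model: each
#' cell-boundary axial flux is scaled by an independent factor drawn
#' uniformly from `1 +/- p_cv` (randomized permeability), and each
#' cell's internal diffusive exchange is scaled by `1 / f` with `f`
#' drawn from `1 +/- length_cv` (a cell of length `L f` has
#' proportionally smaller compartment-to-compartment permeability, which
#' is how randomized cell length enters the dynamics; the small
#' accompanying shift of compartment positions is neglected).
#'
#' @param model a [tissue_model()].
#' @param p_cv half-width of the permeability perturbation (default 0.2).
#' @param length_cv half-width of the cell-length perturbation
#'   (default 0.2).
#' @param seed integer seed (default 0).
#' @return the perturbed model.
#' @export
perturb_model <- function(model, p_cv = 0.2, length_cv = 0.2, seed = 0) {
  stopifnot(inherits(model, "tissue_model"), p_cv >= 0, p_cv < 1,
            length_cv >= 0, length_cv < 1)
  ncol <- length(model$cols)
  ch_of <- vapply(model$cols, `[[`, 0L, "channel")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  # one draw per (cell, channel), shared by a channel's sub-columns
  nch <- length(model$channels)
  axf <- matrix(runif((model$n_cells - 1) * nch, 1 - p_cv, 1 + p_cv),
                model$n_cells - 1, nch)
  lenf <- matrix(runif(model$n_cells * nch, 1 - length_cv, 1 + length_cv),
                 model$n_cells, nch)
  model$ax_scale <- axf[, ch_of, drop = FALSE]
  model$diff_scale <- 1 / lenf[, ch_of, drop = FALSE]
  model
}

#' Advance a concentration field by one time step
#'
#' Single forward-Euler step with no loading; mainly useful for testing
#' conservation and single-flux behaviour.
#'
#' @param state a [concentration_field()].
#' @param model the [tissue_model()] the state belongs to.
#' @return the advanced [concentration_field()].
#' @export
step_field <- function(state, model) {
  res <- run_core(model, state$amounts, 1L, integer(0),
                  numeric(length(model$cols)), 0L, 1L)
  out <- state
  out$amounts <- res$final
  out$time <- state$time + model$delta_t
  out
}

#' Run a pulse-transport simulation
#'
#' Applies the loading protocol and advances the model to `t_end`,
#' recording the concentration field at the requested times. With
#' `normalize = TRUE` each recorded field is scaled to total 1 (the usual
#' convention for comparing pulse profiles).
#'
#' A warning is issued if more than 1% of the mass has reached the final
#' (basal-most) cell by the last recorded time, since the no-flux
#' boundary then distorts the pulse.
#'
#' @param model a [tissue_model()].
#' @param loading a [loading_protocol()].
#' @param t_end simulated time in seconds (`>=` loading duration).
#' @param record_times times (s) at which to record the field; defaults
#'   to `t_end`.
#' @param normalize scale each recorded field to total mass 1.
#' @param initial optional [concentration_field()] to start from.
#' @return an object of class `"pulse_trajectory"`: list with `times`
#'   (s), `fields` (list of [concentration_field()]), `model`, `loading`.
#' @export
simulate_pulse <- function(model, loading, t_end, record_times = NULL,
                           normalize = FALSE, initial = NULL) {
  stopifnot(inherits(model, "tissue_model"),
            inherits(loading, "loading_protocol"))
  if (is.null(record_times)) record_times <- t_end
  record_times <- sort(unique(record_times))
  if (max(record_times) > t_end) stop("record_times exceed t_end",
                                      call. = FALSE)
  dt <- model$delta_t
  nsteps <- as.integer(round(t_end / dt))
  record_steps <- as.integer(round(record_times / dt))

  if (loading$mode == "constant_rate") {
    if (t_end < loading$duration)
      stop("t_end is shorter than the loading duration", call. = FALSE)
    load_steps <- max(1L, as.integer(round(loading$duration / dt)))
  } else {
    load_steps <- 1L
  }
  col_amounts <- loading_columns(model, loading)
  load_per_step <- col_amounts / load_steps
  load_rows <- loading$extent
  if (is.null(load_rows)) load_rows <- model$N
  load_rows <- as.integer(load_rows)
  stopifnot(load_rows >= 1, load_rows <= model$n_cells * model$N)

  A0 <- if (is.null(initial)) NULL else initial$amounts
  if (is.null(A0)) A0 <- matrix(0, model$n_cells * model$N,
                                length(model$cols))
  res <- run_core(model, A0, nsteps, record_steps, load_per_step,
                  load_steps, load_rows)

  fields <- vector("list", length(record_steps))
  for (i in seq_along(record_steps)) {
    A <- res$recorded[[i]]
    f <- concentration_field(model, A, time = record_steps[i] * dt)
    if (normalize && sum(A) > 0) f$amounts <- f$amounts / sum(A)
    fields[[i]] <- f
  }

  last <- res$recorded[[length(res$recorded)]]
  tot <- sum(last)
  if (tot > 0) {
    basal_rows <- seq.int(model$N * (model$n_cells - 1) + 1,
                          model$N * model$n_cells)
    if (sum(last[basal_rows, ]) / tot > 0.01)
      warning("pulse reached the basal boundary (> 1% of mass in the ",
              "final cell); results near the end of the run are distorted",
              call. = FALSE)
  }

  structure(list(times = record_times, fields = fields, model = model,
                 loading = loading),
            class = "pulse_trajectory")
}

#' Bin a concentration field into a segment profile
#'
#' Sums mass over all channels (or one channel) within consecutive axial
#' bins of `bin_width` mm, emulating the experimental cutting of the stem
#' into segments for counting. Total mass is preserved exactly.
#'
#' @param state a [concentration_field()].
#' @param bin_width segment length in mm (default 2).
#' @param channel optional channel index to restrict to.
#' @return a `pulse_profile`: data frame with columns `position` (bin
#'   midpoint, mm) and `amount`, with attributes `bin_width` and `time`.
#' @export
bin_profile <- function(state, bin_width = 2, channel = NULL) {
  stopifnot(bin_width > 0)
  A <- state$amounts
  if (!is.null(channel)) A <- A[, state$col_channel == channel, drop = FALSE]
  w <- rowSums(A)
  x <- cm_to_mm(state$positions)
  stem_mm <- cm_to_mm(state$cell_L) * length(w) / state$N
  nbins <- ceiling(stem_mm / bin_width - 1e-9)
  idx <- pmin(nbins, floor(x / bin_width) + 1L)
  amount <- vapply(seq_len(nbins), function(b) sum(w[idx == b]), 0)
  pulse_profile(position = (seq_len(nbins) - 0.5) * bin_width,
                amount = amount, bin_width = bin_width, time = state$time)
}

#' Construct a pulse profile
#'
#' A binned amount-vs-position profile at one time point: the
#' experimental observable of a pulse-transport assay.
#'
#' @param position bin midpoints (mm), equally spaced.
#' @param amount nonnegative amount (or counts) per bin.
#' @param bin_width bin width in mm (inferred from `position` if omitted).
#' @param time time stamp in seconds (optional).
#' @return a data frame of class `"pulse_profile"`.
#' @export
pulse_profile <- function(position, amount, bin_width = NULL, time = NA_real_) {
  stopifnot(length(position) == length(amount), all(amount >= 0))
  if (is.null(bin_width))
    bin_width <- if (length(position) > 1) diff(position[1:2]) else 1
  structure(data.frame(position = position, amount = amount),
            bin_width = bin_width, time = time,
            class = c("pulse_profile", "data.frame"))
}

#' Position of the peak (modal compartment) of a channel
#'
#' @param state a [concentration_field()].
#' @param channel optional channel index.
#' @return peak position in mm.
#' @export
peak_position <- function(state, channel = NULL) {
  A <- state$amounts
  if (!is.null(channel)) A <- A[, state$col_channel == channel, drop = FALSE]
  w <- rowSums(A)
  cm_to_mm(state$positions[which.max(w)])
}

#' Run the classic pulse-labelling loading protocol
#'
#' 15 minutes of constant-rate uptake at the apical end of all channels,
#' a 15 minute wait (the experimental "zero time"), and recording 30
#' minutes later: fields are recorded at 30 and 60 minutes of simulated
#' time, each normalized to total 1.
#'
#' @param model a [tissue_model()].
#' @param amount total uptake (model units, default 1).
#' @param record_times recording times in seconds (default
#'   `c(1800, 3600)`).
#' @param channels channels receiving the load (`NULL` = all).
#' @return a `pulse_trajectory` (see [simulate_pulse()]).
#' @export
goldsmith_protocol <- function(model, amount = 1,
                               record_times = c(1800, 3600),
                               channels = NULL) {
  loading <- loading_protocol("constant_rate", duration = 900,
                              amount = amount, channels = channels)
  simulate_pulse(model, loading, t_end = max(record_times),
                 record_times = record_times, normalize = TRUE)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "tissue_model: %d channel(s), %d cells x %d compartments, dt = %g s\n",
    length(x$channels), x$n_cells, x$N, x$delta_t))
  for (i in seq_along(x$channels)) {
    ch <- x$channels[[i]]
    cat(sprintf("  channel %d%s: width %g um, D %g cm2/s%s\n", i,
                if (!is.null(ch$name)) paste0(" (", ch$name, ")") else "",
                ch$width * 1e4, ch$D,
                if (x$split[i]) ", split" else ""))
  }
  invisible(x)
}

#' @export
print.pulse_trajectory <- function(x, ...) {
  cat(sprintf("pulse_trajectory: %d field(s) at t = %s s\n",
              length(x$fields), paste(x$times, collapse = ", ")))
  invisible(x)
}
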