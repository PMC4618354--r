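# Pulse-shape estimation: gaussian fits, peak-region ("maximal fit")
# window selection, and regression of fitted means/variances on time to
# estimate the velocity v and spreading rate rho.

#' Amount-weighted moments of a pulse profile
#'
#' @param profile a [pulse_profile()].
#' @return named vector `c(mean, variance)` in mm and mm^2.
#' @export
profile_moments <- function(profile) {
  tot <- sum(profile$amount)
  if (tot <= 0) stop("profile has zero total amount", call. = FALSE)
  m <- sum(profile$amount * profile$position) / tot
  v <- sum(profile$amount * (profile$position - m)^2) / tot
  c(mean = m, variance = v)
}

new_gaussian_fit <- function(amplitude, mean, variance, window,
                             residual_norm, fitted) {
  structure(list(amplitude = amplitude, mean = mean, variance = variance,
                 window = window, residual_norm = residual_norm,
                 fitted = fitted),
            class = "gaussian_fit")
}

#' Least-squares gaussian fit to a pulse profile
#'
#' Minimizes the squared deviation of `A * exp(-(x - mu)^2 / (2 sigma^2))`
#' from the bin amounts over bin midpoints, using Levenberg-Marquardt
#' nonlinear least squares initialized from the profile moments. The
#' fitted standard deviation is bounded below by half the bin width.
#'
#' Least squares over the whole profile is sensitive to trailing or
#' flanking components far from the peak; see [maximal_fit()] for the
#' peak-region variant.
#'
#' @param profile a [pulse_profile()].
#' @param window optional contiguous integer range of bin indices to fit
#'   over (default: all bins).
#' @param weighted if `TRUE`, weight residuals by `1/sqrt(amount + 1)`
#'   (approximate counting-error weights); default unweighted.
#' @return an object of class `"gaussian_fit"` with fields `amplitude`,
#'   `mean` (mm), `variance` (mm^2), `window`, `residual_norm`.
#' @export
gaussian_least_squares <- function(profile, window = NULL, weighted = FALSE) {
  n <- nrow(profile)
  if (is.null(window)) window <- seq_len(n)
  window <- sort(unique(as.integer(window)))
  if (any(diff(window) != 1L) || length(window) == 0)
    stop("window must be a contiguous range of bin indices", call. = FALSE)
  if (length(window) < 4)
    stop("need at least 4 bins in the fit window", call. = FALSE)
  x <- profile$position[window]
  y <- profile$amount[window]
  if (all(y == 0)) stop("all-zero profile: nothing to fit", call. = FALSE)
  if (sum(y > 0) < 2)
    stop("degenerate profile (fewer than 2 nonzero bins): fit failure",
         call. = FALSE)
  bw <- attr(profile, "bin_width")
  if (is.null(bw)) bw <- if (n > 1) diff(profile$position[1:2]) else 1
  s2_min <- (bw / 2)^2

  mom <- profile_moments(pulse_profile(x, y, bin_width = bw))
  start <- list(A = max(y), mu = mom[["mean"]],
                s2 = max(mom[["variance"]], s2_min * 1.01))
  w <- if (weighted) 1 / sqrt(y + 1) else rep(1, length(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s2)),
                      start = start, weights = w,
                      lower = c(A = 0, mu = min(x) - 10 * bw, s2 = s2_min),
                      upper = c(A = Inf, mu = max(x) + 10 * bw, s2 = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("gaussian fit failure: ", conditionMessage(e),
                             call. = FALSE))
  cf <- coef(fit)
  yhat <- cf[["A"]] * exp(-(x - cf[["mu"]])^2 / (2 * cf[["s2"]]))
  new_gaussian_fit(amplitude = cf[["A"]], mean = cf[["mu"]],
                   variance = cf[["s2"]], window = window,
                   residual_norm = sqrt(mean((y - yhat)^2)),
                   fitted = yhat)
}

#' Maximal fit: gaussian fit over an automatically selected peak region
#'
#' Selects a contiguous window of bins around the global maximum and fits
#' a gaussian to it, so that trailing or fast-moving components flanking
#' the main peak are ignored. The algorithm starts from the 5 bins
#' centered on the global maximum and greedily extends the window one bin
#' at a time on the side that least increases the normalized RMS residual
#' of a re-fit gaussian, stopping when no extension keeps the residual
#' within `tol` of the fitted peak amplitude. Deterministic given the
#' profile; ties are broken toward the apical side.
#'
#' @param profile a [pulse_profile()] whose global maximum bin is
#'   interior (not the first or last bin).
#' @param tol residual tolerance as a fraction of the fitted amplitude
#'   (default 0.05).
#' @return a `"gaussian_fit"` (see [gaussian_least_squares()]).
#' @export
maximal_fit <- function(profile, tol = 0.05) {
  n <- nrow(profile)
  m <- which.max(profile$amount)
  if (m == 1L || m == n)
    stop("no interior maximum: profile is monotone at its peak edge",
         call. = FALSE)
  lo <- max(1L, m - 2L)
  hi <- min(n, m + 2L)
  while (hi - lo + 1L < 4L) {      # tiny profiles: grow to a fittable window
    if (lo > 1L) lo <- lo - 1L else if (hi < n) hi <- hi + 1L else break
  }
  fit <- gaussian_least_squares(profile, window = lo:hi)
  nrms <- function(f) f$residual_norm / f$amplitude
  repeat {
    cand <- list()
    if (lo > 1L)
      cand$left <- tryCatch(gaussian_least_squares(profile, (lo - 1L):hi),
                            error = function(e) NULL)
    if (hi < n)
      cand$right <- tryCatch(gaussian_least_squares(profile, lo:(hi + 1L)),
                             error = function(e) NULL)
    cand <- Filter(function(f) !is.null(f) && nrms(f) <= tol, cand)
    if (length(cand) == 0) break
    scores <- vapply(cand, nrms, 0)
    pick <- names(cand)[which.min(scores)]   # which.min ties -> first
    # order candidates apical-first so ties go toward the apical side
    if (length(cand) == 2 && scores[["left"]] <= scores[["right"]])
      pick <- "left"
    fit <- cand[[pick]]
    lo <- fit$window[1]
    hi <- fit$window[length(fit$window)]
  }
  fit
}

#' Estimate velocity and spreading rate from fits over time
#'
#' Ordinary least-squares regression of the fitted pulse means and
#' variances on time: the velocity `v` is the slope of mean vs time and
#' the spreading rate `rho` the slope of variance vs time, each with its
#' standard error.
#'
#' @param x either a list of `"gaussian_fit"` objects (or named-vector
#'   moments with elements `mean` and `variance`), or a data frame with
#'   columns `time`, `mean`, `variance`.
#' @param times times in hours (required when `x` is a list).
#' @return an object of class `"kinetics_estimate"`: fields `v`, `v_se`
#'   (mm/hr), `rho`, `rho_se` (mm^2/hr), and `series` (per-time means and
#'   variances).
#' @export
estimate_kinetics <- function(x, times = NULL) {
  if (is.data.frame(x)) {
    series <- x[, c("time", "mean", "variance")]
  } else {
    if (is.null(times) || length(times) != length(x))
      stop("times must be given, one per fit", call. = FALSE)
    series <- data.frame(
      time = times,
      mean = vapply(x, function(f) f[["mean"]], 0),
      variance = vapply(x, function(f) f[["variance"]], 0))
  }
  if (nrow(series) < 2)
    stop("need at least 2 time points to estimate kinetics", call. = FALSE)
  slope <- function(y) {
    fit <- lm(y ~ series$time)
    # summary() warns on exactly collinear input; zero residual is a
    # legitimate case here (noise-free trajectories)
    s <- suppressWarnings(summary(fit))$coefficients
    se <- if (nrow(series) > 2) s[2, 2] else 0
    if (!is.finite(se)) se <- 0
    c(est = unname(coef(fit)[2]), se = se)
  }
  vs <- slope(series$mean)
  rs <- slope(series$variance)
  structure(list(v = vs[["est"]], v_se = vs[["se"]],
                 rho = rs[["est"]], rho_se = rs[["se"]],
                 series = series),
            class = "kinetics_estimate")
}

#' Kinetics of a simulated trajectory
#'
#' Bins each recorded field of a trajectory, summarises it by the chosen
#' method (exact moments, whole-profile gaussian least squares, or
#' maximal fit) and regresses the summaries on time.
#'
#' @param trajectory a `pulse_trajectory` from [simulate_pulse()].
#' @param method `"moments"` (binned-profile moments), `"lsq"`,
#'   `"maximal"`, or `"field"` (exact unbinned field moments, free of
#'   segment-aliasing; preferred when comparing against closed forms).
#' @param bin_width segment length in mm (default 2).
#' @param channel optional channel index to restrict to.
#' @return a `"kinetics_estimate"` (see [estimate_kinetics()]).
#' @export
trajectory_kinetics <- function(trajectory,
                                method = c("moments", "lsq", "maximal",
                                           "field"),
                                bin_width = 2, channel = NULL) {
  method <- match.arg(method)
  if (method == "field") {
    summaries <- lapply(trajectory$fields, function(f)
      as.list(field_moments(f, channel = channel)))
    return(estimate_kinetics(summaries, times = trajectory$times / 3600))
  }
  profiles <- lapply(trajectory$fields, bin_profile, bin_width = bin_width,
                     channel = channel)
  summaries <- lapply(profiles, function(p) switch(method,
    moments = as.list(profile_moments(p)),
    lsq = gaussian_least_squares(p),
    maximal = maximal_fit(p)))
  estimate_kinetics(summaries, times = trajectory$times / 3600)
}

#' Spreading rate from exact field variances at two times
#'
#' Initiates a pulse in a single compartment of the first channel, runs
#' the model, and estimates the spreading rate as
#' `(Var(t1) - Var(t0)) / (t1 - t0)` from the exact (unbinned) field
#' moments.
#'
#' @param model a [tissue_model()].
#' @param t0,t1 measurement times in seconds (defaults 30 and 60 min).
#' @param start_cell cell receiving the initial pulse (default 1, the
#'   apical-most; use a mid-stem cell for drift-free purely diffusive
#'   channels so the reflecting apical boundary does not fold the pulse).
#' @return spreading rate in mm^2/hr.
#' @export
empirical_spreading_rate <- function(model, t0 = 1800, t1 = 3600,
                                     start_cell = 1L) {
  stopifnot(t1 > t0, t0 > 0, start_cell >= 1,
            start_cell <= model$n_cells)
  A0 <- matrix(0, model$n_cells * model$N, length(model$cols))
  A0[(start_cell - 1L) * model$N + 1L, 1L] <- 1
  init <- concentration_field(model, A0)
  traj <- simulate_pulse(model,
                         loading_protocol("instantaneous", amount = 0),
                         t_end = t1, record_times = c(t0, t1),
                         initial = init)
  v0 <- field_moments(traj$fields[[1]])[["variance"]]
  v1 <- field_moments(traj$fields[[2]])[["variance"]]
  (v1 - v0) / (t1 - t0) * 3600
}

#' Surrogate spreading rate for the weak-coupling regime
#'
#' When the variance of a pulse grows faster than linearly with time
#' (weak lateral coupling leaves a trailing streak), the spreading rate
#' is not properly defined; the surrogate `|Var(t) - Var(0)| / t` is
#' reported instead, with `Var(0)` the variance at the first recorded
#' time of the trajectory.
#'
#' @param trajectory a `pulse_trajectory` whose recorded times include
#'   its first time plus `t`.
#' @param t interval in seconds (default 1800).
#' @return surrogate spreading rate in mm^2/hr.
#' @export
surrogate_spreading_rate <- function(trajectory, t = 1800) {
  t0 <- trajectory$times[1]
  target <- t0 + t
  i <- which(abs(trajectory$times - target) < trajectory$model$delta_t)
  if (length(i) == 0)
    stop("trajectory has no field recorded at its first time + t",
         call. = FALSE)
  v0 <- field_moments(trajectory$fields[[1]])[["variance"]]
  v1 <- field_moments(trajectory$fields[[i[1]]])[["variance"]]
  abs(v1 - v0) / t * 3600
}

#' Read pulse profiles from delimited text
#'
#' Expects tab-separated columns `position_mm` and `amount`, plus an
#' optional `time_s` column separating multiple profiles.
#'
#' @param path file path.
#' @return a list of [pulse_profile()] objects (one per time point).
#' @export
read_profiles <- function(path) {
  d <- read.delim(path, check.names = TRUE)
  if (!all(c("position_mm", "amount") %in% names(d)))
    stop("profile file needs columns position_mm and amount", call. = FALSE)
  if (!"time_s" %in% names(d)) d$time_s <- NA_real_
  split_d <- split(d, d$time_s, drop = TRUE)
  if (length(split_d) == 0) split_d <- list(d)
  unname(lapply(split_d, function(g)
    pulse_profile(g$position_mm, g$amount, time = g$time_s[1])))
}

#' Write pulse profiles to delimited text
#'
#' @param profiles a [pulse_profile()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "pulse_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(position_mm = p$position, amount = p$amount,
               time_s = attr(p, "time"))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "gaussian fit: A = %.4g, mean = %.3f mm, variance = %.3f mm^2 (bins %d-%d)\n",
    x$amplitude, x$mean, x$variance, x$window[1], x$window[length(x$window)]))
  invisible(x)
}

#' @export
print.kinetics_estimate <- function(x, ...) {
  cat(sprintf("v   = %.3f +/- %.3f mm/hr\nrho = %.3f +/- %.3f mm^2/hr\n",
              x$v, x$v_se, x$rho, x$rho_se))
  invisible(x)
}
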