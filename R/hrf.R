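#' Canonical hemodynamic response parameters
#'
#' The canonical double-gamma BOLD impulse response: a positive gamma lobe
#' peaking near 5 s minus a later gamma undershoot at 1/6 amplitude. All
#' times in seconds.
#'
#' @param peak_delay Delay of the response peak.
#' @param undershoot_delay Delay of the undershoot.
#' @param peak_dispersion,undershoot_dispersion Dispersions (gamma scale
#'   parameters) of the two lobes.
#' @param undershoot_ratio Amplitude of the undershoot relative to the
#'   peak lobe.
#' @param kernel_length Kernel support; the response is zero beyond this.
#' @return An object of class `hemo_params`.
#' @export
hemo_params <- function(peak_delay = 6, undershoot_delay = 16,
                        peak_dispersion = 1, undershoot_dispersion = 1,
                        undershoot_ratio = 1 / 6, kernel_length = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_dispersion > 0,
            undershoot_dispersion > 0, undershoot_ratio >= 0,
            kernel_length > 0)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length),
            class = "hemo_params")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities:
#' `dgamma(t, peak_delay / peak_dispersion, scale = peak_dispersion) -
#'  undershoot_ratio * dgamma(t, undershoot_delay / undershoot_dispersion,
#'  scale = undershoot_dispersion)`, zero beyond the kernel length.
#'
#' @param t Time since impulse (seconds, non-negative).
#' @param params A [hemo_params()].
#' @return Response values, same length as `t`.
#' @export
canonical_hrf <- function(t, params = hemo_params()) {
  stopifnot(inherits(params, "hemo_params"))
  if (any(t < 0)) stop("HRF is defined for t >= 0", call. = FALSE)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    params$undershoot_ratio *
    stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
                  scale = params$undershoot_dispersion)
  h[t > params$kernel_length] <- 0
  h
}

#' Hemodynamic condition regressor for one run
#'
#' A unit-height boxcar over all blocks of the condition, convolved with
#' the canonical hemodynamic response on a fine time grid and sampled at
#' volume acquisition times `0, tr, 2 tr, ...`.
#'
#' @param timeline A [build_run_timeline()] result.
#' @param condition Condition label.
#' @param params A [hemo_params()].
#' @param tr Sampling interval (seconds); defaults to the timeline's TR.
#' @param dt Fine convolution grid step (seconds).
#' @return Numeric vector of length `timeline$n_volumes`.
#' @export
condition_regressor <- function(timeline, condition, params = hemo_params(),
                                tr = timeline$tr, dt = 0.1) {
  stopifnot(inherits(timeline, "run_timeline"))
  if (!condition %in% c(timeline$conditions, "blank")) {
    stop("condition not in timeline: ", condition, call. = FALSE)
  }
  onsets <- condition_onsets(timeline, condition)
  n_vol <- as.integer(timeline$total_duration / tr)
  n_fine <- as.integer(ceiling(timeline$total_duration / dt))
  box <- numeric(n_fine)
  durs <- timeline$blocks$duration[timeline$blocks$condition == condition]
  for (i in seq_along(onsets)) {
    i0 <- as.integer(floor(onsets[i] / dt)) + 1L
    i1 <- min(n_fine, as.integer(ceiling((onsets[i] + durs[i]) / dt)))
    box[i0:i1] <- 1
  }
  kern <- canonical_hrf(seq(0, params$kernel_length, by = dt), params) * dt
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_fine)]
  vol_idx <- pmin(n_fine, as.integer(round((0:(n_vol - 1L)) * tr / dt)) + 1L)
  conv[vol_idx]
}
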