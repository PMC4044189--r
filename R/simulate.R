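#' Noise parameters for simulated node timecourses
#'
#' Temporal noise is ARMA(1,1) (one autoregressive and one moving-average
#' coefficient, as assumed by the prewhitening analysis), added to per-run
#' cubic Legendre drift and optional coupling to six motion nuisance
#' series. Defaults give a lag-1 autocorrelation of about 0.21 with an
#' innovation standard deviation of 1% of the default 1000 a.u. baseline
#' (temporal SNR around 100, typical of high-field acquisitions), and
#' degree 1-3 drift weights drawn per run from Normal(0, 5 a.u.).
#'
#' @param ar AR(1) coefficient, in (-1, 1).
#' @param ma MA(1) coefficient, in (-1, 1).
#' @param innovation_sd Innovation standard deviation (signal units).
#' @param drift_sd Standard deviations of the per-run Legendre drift
#'   weights for degrees 0..3 (signal units). Degree 0 defaults to zero:
#'   the constant level is carried by the baseline.
#' @param motion_coupling Length-6 weights coupling the node to the motion
#'   nuisance series (zero = pure nuisance columns).
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(ar = 0.3, ma = -0.1, innovation_sd = 10,
                         drift_sd = c(0, 5, 5, 5),
                         motion_coupling = rep(0, 6)) {
  stopifnot(abs(ar) < 1, abs(ma) < 1, innovation_sd >= 0,
            length(drift_sd) == 4, all(drift_sd >= 0),
            length(motion_coupling) == 6)
  structure(list(ar = ar, ma = ma, innovation_sd = innovation_sd,
                 drift_sd = drift_sd, motion_coupling = motion_coupling),
            class = "noise_params")
}

#' Coherence response profile of a visual area
#'
#' Mean percent-signal-change amplitude for each coherence condition
#' (0%, 33%, 66%, 100%). The built-in defaults encode the qualitative
#' pattern of area responses: V1 and V2 flat across coherence, while V3,
#' hMT+, DRA and VRA rise linearly with full-versus-zero differences of
#' 0.153, 0.101, 0.185 and 0.246 psc respectively, all on a 1 psc
#' zero-coherence pedestal (every area responds to the pattern per se).
#'
#' @param area Area label; one of `"V1"`, `"V2"`, `"V3"`, `"hMT+"`,
#'   `"DRA"`, `"VRA"`, or any label if `amplitudes` is given.
#' @param amplitudes Optional explicit length-4 psc amplitudes overriding
#'   the built-in profile.
#' @param pedestal Zero-coherence response level (psc) for the built-in
#'   profiles.
#' @return An object of class `area_profile` with fields `area` and
#'   `condition_amplitudes` (named psc vector).
#' @export
area_profile <- function(area, amplitudes = NULL, pedestal = 1) {
  full_minus_zero <- c(V1 = 0, V2 = 0, V3 = 0.153, `hMT+` = 0.101,
                       DRA = 0.185, VRA = 0.246)
  if (is.null(amplitudes)) {
    if (!area %in% names(full_minus_zero)) {
      stop("no built-in profile for area ", area,
           "; supply `amplitudes`", call. = FALSE)
    }
    amplitudes <- pedestal + full_minus_zero[[area]] * c(0, 1, 2, 3) / 3
  }
  stopifnot(length(amplitudes) == 4)
  names(amplitudes) <- c("c0", "c33", "c66", "c100")
  structure(list(area = area, condition_amplitudes = amplitudes),
            class = "area_profile")
}

# ARMA(1,1) noise, independent per run
arma11_noise <- function(n, ar, ma, sd) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n + 1L, sd = sd)
  z <- innov[-1L] + ma * innov[-(n + 1L)]
  as.numeric(stats::filter(z, ar, method = "recursive"))
}

# six smooth low-frequency random walks, standardized per run
simulate_motion <- function(n_volumes) {
  m <- sapply(seq_len(6), function(i) {
    w <- cumsum(stats::rnorm(n_volumes))
    w <- stats::filter(w, rep(1 / 9, 9), sides = 2)
    w[is.na(w)] <- 0
    as.numeric(w)
  })
  scale(m)[, , drop = FALSE]
}

#' Simulate one node's BOLD timecourse for one run
#'
#' Forward model matching the GLM analysis assumptions:
#' `baseline * (1 + sum_c amplitude_c / 100 * regressor_c) + drift +
#'  motion %*% coupling + ARMA(1,1) noise`,
#' where `regressor_c` is the hemodynamic condition regressor and drift is
#' a cubic Legendre expansion over the run.
#'
#' @param timeline A [build_run_timeline()] result.
#' @param amplitudes Named length-4 psc amplitudes (condition order
#'   `c0, c33, c66, c100`).
#' @param noise A [noise_params()].
#' @param baseline Baseline signal level (arbitrary units).
#' @param motion Optional `n_volumes x 6` motion matrix (standardized); if
#'   `NULL` coupling is skipped.
#' @param hemo A [hemo_params()].
#' @param drift_weights Optional explicit length-4 Legendre weights; if
#'   `NULL`, drawn from `Normal(0, noise$drift_sd)`.
#' @return Numeric vector of length `timeline$n_volumes` with attribute
#'   `truth` (the generating amplitudes).
#' @export
simulate_node <- function(timeline, amplitudes, noise = noise_params(),
                          baseline = 1000, motion = NULL,
                          hemo = hemo_params(), drift_weights = NULL) {
  stopifnot(inherits(timeline, "run_timeline"), length(amplitudes) == 4)
  n <- timeline$n_volumes
  sig <- numeric(n)
  for (k in seq_along(timeline$conditions)) {
    sig <- sig + amplitudes[k] / 100 *
      condition_regressor(timeline, timeline$conditions[k], hemo)
  }
  if (is.null(drift_weights)) {
    drift_weights <- stats::rnorm(4, sd = noise$drift_sd)
  }
  drift <- legendre_regressors(n, 3) %*% drift_weights
  y <- baseline * (1 + sig) + as.numeric(drift) +
    arma11_noise(n, noise$ar, noise$ma, noise$innovation_sd)
  if (!is.null(motion) && any(noise$motion_coupling != 0)) {
    y <- y + as.numeric(motion %*% noise$motion_coupling)
  }
  attr(y, "truth") <- amplitudes
  y
}

#' Simulate a multi-participant BOLD cohort
#'
#' Generates node-level timecourses for each participant, run, visual area
#' and hemisphere under the block protocol, with per-participant,
#' per-condition amplitude jitter (so between-participant SEMs are
#' non-degenerate), a configurable fraction of non-responsive nodes (zero
#' stimulus amplitude, exercising the responsiveness selection), and a
#' uniformly distributed visual-field meridian distance per node (used by
#' the binned V3 analysis). Block orders are re-randomized per run under
#' the first-order counterbalancing constraint.
#'
#' @param protocol A [block_protocol()].
#' @param profiles List of [area_profile()]s, one per simulated area.
#' @param noise A [noise_params()].
#' @param n_participants Number of participants.
#' @param nodes_per_hemi Responsive nodes per area per hemisphere.
#' @param null_nodes_per_hemi Non-responsive nodes per area per hemisphere.
#' @param amp_jitter_sd SD (psc) of the per-participant, per-condition
#'   amplitude jitter.
#' @param baseline Baseline signal level (arbitrary units).
#' @param hemo A [hemo_params()].
#' @return An object of class `glass_cohort`: a list with `protocol`,
#'   `hemo`, `areas` (labels) and `participants`, where each participant
#'   holds `timelines` (per run), `motion` (per run, volumes x 6) and per
#'   area a list with `Y` (full-run-concatenated volumes x nodes matrix),
#'   `hemisphere`, `meridian_distance`, `responsive` and `truth` (nodes x
#'   4 generating amplitudes).
#' @export
simulate_cohort <- function(protocol = block_protocol(),
                            profiles = list(area_profile("V3")),
                            noise = noise_params(),
                            n_participants = 6,
                            nodes_per_hemi = 50,
                            null_nodes_per_hemi = 10,
                            amp_jitter_sd = 0.08,
                            baseline = 1000,
                            hemo = hemo_params()) {
  areas <- vapply(profiles, function(p) p$area, character(1))
  stopifnot(!anyDuplicated(areas))
  participants <- vector("list", n_participants)
  n_nodes <- 2L * (nodes_per_hemi + null_nodes_per_hemi)
  for (p in seq_len(n_participants)) {
    timelines <- lapply(seq_len(protocol$n_runs), function(r) {
      build_run_timeline(protocol, counterbalanced_orders(protocol$n_conditions))
    })
    n_vol <- timelines[[1]]$n_volumes
    motion <- lapply(seq_len(protocol$n_runs),
                     function(r) simulate_motion(n_vol))
    # precompute per-run condition regressors once per participant
    regs <- lapply(timelines, function(tl) {
      sapply(tl$conditions, function(cc) condition_regressor(tl, cc, hemo))
    })
    area_data <- vector("list", length(profiles))
    names(area_data) <- areas
    for (a in seq_along(profiles)) {
      amps <- profiles[[a]]$condition_amplitudes
      hemi <- rep(rep(c("lh", "rh"), each = nodes_per_hemi + null_nodes_per_hemi))
      responsive <- rep(rep(c(TRUE, FALSE),
                            c(nodes_per_hemi, null_nodes_per_hemi)), 2)
      meridian <- stats::runif(n_nodes, 0, 90)
      # participant-level amplitude jitter is shared across the area's nodes
      ppt_amps <- amps + stats::rnorm(4, sd = amp_jitter_sd)
      truth <- matrix(0, n_nodes, 4,
                      dimnames = list(NULL, names(amps)))
      truth[responsive, ] <- matrix(ppt_amps, sum(responsive), 4,
                                    byrow = TRUE)
      Y <- matrix(0, n_vol * protocol$n_runs, n_nodes)
      for (r in seq_len(protocol$n_runs)) {
        rows <- (r - 1L) * n_vol + seq_len(n_vol)
        P <- legendre_regressors(n_vol, 3)
        for (j in seq_len(n_nodes)) {
          sig <- as.numeric(regs[[r]] %*% (truth[j, ] / 100))
          drift <- as.numeric(P %*% stats::rnorm(4, sd = noise$drift_sd))
          y <- baseline * (1 + sig) + drift +
            arma11_noise(n_vol, noise$ar, noise$ma, noise$innovation_sd)
          if (any(noise$motion_coupling != 0)) {
            y <- y + as.numeric(motion[[r]] %*% noise$motion_coupling)
          }
          Y[rows, j] <- y
        }
      }
      area_data[[a]] <- list(Y = Y, hemisphere = hemi,
                             meridian_distance = meridian,
                             responsive = responsive, truth = truth)
    }
    participants[[p]] <- list(timelines = timelines, motion = motion,
                              areas = area_data)
  }
  structure(list(protocol = protocol, hemo = hemo, areas = areas,
                 profiles = profiles, baseline = baseline,
                 participants = participants),
            class = "glass_cohort")
}

#' @export
print.glass_cohort <- function(x, ...) {
  n_nodes <- ncol(x$participants[[1]]$areas[[1]]$Y)
  cat(sprintf(
    "Simulated BOLD cohort: %d participants x %d runs, areas: %s\n",
    length(x$participants), x$protocol$n_runs,
    paste(x$areas, collapse = ", ")))
  cat(sprintf("  %d nodes per area per participant, %d volumes per run\n",
              n_nodes, x$participants[[1]]$timelines[[1]]$n_volumes))
  invisible(x)
}

#' Simulate the behavioral fixation task for one run
#'
#' A digit is presented at fixation at 3 Hz, randomly drawn from ten
#' digits by two polarities with two designated targets, so each
#' presentation is a target with probability 1/20. The observer responds
#' `lag` seconds after a target with probability `hit_rate`; false alarms
#' arrive as a Poisson process. Target and response trains are discretized
#' into 100 ms bins, together with the condition label of the block active
#' in each bin.
#'
#' @param timeline A [build_run_timeline()] result.
#' @param lag Response latency (seconds).
#' @param hit_rate Probability of responding to a target.
#' @param false_alarm_rate Poisson rate of spurious responses (events per
#'   second).
#' @param digit_rate Digit update rate (Hz).
#' @param target_prob Probability that a presentation is a target.
#' @param bin_width Discretization bin width (seconds).
#' @return An object of class `behavior_train`: a list of equal-length
#'   binary vectors `target_bins` and `response_bins` and a character
#'   vector `condition_bins`.
#' @export
simulate_behavior_run <- function(timeline, lag = 0.5, hit_rate = 0.8,
                                  false_alarm_rate = 0.02,
                                  digit_rate = 3, target_prob = 1 / 20,
                                  bin_width = 0.1) {
  stopifnot(inherits(timeline, "run_timeline"),
            hit_rate >= 0, hit_rate <= 1, false_alarm_rate >= 0)
  dur <- timeline$total_duration
  digit_times <- seq(0, dur - 1 / digit_rate, by = 1 / digit_rate)
  is_target <- stats::runif(length(digit_times)) < target_prob
  target_times <- digit_times[is_target]
  resp_times <- target_times[stats::runif(length(target_times)) < hit_rate] + lag
  n_fa <- stats::rpois(1, false_alarm_rate * dur)
  resp_times <- sort(c(resp_times, stats::runif(n_fa, 0, dur)))
  resp_times <- resp_times[resp_times < dur]

  n_bins <- as.integer(ceiling(dur / bin_width))
  bin_t <- (seq_len(n_bins) - 1) * bin_width
  cond <- rep("blank", n_bins)
  for (i in seq_len(nrow(timeline$blocks))) {
    b <- timeline$blocks[i, ]
    cond[bin_t >= b$onset & bin_t < b$onset + b$duration] <- b$condition
  }
  structure(list(target_bins = bin_events(target_times, dur, bin_width),
                 response_bins = bin_events(resp_times, dur, bin_width),
                 condition_bins = cond),
            class = "behavior_train")
}
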