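#' Simulation configuration
#'
#' Builds the parameter set for the synthetic-recording generator. Defaults
#' emulate the experimental protocol the pipeline targets: 2.2 Hz two-photon
#' recordings of tectal neurons, a 30 min spontaneous epoch in the dark,
#' followed by 20 trials of nine 6-degree spots at positions 45--165 degrees
#' in 15-degree steps (presented within each trial in an order maximising
#' spatial separation), each spot shown for 1 s with a 20 s gap and 25 s
#' inter-trial interval.
#'
#' @param n_neurons number of neurons.
#' @param frame_rate_hz imaging frame rate (frames / second).
#' @param sa_duration_s duration of the spontaneous (dark) epoch in seconds.
#' @param n_trials number of stimulus trials.
#' @param stimulus_positions_deg within-trial ordered spot positions (degrees
#'   of visual field, 0 = body axis).
#' @param spot_on_s spot presentation duration (s).
#' @param gap_s blank gap after each spot (s).
#' @param iti_s inter-trial interval (s).
#' @param n_sa_assemblies number of spontaneous assemblies.
#' @param n_ea_ensembles number of evoked ensembles (co-tuned groups).
#' @param assembly_event_rate_hz Poisson rate of spontaneous activation events
#'   per assembly.
#' @param tuning_sd_deg width (SD) of the Gaussian tuning of evoked responses,
#'   degrees.
#' @param retinotopy_noise_deg SD of the jitter between a neuron's
#'   anterior-posterior position and its preferred angle, degrees.
#' @param ea_sa_overlap fraction in `[0, 1]` of each evoked ensemble's members
#'   shared with the corresponding spontaneous assembly.
#' @param sa_member_fraction fraction of neurons assigned to spontaneous
#'   assemblies (the rest form a free pool that evoked ensembles can draw
#'   from), default 0.5.
#' @param calcium_tau_s decay constant of the single-exponential calcium
#'   kernel (s); default is nuclear-GCaMP6s-like.
#' @param noise_sd SD of additive white noise on the dF/F traces.
#' @param trial_gain_sd SD of the multiplicative trial-to-trial gain jitter
#'   on evoked responses, default 0.1 (set 0 for fully deterministic evoked
#'   amplitudes).
#' @param evoked_gain peak dF/F amplitude of a perfectly-matched evoked
#'   response of an ensemble member.
#' @param background_gain_frac evoked gain of neurons outside every evoked
#'   ensemble, as a fraction of `evoked_gain`; ensembles are the strongly
#'   responsive co-tuned groups, the background responds weakly.
#' @param assembly_amplitude dF/F impulse amplitude of a spontaneous assembly
#'   event.
#' @param seed integer seed; all randomness derives from it.
#' @return a list of class `tecto_config`.
#' @export
simulation_config <- function(n_neurons = 120L,
                              frame_rate_hz = 2.2,
                              sa_duration_s = 1800,
                              n_trials = 20L,
                              stimulus_positions_deg = c(45, 120, 60, 135, 75, 150, 90, 165, 105),
                              spot_on_s = 1,
                              gap_s = 20,
                              iti_s = 25,
                              n_sa_assemblies = 4L,
                              n_ea_ensembles = 4L,
                              assembly_event_rate_hz = 0.02,
                              tuning_sd_deg = 20,
                              retinotopy_noise_deg = 5,
                              ea_sa_overlap = 0.5,
                              sa_member_fraction = 0.5,
                              calcium_tau_s = 1.8,
                              noise_sd = 0.05,
                              trial_gain_sd = 0.1,
                              evoked_gain = 1,
                              background_gain_frac = 0.3,
                              assembly_amplitude = 1.2,
                              seed = 1L) {
  cfg <- list(
    n_neurons = as.integer(n_neurons), frame_rate_hz = frame_rate_hz,
    sa_duration_s = sa_duration_s, n_trials = as.integer(n_trials),
    stimulus_positions_deg = stimulus_positions_deg,
    spot_on_s = spot_on_s, gap_s = gap_s, iti_s = iti_s,
    n_sa_assemblies = as.integer(n_sa_assemblies),
    n_ea_ensembles = as.integer(n_ea_ensembles),
    assembly_event_rate_hz = assembly_event_rate_hz,
    tuning_sd_deg = tuning_sd_deg,
    retinotopy_noise_deg = retinotopy_noise_deg,
    ea_sa_overlap = ea_sa_overlap,
    sa_member_fraction = sa_member_fraction,
    calcium_tau_s = calcium_tau_s, noise_sd = noise_sd,
    trial_gain_sd = trial_gain_sd,
    evoked_gain = evoked_gain, background_gain_frac = background_gain_frac,
    assembly_amplitude = assembly_amplitude,
    seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "tecto_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("frame_rate_hz", "sa_duration_s", "spot_on_s", "gap_s", "iti_s",
           "calcium_tau_s", "tuning_sd_deg")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stopf("configuration error: '%s' must be strictly positive", p)
  nonneg <- c("assembly_event_rate_hz", "retinotopy_noise_deg", "noise_sd",
              "trial_gain_sd")
  for (p in nonneg)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
      stopf("configuration error: '%s' must be non-negative", p)
  if (cfg$n_trials < 1L) stopf("configuration error: 'n_trials' must be >= 1")
  if (length(cfg$stimulus_positions_deg) < 1L)
    stopf("configuration error: at least one stimulus position is required")
  if (cfg$ea_sa_overlap < 0 || cfg$ea_sa_overlap > 1)
    stopf("configuration error: 'ea_sa_overlap' must lie in [0, 1]")
  if (cfg$sa_member_fraction <= 0 || cfg$sa_member_fraction > 1)
    stopf("configuration error: 'sa_member_fraction' must lie in (0, 1]")
  invisible(cfg)
}

#' Build the spot-presentation schedule
#'
#' Lays out every spot presentation of the evoked protocol. Within a trial,
#' consecutive onsets are `spot_on_s + gap_s` apart; trials are separated by
#' an additional `iti_s`. Onset times are relative to the start of the evoked
#' epoch; `onset_frame` is the 1-based frame index of the onset at the
#' configured frame rate.
#'
#' @param config a [simulation_config()] object.
#' @return data.frame with columns `trial`, `position_deg`, `onset_time_s`,
#'   `onset_frame`, one row per presentation (`n_trials * n_positions` rows).
#' @export
build_stimulus_schedule <- function(config) {
  validate_config(config)
  pos <- config$stimulus_positions_deg
  np <- length(pos)
  step <- config$spot_on_s + config$gap_s
  trial_len <- np * step + config$iti_s
  trial <- rep(seq_len(config$n_trials), each = np)
  within <- rep(seq_len(np) - 1L, times = config$n_trials)
  onset <- (trial - 1L) * trial_len + within * step
  data.frame(
    trial = trial,
    position_deg = rep(pos, times = config$n_trials),
    onset_time_s = onset,
    onset_frame = as.integer(round_half_up(onset * config$frame_rate_hz)) + 1L)
}

# --- membership layout -------------------------------------------------------
# A fraction of the neurons is partitioned into spontaneous assemblies; the
# rest form a free pool. Each evoked ensemble takes round(overlap * size)
# members from its paired assembly and the rest from the pool, so
# ea_sa_overlap = 1 gives identical sets and ea_sa_overlap = 0 disjoint ones
# (when the pool is large enough).
build_memberships <- function(cfg) {
  n <- cfg$n_neurons
  # with few neurons, fewer (but never zero) groups of at least 2
  n_sa <- max(1L, min(cfg$n_sa_assemblies, n %/% 2L))
  n_ea <- max(1L, min(cfg$n_ea_ensembles, n %/% 2L))
  size <- max(2L, floor(n * cfg$sa_member_fraction / n_sa))
  perm <- sample.int(n)
  sa <- vector("list", n_sa)
  k <- 0L
  for (i in seq_len(n_sa)) {
    sa[[i]] <- sort(perm[(k + 1L):(k + size)])
    k <- k + size
  }
  pool <- if (k < n) perm[(k + 1L):n] else integer(0)
  ea <- vector("list", n_ea)
  for (i in seq_len(n_ea)) {
    src <- sa[[((i - 1L) %% n_sa) + 1L]]
    n_shared <- round_half_up(cfg$ea_sa_overlap * size)
    shared <- if (n_shared > 0) src[seq_len(n_shared)] else integer(0)
    n_new <- size - n_shared
    fresh <- integer(0)
    if (n_new > 0) {
      take <- min(n_new, length(pool))
      fresh <- pool[seq_len(take)]
      pool <- pool[-seq_len(take)]
      if (take < n_new) {
        # pool exhausted; borrow from assemblies other than the paired one
        others <- setdiff(seq_len(n), c(src, shared, fresh))
        n_borrow <- min(n_new - take, length(others))
        if (n_borrow > 0)
          fresh <- c(fresh, others[sample.int(length(others), n_borrow)])
      }
    }
    ea[[i]] <- sort(c(shared, fresh))
  }
  list(sa = sa, ea = ea, pool = sort(pool))
}

# exponential calcium-kernel convolution, exact via a recursive filter
calcium_convolve <- function(impulses, tau_s, frame_rate_hz) {
  a <- exp(-1 / (tau_s * frame_rate_hz))
  t(apply(impulses, 1L, function(s) as.numeric(stats::filter(s, a, method = "recursive"))))
}

#' Generate a synthetic recording with ground truth
#'
#' Produces a dF/F trace matrix covering a spontaneous epoch followed by the
#' evoked protocol, together with neuron positions, a neuropil contour, the
#' stimulus log, and the ground truth needed for parameter-recovery tests.
#'
#' Spontaneous assemblies activate jointly at Poisson times (also during the
#' inter-stimulus parts of the evoked epoch, never inside the 5 s evoked
#' windows); evoked responses scale with a Gaussian of the distance between a
#' neuron's true preferred angle and the spot position; all impulses are
#' convolved with a single-exponential calcium kernel and white noise is
#' added. A neuron's anterior-posterior coordinate maps linearly onto its
#' preferred angle up to retinotopic jitter, and the whole geometry is
#' rotated/translated so the anterior-posterior axis is not axis-aligned.
#'
#' @param config a [simulation_config()] object.
#' @return list of class `tecto_dataset` with elements `traces` (neurons x
#'   frames dF/F), `positions` (data.frame `neuron_id`, `x_um`, `y_um`),
#'   `neuropil_contour` (two-column matrix), `stimulus_log`, `frame_rate_hz`,
#'   `sa_end_frame`, `ground_truth`, `config`.
#' @export
generate_dataset <- function(config) {
  validate_config(config)
  if (config$n_neurons < 2L) stopf("configuration error: n_neurons must be >= 2")
  fps <- config$frame_rate_hz
  n <- config$n_neurons

  sched <- build_stimulus_schedule(config)
  sa_frames <- as.integer(round_half_up(config$sa_duration_s * fps))
  np <- length(config$stimulus_positions_deg)
  evoked_dur <- config$n_trials * (np * (config$spot_on_s + config$gap_s)) +
    (config$n_trials - 1L) * config$iti_s
  n_frames <- sa_frames + as.integer(round_half_up(evoked_dur * fps)) + 1L

  stim <- data.frame(
    trial = sched$trial,
    position_deg = sched$position_deg,
    onset_time_s = sched$onset_time_s + config$sa_duration_s,
    onset_frame = as.integer(round_half_up((sched$onset_time_s + config$sa_duration_s) * fps)) + 1L)

  set.seed(stage_seed(config$seed, "membership"))
  memb <- build_memberships(config)

  # preferred angles: ensemble members cluster near their ensemble's centre;
  # remaining neurons are uniformly tuned across the stimulus range
  set.seed(stage_seed(config$seed, "tuning"))
  rng <- range(config$stimulus_positions_deg)
  n_ens <- length(memb$ea)
  centres <- if (n_ens == 1L) mean(rng) else
    seq(rng[1], rng[2], length.out = n_ens)
  pref <- stats::runif(n, rng[1], rng[2])
  for (i in seq_along(memb$ea))
    pref[memb$ea[[i]]] <- centres[i] + stats::rnorm(length(memb$ea[[i]]), 0, 3)
  pref <- clamp(pref, rng[1] - 10, rng[2] + 10)

  # geometry: anterior-posterior coordinate is the linear image of the
  # preferred angle plus retinotopic jitter, then rotated off-axis
  set.seed(stage_seed(config$seed, "geometry"))
  ap_len <- 200
  x0 <- ap_len * (pref - rng[1] + stats::rnorm(n, 0, config$retinotopy_noise_deg)) / diff(rng)
  x0 <- clamp(x0, 0, ap_len)
  y0 <- stats::runif(n, 20, 100)
  theta_c <- seq(0, 2 * pi, length.out = 61L)[-61L]
  contour0 <- cbind(100 + 100 * cos(theta_c), 60 + 50 * sin(theta_c))
  rot <- 25 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
  xy <- cbind(x0, y0) %*% t(R)
  xy[, 1] <- xy[, 1] + 30; xy[, 2] <- xy[, 2] + 30
  contour <- contour0 %*% t(R)
  contour[, 1] <- contour[, 1] + 30; contour[, 2] <- contour[, 2] + 30

  # spontaneous assembly events: Poisson, suppressed inside evoked windows
  ea_halfwin <- as.integer(round_half_up(5 * fps))
  in_ea <- rep(FALSE, n_frames)
  for (f in stim$onset_frame)
    in_ea[f:min(n_frames, f + ea_halfwin)] <- TRUE
  set.seed(stage_seed(config$seed, "sa-events"))
  impulses <- matrix(0, n, n_frames)
  true_event_times <- vector("list", length(memb$sa))
  total_s <- n_frames / fps
  for (i in seq_along(memb$sa)) {
    n_ev <- stats::rpois(1L, config$assembly_event_rate_hz * total_s)
    times <- sort(stats::runif(n_ev, 0, total_s))
    frames <- as.integer(round_half_up(times * fps)) + 1L
    keep <- frames <= n_frames & !in_ea[pmin(frames, n_frames)]
    frames <- frames[keep]
    true_event_times[[i]] <- times[keep]
    for (f in frames) {
      amp <- config$assembly_amplitude * stats::runif(length(memb$sa[[i]]), 0.8, 1.2)
      impulses[memb$sa[[i]], f] <- impulses[memb$sa[[i]], f] + amp
    }
  }

  # evoked responses: Gaussian tuning around the true preferred angle, with
  # ensemble members responding at full gain and the background attenuated
  set.seed(stage_seed(config$seed, "evoked"))
  in_ensemble <- rep(FALSE, n)
  for (m in memb$ea) in_ensemble[m] <- TRUE
  gain <- config$evoked_gain *
    ifelse(in_ensemble, 1, config$background_gain_frac)
  for (k in seq_len(nrow(stim))) {
    f <- stim$onset_frame[k]
    if (f > n_frames) next
    amp <- gain *
      exp(-(pref - stim$position_deg[k])^2 / (2 * config$tuning_sd_deg^2))
    if (config$trial_gain_sd > 0)
      amp <- amp * (1 + stats::rnorm(n, 0, config$trial_gain_sd))
    impulses[, f] <- impulses[, f] + pmax(amp, 0)
  }

  traces <- calcium_convolve(impulses, config$calcium_tau_s, fps)
  set.seed(stage_seed(config$seed, "noise"))
  if (config$noise_sd > 0)
    traces <- traces + matrix(stats::rnorm(n * n_frames, 0, config$noise_sd), n, n_frames)

  structure(list(
    traces = traces,
    positions = data.frame(neuron_id = seq_len(n), x_um = xy[, 1], y_um = xy[, 2]),
    neuropil_contour = contour,
    stimulus_log = stim,
    frame_rate_hz = fps,
    sa_end_frame = sa_frames,
    ground_truth = list(
      sa_assembly_membership = memb$sa,
      ea_ensemble_membership = memb$ea,
      true_preferred_deg = pref,
      true_event_times = true_event_times,
      roi_masks = NULL),
    config = config), class = "tecto_dataset")
}

#' @export
print.tecto_dataset <- function(x, ...) {
  cat(sprintf("<tecto_dataset> %d neurons x %d frames @ %.2f Hz; %d presentations; SA ends at frame %d\n",
              nrow(x$traces), ncol(x$traces), x$frame_rate_hz,
              nrow(x$stimulus_log), x$sa_end_frame))
  invisible(x)
}
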