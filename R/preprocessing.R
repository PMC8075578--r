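#' Compute dF/F traces with a running lower-percentile baseline
#'
#' For each neuron a baseline curve is fitted through the lower fraction of
#' the fluorescence samples (a running 20th percentile over a long window,
#' linearly interpolated between evaluation points), and the time-varying
#' baseline `F0(t)` is the minimum of that curve in a short window centred at
#' `t`. dF/F is `(F - F0) / F0`. Window edges use truncated windows.
#'
#' @param F raw fluorescence matrix, neurons x frames; must be non-negative.
#' @param frame_rate_hz frames per second.
#' @param window_s width of the minimum window (s), default 3.
#' @param lower_fraction percentile of the baseline curve, default 0.2.
#' @param baseline_window_s width of the running-percentile window (s),
#'   default 30.
#' @return list of class `tecto_dff` with `dff` and `F0` (both neurons x
#'   frames).
#' @export
compute_dff <- function(F, frame_rate_hz, window_s = 3, lower_fraction = 0.2,
                        baseline_window_s = 30) {
  F <- as.matrix(F)
  if (any(F < 0)) stopf("raw fluorescence must be non-negative")
  w_min <- as.integer(round_half_up(window_s * frame_rate_hz))
  if (w_min < 1L) stopf("window_s x frame_rate_hz must be >= 1")
  n_frames <- ncol(F)
  w_base <- max(3L, as.integer(round_half_up(baseline_window_s * frame_rate_hz)))
  half_b <- w_base %/% 2L
  stride <- max(1L, half_b %/% 2L)
  grid <- unique(c(seq(1L, n_frames, by = stride), n_frames))

  F0 <- matrix(0, nrow(F), n_frames)
  for (i in seq_len(nrow(F))) {
    q <- vapply(grid, function(t0) {
      lo <- max(1L, t0 - half_b); hi <- min(n_frames, t0 + half_b)
      stats::quantile(F[i, lo:hi], lower_fraction, names = FALSE)
    }, numeric(1))
    curve <- stats::approx(grid, q, xout = seq_len(n_frames), rule = 2)$y
    F0[i, ] <- windowed_min(curve, w_min)
    if (any(F0[i, ] <= 0))
      stopf("baseline F0 is non-positive for neuron %d; dF/F is undefined", i)
  }
  dff <- (F - F0) / F0
  structure(list(dff = dff, F0 = F0), class = "tecto_dff")
}

# minimum over a centred window of width w (truncated at the edges)
windowed_min <- function(x, w) {
  half <- w %/% 2L
  out <- x
  if (half == 0L) return(out)
  for (k in seq_len(half)) {
    n <- length(x)
    out <- pmin(out, c(x[(k + 1L):n], rep(x[n], k)))        # lead
    out <- pmin(out, c(rep(x[1L], k), x[1L:(n - k)]))       # lag
  }
  out
}

#' Binarize dF/F traces at mean + 2 SD
#'
#' A frame is active for a neuron when its dF/F strictly exceeds the neuron's
#' mean plus two standard deviations, both computed over the full recording.
#' Zero-variance neurons yield all-zero rows and are flagged.
#'
#' @param dff dF/F matrix (neurons x frames) or a `tecto_dff` object.
#' @param n_sd number of standard deviations above the mean, default 2.
#' @return list of class `tecto_raster` with `B` (0/1 matrix), `thresholds`,
#'   and `flat_neurons` (indices with zero variance).
#' @export
binarize <- function(dff, n_sd = 2) {
  if (inherits(dff, "tecto_dff")) dff <- dff$dff
  dff <- as.matrix(dff)
  if (!all(is.finite(dff))) stopf("dff must be finite")
  mu <- rowMeans(dff)
  sdv <- apply(dff, 1L, stats::sd)
  thr <- mu + n_sd * sdv
  B <- (dff > thr) * 1L
  flat <- which(sdv == 0)
  B[flat, ] <- 0L
  structure(list(B = B, thresholds = thr, flat_neurons = flat),
            class = "tecto_raster")
}

#' Label frames as spontaneous, evoked, or spontaneous-within-evoked
#'
#' SA covers the dark epoch before stimulation. For each stimulus onset, EA
#' covers the onset frame through `round(5 * fps)` frames after it, and SE
#' covers frames `round(6 * fps)` to `round(20 * fps)` after the onset,
#' except where a later stimulus' EA window has claimed them. Frames in the
#' evoked period belonging to neither window are labelled `none`.
#'
#' @param stimulus_log data.frame with `onset_frame` (1-based) and
#'   `position_deg`.
#' @param frame_rate_hz frames per second.
#' @param n_frames total number of frames.
#' @param sa_end_frame last frame of the spontaneous epoch.
#' @return list of class `tecto_epochs` with `labels` (character vector of
#'   `"SA"`, `"EA"`, `"SE"`, `"none"`) and `stimulus` (position shown, NA
#'   outside EA frames).
#' @export
segment_epochs <- function(stimulus_log, frame_rate_hz, n_frames, sa_end_frame) {
  if (nrow(stimulus_log) > 0 && any(stimulus_log$onset_frame <= sa_end_frame))
    stopf("all stimulus onsets must fall after sa_end_frame")
  labels <- rep("none", n_frames)
  stimulus <- rep(NA_real_, n_frames)
  if (sa_end_frame > 0) labels[seq_len(min(sa_end_frame, n_frames))] <- "SA"

  ea_w <- as.integer(round_half_up(5 * frame_rate_hz))
  se_lo <- as.integer(round_half_up(6 * frame_rate_hz))
  se_hi <- as.integer(round_half_up(20 * frame_rate_hz))

  ons <- stimulus_log$onset_frame
  pos <- stimulus_log$position_deg
  ord <- order(ons)
  # EA windows; later onsets overwrite earlier ones on overlap
  overlap_seen <- FALSE
  for (k in ord) {
    f <- ons[k]
    if (f > n_frames) next
    win <- f:min(n_frames, f + ea_w)
    if (any(labels[win] == "EA")) overlap_seen <- TRUE
    labels[win] <- "EA"
    stimulus[win] <- pos[k]
  }
  if (overlap_seen) warnf("overlapping EA windows: later onsets take precedence")
  # SE windows only claim frames not already taken by any EA window
  for (k in ord) {
    f <- ons[k]
    lo <- f + se_lo; hi <- min(n_frames, f + se_hi)
    if (lo > n_frames) next
    win <- lo:hi
    win <- win[labels[win] == "none"]
    labels[win] <- "SE"
  }
  structure(list(labels = labels, stimulus = stimulus), class = "tecto_epochs")
}

#' Frames carrying a given epoch label
#'
#' @param epochs a `tecto_epochs` object.
#' @param epoch one of `"SA"`, `"EA"`, `"SE"`, `"none"`, or `"TEA"` (the
#'   whole evoked period: every non-SA frame).
#' @return integer frame indices.
#' @export
epoch_frames <- function(epochs, epoch) {
  if (epoch == "TEA") return(which(epochs$labels != "SA"))
  which(epochs$labels == epoch)
}
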