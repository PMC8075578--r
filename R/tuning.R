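#' Per-neuron stimulus response amplitudes
#'
#' For every presentation, the response is the mean dF/F over frames 4 to 7
#' after the onset frame (inclusive); responses are then averaged over the
#' presentations of each stimulus position.
#'
#' @param dff dF/F matrix or `tecto_dff`.
#' @param stimulus_log data.frame with `onset_frame` and `position_deg`.
#' @return list with `amplitudes` (neurons x positions matrix) and
#'   `positions_deg` (sorted unique positions, the column order).
#' @export
stimulus_response_amplitudes <- function(dff, stimulus_log) {
  if (inherits(dff, "tecto_dff")) dff <- dff$dff
  dff <- as.matrix(dff)
  n_frames <- ncol(dff)
  pos <- sort(unique(stimulus_log$position_deg))
  acc <- matrix(0, nrow(dff), length(pos))
  cnt <- integer(length(pos))
  skipped <- 0L
  for (k in seq_len(nrow(stimulus_log))) {
    f <- stimulus_log$onset_frame[k]
    if (f + 7L > n_frames) { skipped <- skipped + 1L; next }
    j <- match(stimulus_log$position_deg[k], pos)
    acc[, j] <- acc[, j] + rowMeans(dff[, (f + 4L):(f + 7L), drop = FALSE])
    cnt[j] <- cnt[j] + 1L
  }
  if (skipped > 0L)
    warnf("%d presentation(s) too close to the recording end were skipped", skipped)
  if (any(cnt == 0L)) stopf("no usable presentations for some stimulus position")
  amplitudes <- sweep(acc, 2L, cnt, "/")
  list(amplitudes = amplitudes, positions_deg = pos)
}

#' Fit a Gaussian-with-offset tuning curve to one neuron
#'
#' The per-position amplitudes are interpolated by a natural cubic spline
#' onto a 5-degree grid spanning the stimulus range, and the curve
#' `b + a * exp(-(theta - mu)^2 / (2 sigma^2))` is fitted to the interpolated
#' amplitudes by least squares, restarted from several sigma initializations
#' (mu initialized at the grid argmax). The best fit by adjusted r-squared is
#' kept; a neuron is selective when adjusted r-squared exceeds 0.7.
#'
#' @param amplitudes amplitude per stimulus position.
#' @param positions_deg stimulus positions (>= 4 required).
#' @param grid_step_deg interpolation step, default 5.
#' @param r2_threshold selectivity threshold on adjusted r-squared, default
#'   0.7 (strict inequality).
#' @param sigma_starts sigma initializations (degrees).
#' @return one-row data.frame: `a`, `mu_deg`, `sigma_deg`, `b`, `adj_r2`,
#'   `selective`, `preferred_deg` (fitted peak clamped to the grid range).
#' @export
fit_tuning_curve <- function(amplitudes, positions_deg, grid_step_deg = 5,
                             r2_threshold = 0.7,
                             sigma_starts = c(5, 10, 20, 40, 80)) {
  if (length(positions_deg) < 4L) stopf("need at least 4 stimulus positions")
  ord <- order(positions_deg)
  xs <- positions_deg[ord]; ys <- amplitudes[ord]
  grid <- seq(min(xs), max(xs), by = grid_step_deg)
  yi <- stats::spline(xs, ys, xout = grid, method = "natural")$y

  n <- length(grid); p <- 4L
  mu0 <- grid[which.max(yi)]
  best <- NULL; best_r2 <- -Inf
  sst <- sum((yi - mean(yi))^2)
  for (s0 in sigma_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a * exp(-(g - mu)^2 / (2 * sg^2)),
        data = list(y = yi, g = grid),
        start = list(b = min(yi), a = max(yi) - min(yi), mu = mu0, sg = s0),
        lower = c(b = -Inf, a = 0, mu = min(grid) - 15, sg = 1),
        upper = c(b = Inf, a = Inf, mu = max(grid) + 15, sg = 500),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    res <- sum(stats::resid(fit)^2)
    r2 <- if (sst > 0) 1 - res / sst else 0
    adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    if (adj > best_r2) { best_r2 <- adj; best <- stats::coef(fit) }
  }
  if (is.null(best)) {
    return(data.frame(a = NA_real_, mu_deg = NA_real_, sigma_deg = NA_real_,
                      b = NA_real_, adj_r2 = NA_real_, selective = FALSE,
                      preferred_deg = NA_real_))
  }
  sel <- is.finite(best_r2) && best_r2 > r2_threshold
  data.frame(a = unname(best["a"]), mu_deg = unname(best["mu"]),
             sigma_deg = unname(best["sg"]), b = unname(best["b"]),
             adj_r2 = best_r2, selective = sel,
             preferred_deg = clamp(unname(best["mu"]), min(grid), max(grid)))
}

#' Fit tuning curves for every neuron
#'
#' @param dff dF/F matrix or `tecto_dff`.
#' @param stimulus_log stimulus log (see
#'   [stimulus_response_amplitudes()]).
#' @param ... passed to [fit_tuning_curve()].
#' @return data.frame with one row per neuron (`neuron_id` first column).
#' @export
fit_tuning <- function(dff, stimulus_log, ...) {
  amp <- stimulus_response_amplitudes(dff, stimulus_log)
  rows <- lapply(seq_len(nrow(amp$amplitudes)), function(i)
    fit_tuning_curve(amp$amplitudes[i, ], amp$positions_deg, ...))
  cbind(neuron_id = seq_len(nrow(amp$amplitudes)), do.call(rbind, rows))
}

#' Indices of selective neurons
#'
#' @param curves data.frame from [fit_tuning()].
#' @param r2_threshold threshold on adjusted r-squared (strict inequality),
#'   default 0.7.
#' @return integer vector of neuron indices.
#' @export
select_tuned <- function(curves, r2_threshold = 0.7) {
  which(!is.na(curves$adj_r2) & curves$adj_r2 > r2_threshold)
}
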