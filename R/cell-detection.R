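#' Rigid x-y registration by integer-pixel cross-correlation
#'
#' Each frame is compared with the reference frame by circular
#' cross-correlation (FFT-based) over shifts up to `max_shift_px`; the
#' best-correlating integer shift is reported as the frame's drift and the
#' frame is translated back by it. Ties (including constant frames) resolve
#' to the smallest shift, so a constant movie reports (0, 0) everywhere.
#'
#' @param movie 3-D array (rows x cols x frames), >= 2 frames.
#' @param reference_frame index of the reference, default 1.
#' @param max_shift_px largest drift considered, default 10.
#' @return list with `movie` (registered array; vacated borders filled with
#'   the frame median) and `shifts` (data.frame `dx`, `dy`: detected drift
#'   of each frame relative to the reference, in pixels; dx = columns,
#'   dy = rows).
#' @export
register_rigid <- function(movie, reference_frame = 1L, max_shift_px = 10L) {
  if (length(dim(movie)) != 3L || dim(movie)[3] < 2L)
    stopf("movie must be a 3-D array with at least 2 frames")
  h <- dim(movie)[1]; w <- dim(movie)[2]; nt <- dim(movie)[3]
  ref <- movie[, , reference_frame]
  ref0 <- ref - mean(ref)
  Fref <- stats::fft(ref0)
  shifts <- matrix(0L, nt, 2L)
  out <- movie
  # candidate circular lags within +/- max_shift_px
  lag_r <- c(0:min(max_shift_px, h - 1L),
             if (max_shift_px >= 1) (h - min(max_shift_px, h - 1L)):(h - 1L)) |> unique()
  lag_c <- c(0:min(max_shift_px, w - 1L),
             if (max_shift_px >= 1) (w - min(max_shift_px, w - 1L)):(w - 1L)) |> unique()
  to_signed <- function(lag, n) ifelse(lag > n %/% 2, lag - n, lag)
  for (t in seq_len(nt)) {
    fr <- movie[, , t]
    fr0 <- fr - mean(fr)
    if (sum(fr0^2) == 0 || sum(ref0^2) == 0) { shifts[t, ] <- c(0L, 0L); next }
    cc <- Re(stats::fft(Fref * Conj(stats::fft(fr0)), inverse = TRUE))
    cand <- cc[lag_r + 1L, lag_c + 1L, drop = FALSE]
    # tie-break: smallest shift norm
    sr <- to_signed(lag_r, h); sc <- to_signed(lag_c, w)
    pen <- outer(sr^2, sc^2, "+") * 1e-9 * max(abs(cand))
    best <- which(cand - pen == max(cand - pen), arr.ind = TRUE)[1L, ]
    # cc peak at lag k means frame content sits at ref position shifted by -k;
    # the drift of the frame relative to the reference is therefore -signed(k)
    dy <- -sr[best[1L]]; dx <- -sc[best[2L]]
    shifts[t, ] <- c(dx, dy)
    out[, , t] <- translate_frame(fr, -dx, -dy)
  }
  list(movie = out, shifts = data.frame(dx = shifts[, 1], dy = shifts[, 2]))
}

# integer translation with median fill
translate_frame <- function(fr, dx, dy) {
  h <- nrow(fr); w <- ncol(fr)
  out <- matrix(stats::median(fr), h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h; ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- fr[src_r[ok_r], src_c[ok_c]]
  out
}

#' Per-pixel activity map
#'
#' Scores each pixel by the temporal standard deviation of its
#' high-pass-filtered series (a running mean over `highpass_frames` is
#' subtracted), after removing each frame's spatial mean so frame-wide
#' intensity offsets do not register as activity.
#'
#' @param movie 3-D array (registered), >= 2 frames.
#' @param highpass_frames running-mean window of the high-pass filter,
#'   default 15.
#' @return matrix of non-negative scores, same spatial shape as the movie.
#' @export
compute_activity_map <- function(movie, highpass_frames = 15L) {
  if (length(dim(movie)) != 3L || dim(movie)[3] < 2L)
    stopf("activity map needs at least 2 frames")
  h <- dim(movie)[1]; w <- dim(movie)[2]; nt <- dim(movie)[3]
  M <- matrix(movie, h * w, nt)
  M <- sweep(M, 2L, colMeans(M))          # frame-wide offsets removed
  k <- min(highpass_frames, nt)
  run <- t(apply(M, 1L, function(x) {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(nt) - k %/% 2L, 1L)
    hi <- pmin(seq_len(nt) + k %/% 2L, nt)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }))
  hp <- M - run
  matrix(apply(hp, 1L, stats::sd), h, w)
}

#' Segment the activity map into candidate regions
#'
#' Thresholds the map (Otsu by default) and splits the suprathreshold area
#' into connected regions with a watershed transform, so neighbouring cells
#' separated by a ridge become distinct regions.
#'
#' @param map activity-map matrix.
#' @param threshold absolute score threshold; default Otsu on the map.
#' @param tolerance watershed merge tolerance as a fraction of the map
#'   maximum, default 0.05.
#' @param dilate_px grow each region by this many pixels so its surround is
#'   available to the correlation-based refinement (regions may then touch;
#'   the refinement and overlap resolution restore disjointness). Default 0.
#' @return list of integer vectors (pixel linear indices), largest first;
#'   empty list when nothing exceeds the threshold.
#' @export
segment_regions <- function(map, threshold = NULL, tolerance = 0.05,
                            dilate_px = 0L) {
  if (max(map) <= 0) return(list())
  if (is.null(threshold)) {
    norm <- map / max(map)
    threshold <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * max(map)
  }
  if (threshold < 0) stopf("threshold must be >= 0")
  mask <- map > threshold
  if (!any(mask)) return(list())
  relief <- map * mask
  lab <- EBImage::watershed(EBImage::Image(relief), tolerance = tolerance * max(map), ext = 1L)
  lab <- EBImage::imageData(lab)
  ids <- setdiff(unique(as.vector(lab)), 0)
  regions <- lapply(ids, function(i) which(lab == i))
  if (dilate_px > 0L) {
    kern <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "disc")
    regions <- lapply(regions, function(px) {
      m <- matrix(0, nrow(map), ncol(map))
      m[px] <- 1
      which(as.matrix(EBImage::dilate(EBImage::Image(m), kern)) > 0)
    })
  }
  regions[order(vapply(regions, length, integer(1)), decreasing = TRUE)]
}

#' Refine a candidate region into a cell ROI
#'
#' Correlates every region pixel's trace with the mean trace of the most
#' active pixel and its eight neighbours, fits a two-component Gaussian
#' mixture to the correlation distribution, and keeps the pixels above the
#' point where the two component densities cross (falling back to the median
#' correlation when the mixture is degenerate). ROIs smaller than `min_px`
#' pixels are rejected.
#'
#' @param region integer vector of pixel linear indices.
#' @param movie 3-D array.
#' @param min_px minimum ROI area in pixels, default 26 (5.5 um^2 at the
#'   default scale).
#' @return list: `accepted` (logical), then either `pixels`, `seed_pixel`,
#'   `threshold`, `correlations`, or `reason`.
#' @export
refine_roi <- function(region, movie, min_px = 26L) {
  if (length(region) == 0L) stopf("region is empty")
  if (length(region) < 9L)
    return(list(accepted = FALSE, reason = "region smaller than 9 pixels"))
  h <- dim(movie)[1]; w <- dim(movie)[2]; nt <- dim(movie)[3]
  M <- matrix(movie, h * w, nt)
  sdv <- apply(M[region, , drop = FALSE], 1L, stats::sd)
  seed_px <- region[which.max(sdv)]
  rr <- (seed_px - 1L) %% h + 1L; cc <- (seed_px - 1L) %/% h + 1L
  nb_r <- pmax(1L, rr - 1L):pmin(h, rr + 1L)
  nb_c <- pmax(1L, cc - 1L):pmin(w, cc + 1L)
  nb <- as.vector(outer(nb_r, nb_c, function(r, c) (c - 1L) * h + r))
  seed_trace <- colMeans(M[nb, , drop = FALSE])
  if (stats::sd(seed_trace) == 0)
    return(list(accepted = FALSE, reason = "seed trace has zero variance"))
  cors <- suppressWarnings(
    as.vector(stats::cor(t(M[region, , drop = FALSE]), seed_trace)))
  cors[is.na(cors)] <- 0

  thr <- gmm_correlation_threshold(cors)
  keep <- region[cors > thr]
  if (length(keep) < min_px)
    return(list(accepted = FALSE,
                reason = sprintf("ROI area %d < %d pixels", length(keep), min_px)))
  list(accepted = TRUE, pixels = keep, seed_pixel = seed_px, threshold = thr,
       correlations = cors)
}

# Mclust resolves mclustBIC in the caller's environment, so both must be in
# the package namespace
#' @importFrom mclust Mclust mclustBIC
NULL

# threshold separating the two mixture components: the boundary of the
# posterior classification when the classes separate cleanly, otherwise the
# point between the means where the component densities cross; median
# fallback when the mixture is degenerate (single mode)
gmm_correlation_threshold <- function(cors) {
  if (stats::sd(cors) < 1e-12) return(min(cors) - 1)   # all equal: keep all
  fit <- tryCatch(
    suppressWarnings(Mclust(cors, G = 2L, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL)
  fallback <- stats::median(cors)
  if (is.null(fit)) return(fallback)
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1L) sg <- rep(sg, 2L)
  pr <- fit$parameters$pro
  if (abs(diff(mu)) < 0.02) return(fallback)
  hi_class <- which.max(mu)
  hi_cors <- cors[fit$classification == hi_class]
  lo_cors <- cors[fit$classification != hi_class]
  if (length(hi_cors) > 0L && length(lo_cors) > 0L &&
      max(lo_cors) < min(hi_cors))
    return((max(lo_cors) + min(hi_cors)) / 2)
  grid <- seq(min(mu), max(mu), length.out = 512L)
  d1 <- pr[1] * stats::dnorm(grid, mu[1], sg[1])
  d2 <- pr[2] * stats::dnorm(grid, mu[2], sg[2])
  s <- sign(d1 - d2)
  cross <- which(diff(s) != 0)
  if (length(cross) == 0L) return(fallback)
  grid[cross[which.min(abs(grid[cross] - mean(mu)))]]
}

#' Average ROI pixels into raw fluorescence traces
#'
#' @param rois list of pixel-index vectors (or a `tecto_rois` object).
#' @param movie 3-D array.
#' @return matrix, cells x frames: `F[c, t]` is the mean over the ROI's
#'   pixels at frame `t`.
#' @export
extract_raw_traces <- function(rois, movie) {
  if (inherits(rois, "tecto_rois")) rois <- rois$pixels
  h <- dim(movie)[1]; w <- dim(movie)[2]; nt <- dim(movie)[3]
  M <- matrix(movie, h * w, nt)
  bad <- vapply(rois, function(px) any(px < 1L | px > h * w), logical(1))
  if (any(bad)) stopf("ROI pixel index out of movie bounds")
  t(vapply(rois, function(px) colMeans(M[px, , drop = FALSE]), numeric(nt)))
}

#' Full automatic cell-detection pipeline
#'
#' Registers the movie, computes the activity map, segments it by watershed,
#' refines each region with the Gaussian-mixture correlation threshold,
#' resolves pixels claimed by several ROIs in favour of the ROI with the
#' higher seed correlation, and extracts raw traces.
#'
#' @param movie 3-D array (rows x cols x frames).
#' @param scale_um_per_px pixel size; default `sqrt(5.5 / 26)` (26 px =
#'   5.5 um^2).
#' @param min_px minimum ROI area, default 26.
#' @param threshold,tolerance passed to [segment_regions()].
#' @param register run rigid registration first (default TRUE).
#' @return list of class `tecto_rois`: `pixels` (list per cell), `centroids`
#'   (data.frame `x_um`, `y_um`), `scale_um_per_px`, `F` (cells x frames raw
#'   traces), `shifts`, `activity_map`, `rejected` (reasons).
#' @export
detect_cells <- function(movie, scale_um_per_px = sqrt(5.5 / 26), min_px = 26L,
                         threshold = NULL, tolerance = 0.03, dilate_px = 2L,
                         register = TRUE) {
  shifts <- NULL
  if (register) {
    reg <- register_rigid(movie)
    movie <- reg$movie; shifts <- reg$shifts
  }
  amap <- compute_activity_map(movie)
  regions <- segment_regions(amap, threshold = threshold, tolerance = tolerance,
                             dilate_px = dilate_px)
  rois <- list(); seed_cor <- list(); rejected <- character(0)
  for (rg in regions) {
    ref <- refine_roi(rg, movie, min_px = min_px)
    if (!ref$accepted) { rejected <- c(rejected, ref$reason); next }
    rois[[length(rois) + 1L]] <- ref$pixels
    seed_cor[[length(seed_cor) + 1L]] <-
      stats::setNames(ref$correlations[match(ref$pixels, rg)], ref$pixels)
  }
  # disjointness: a pixel claimed twice goes to the ROI where it correlates
  # better with the seed
  if (length(rois) > 1L) {
    owner <- new.env(hash = TRUE)
    for (i in seq_along(rois)) {
      for (px in rois[[i]]) {
        key <- as.character(px)
        sc <- seed_cor[[i]][[key]]
        cur <- owner[[key]]
        if (is.null(cur) || sc > cur[2]) owner[[key]] <- c(i, sc)
      }
    }
    for (i in seq_along(rois))
      rois[[i]] <- rois[[i]][vapply(as.character(rois[[i]]),
                                    function(k) owner[[k]][1] == i, logical(1))]
    keep <- vapply(rois, length, integer(1)) >= min_px
    rejected <- c(rejected, rep("below min_px after overlap resolution", sum(!keep)))
    rois <- rois[keep]
  }
  h <- dim(movie)[1]
  centroids <- do.call(rbind, lapply(rois, function(px) {
    rr <- (px - 1L) %% h + 1L; cc <- (px - 1L) %/% h + 1L
    data.frame(x_um = mean(cc) * scale_um_per_px, y_um = mean(rr) * scale_um_per_px)
  }))
  F <- if (length(rois) > 0) extract_raw_traces(rois, movie) else
    matrix(0, 0L, dim(movie)[3])
  structure(list(pixels = rois, centroids = centroids,
                 scale_um_per_px = scale_um_per_px, F = F, shifts = shifts,
                 activity_map = amap, rejected = rejected),
            class = "tecto_rois")
}
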