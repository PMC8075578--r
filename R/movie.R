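#' Render a pixel-level movie from synthetic traces
#'
#' Places disk ROIs at the dataset's neuron positions (rescaled to fit the
#' field of view), sets pixel fluorescence to `baseline + amplitude * trace`
#' inside each disk, blurs with a Gaussian PSF, and adds signal-dependent
#' noise. The ROI masks are returned as ground truth for cell-detection
#' recovery tests.
#'
#' @param dataset a `tecto_dataset` (traces are used as the per-cell
#'   signal).
#' @param neurons indices of the neurons to render (default: all).
#' @param frames frame indices to render (default: all).
#' @param fov c(rows, cols) of the field of view, default c(192, 192).
#' @param cell_radius_px disk radius, default 4 (a 49-pixel ROI).
#' @param psf_sigma_px Gaussian PSF sigma; 0 disables blurring.
#' @param baseline background fluorescence level, default 100.
#' @param amplitude fluorescence per unit trace, default 120.
#' @param photon_noise_scale noise SD is `photon_noise_scale * sqrt(value)`;
#'   0 disables noise.
#' @param max_overlap_frac warn (not error) when any two ROIs overlap by
#'   more than this fraction of the smaller disk, default 0.25.
#' @param min_sep_px minimum centre-to-centre distance enforced between
#'   rendered cells (somata are packed, not interpenetrating); default one
#'   disk diameter plus one pixel. Set 0 to disable the repulsion.
#' @param seed integer seed for the noise.
#' @return list: `movie` (rows x cols x frames array), `roi_masks` (list of
#'   pixel linear-index vectors), `centers_px` (matrix row, col).
#' @export
generate_movie <- function(dataset, neurons = NULL, frames = NULL,
                           fov = c(192L, 192L), cell_radius_px = 4L,
                           psf_sigma_px = 0.8, baseline = 100,
                           amplitude = 120, photon_noise_scale = 1,
                           max_overlap_frac = 0.25,
                           min_sep_px = 2L * cell_radius_px + 1L, seed = 1L) {
  if (is.null(neurons)) neurons <- seq_len(nrow(dataset$traces))
  if (is.null(frames)) frames <- seq_len(ncol(dataset$traces))
  traces <- dataset$traces[neurons, frames, drop = FALSE]
  pos <- dataset$positions[neurons, c("x_um", "y_um")]
  h <- fov[1]; w <- fov[2]
  margin <- cell_radius_px + 2L
  sx <- (w - 2 * margin) / max(diff(range(pos$x_um)), 1e-9)
  sy <- (h - 2 * margin) / max(diff(range(pos$y_um)), 1e-9)
  s <- min(sx, sy)
  cx <- (pos$x_um - min(pos$x_um)) * s + margin
  cy <- (pos$y_um - min(pos$y_um)) * s + margin
  # deterministic pairwise repulsion: push near-coincident centres apart
  if (min_sep_px > 0 && length(cx) > 1L) {
    for (it in seq_len(50L)) {
      moved <- FALSE
      for (i in seq_along(cx)[-1L]) for (j in seq_len(i - 1L)) {
        dx <- cx[i] - cx[j]; dy <- cy[i] - cy[j]
        dist <- sqrt(dx^2 + dy^2)
        if (dist < min_sep_px) {
          if (dist < 1e-6) { dx <- 1; dy <- 0; dist <- 1 }
          push <- (min_sep_px - dist) / 2 + 0.1
          cx[i] <- cx[i] + push * dx / dist; cy[i] <- cy[i] + push * dy / dist
          cx[j] <- cx[j] - push * dx / dist; cy[j] <- cy[j] - push * dy / dist
          moved <- TRUE
        }
      }
      cx <- clamp(cx, margin, w - margin); cy <- clamp(cy, margin, h - margin)
      if (!moved) break
    }
  }
  cx <- round(cx); cy <- round(cy)
  if (any(cx < 1 | cx > w | cy < 1 | cy > h))
    stopf("neuron positions do not fit inside the field of view")

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  masks <- lapply(seq_along(neurons), function(i)
    which((rows - cy[i])^2 + (cols - cx[i])^2 <= cell_radius_px^2))
  # overlapping ROI check (warn only)
  if (length(masks) > 1L) {
    worst <- 0
    for (i in seq_along(masks)[-1L]) for (j in seq_len(i - 1L)) {
      ov <- length(intersect(masks[[i]], masks[[j]])) /
        min(length(masks[[i]]), length(masks[[j]]))
      worst <- max(worst, ov)
    }
    if (worst > max_overlap_frac)
      warnf("ROIs overlap by up to %.0f%% of the smaller disk", 100 * worst)
  }

  nt <- length(frames)
  movie <- array(baseline, dim = c(h, w, nt))
  for (i in seq_along(masks)) {
    px <- masks[[i]]
    for (t in seq_len(nt))
      movie[px + (t - 1L) * h * w] <- movie[px + (t - 1L) * h * w] +
        amplitude * traces[i, t]
  }
  if (psf_sigma_px > 0)
    for (t in seq_len(nt))
      movie[, , t] <- as.matrix(EBImage::gblur(EBImage::Image(movie[, , t]),
                                               sigma = psf_sigma_px))
  if (photon_noise_scale > 0) {
    set.seed(seed)
    movie <- movie + stats::rnorm(length(movie)) * photon_noise_scale *
      sqrt(pmax(movie, 0))
    movie[movie < 0] <- 0
  }
  list(movie = movie, roi_masks = masks, centers_px = cbind(row = cy, col = cx))
}

#' Intersection-over-union matching of detected vs true ROI masks
#'
#' Greedy best-match per true mask.
#'
#' @param detected list of pixel-index vectors.
#' @param truth list of pixel-index vectors.
#' @param iou_match IoU above which a true cell counts as matched, default
#'   0.5.
#' @return list: `mean_iou` (over true cells, best-match IoU), `matched_frac`
#'   (true cells with best IoU >= `iou_match`), `per_cell` IoU vector.
#' @export
roi_match_iou <- function(detected, truth, iou_match = 0.5) {
  if (length(truth) == 0L) stopf("truth mask list is empty")
  per <- vapply(truth, function(tr) {
    if (length(detected) == 0L) return(0)
    max(vapply(detected, function(d)
      length(intersect(d, tr)) / length(union(d, tr)), numeric(1)))
  }, numeric(1))
  list(mean_iou = mean(per), matched_frac = mean(per >= iou_match),
       per_cell = per)
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Intensities are scaled linearly onto the 16-bit range; the scale and
#' offset are returned so the movie can be recovered exactly up to
#' quantization.
#'
#' @param movie 3-D array.
#' @param path output file.
#' @return invisibly, list(offset, scale) of the quantization.
#' @export
write_movie_tiff <- function(movie, path) {
  lo <- min(movie); hi <- max(movie)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(t) (movie[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(list(offset = lo, scale = scale))
}

#' Read a multi-page TIFF as a movie array
#'
#' @param path TIFF file.
#' @param offset,scale quantization parameters from [write_movie_tiff()]
#'   (defaults leave intensities in `[0, 1]`).
#' @return 3-D array (rows x cols x frames).
#' @export
read_movie_tiff <- function(path, offset = 0, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale + offset
  arr
}
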