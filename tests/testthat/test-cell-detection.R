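flashing_disk_movie <- function(h = 32, w = 32, nt = 60, centre = c(16, 16),
                                radius = 3, background = 10, flash = 50,
                                seed = 30) {
  set.seed(seed)
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  disk <- (rows - centre[1])^2 + (cols - centre[2])^2 <= radius^2
  mv <- array(background, dim = c(h, w, nt))
  on_frames <- seq(5, nt, by = 7)
  for (t in on_frames) mv[, , t][disk] <- flash
  list(movie = mv, disk = which(disk), on_frames = on_frames)
}

test_that("registration reports zero drift for still or constant movies", {
  fx <- flashing_disk_movie()
  reg <- register_rigid(fx$movie)
  expect_true(all(reg$shifts == 0))
  const <- array(5, dim = c(16, 16, 4))
  expect_true(all(register_rigid(const)$shifts == 0))
})

test_that("an injected integer drift is inverted exactly", {
  set.seed(31)
  scene <- matrix(runif(48 * 48, 0, 1), 48, 48)
  scene[20:26, 20:26] <- 3
  mv <- array(0, dim = c(48, 48, 3))
  mv[, , 1] <- scene
  mv[, , 2] <- scene
  shift_scene <- function(s, dx, dy) {
    out <- matrix(median(s), nrow(s), ncol(s))
    sr <- seq_len(nrow(s)) - dy; sc <- seq_len(ncol(s)) - dx
    okr <- sr >= 1 & sr <= nrow(s); okc <- sc >= 1 & sc <= ncol(s)
    out[okr, okc] <- s[sr[okr], sc[okc]]
    out
  }
  mv[, , 3] <- shift_scene(scene, 3, -2)
  reg <- register_rigid(mv)
  expect_equal(unlist(reg$shifts[3, ]), c(dx = 3, dy = -2))
  expect_equal(unlist(reg$shifts[2, ]), c(dx = 0, dy = 0))
  # registration restores the interior of the drifted frame
  expect_equal(reg$movie[10:40, 10:40, 3], scene[10:40, 10:40])
})

test_that("the activity map isolates flashing pixels and ignores offsets", {
  fx <- flashing_disk_movie()
  amap <- compute_activity_map(fx$movie)
  expect_true(all(amap >= 0))
  # the top-scoring pixels are exactly the disk
  k <- length(fx$disk)
  expect_setequal(order(amap, decreasing = TRUE)[seq_len(k)], fx$disk)
  # constant movie maps to zero
  expect_true(all(compute_activity_map(array(7, dim = c(8, 8, 10))) == 0))
  # frame-wide constant offsets leave the map unchanged
  mv2 <- fx$movie
  offs <- rnorm(dim(mv2)[3], 0, 2)
  for (t in seq_len(dim(mv2)[3])) mv2[, , t] <- mv2[, , t] + offs[t]
  expect_equal(compute_activity_map(mv2), amap, tolerance = 1e-9)
  expect_error(compute_activity_map(array(1, dim = c(4, 4, 1))), "2 frames")
})

test_that("watershed segmentation separates blobs that thresholding merges", {
  gauss_blob <- function(h, w, cy, cx, s, amp) {
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    amp * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * s^2))
  }
  # two well-separated blobs: two regions (oracle: connected components)
  m1 <- gauss_blob(40, 40, 10, 10, 2, 1) + gauss_blob(40, 40, 30, 30, 2, 1)
  reg1 <- segment_regions(m1, threshold = 0.2)
  expect_length(reg1, 2L)
  # empty map: zero regions, and a too-high threshold is not an error
  expect_length(segment_regions(matrix(0, 10, 10)), 0L)
  expect_length(segment_regions(m1, threshold = 10), 0L)
  # one dumbbell with a saddle: watershed gives 2 where thresholding gives 1
  m2 <- gauss_blob(40, 40, 20, 14, 3, 1) + gauss_blob(40, 40, 20, 26, 3, 1)
  reg2 <- segment_regions(m2, threshold = 0.15, tolerance = 0.05)
  expect_length(reg2, 2L)
  # oracle: plain connected components of the thresholded mask see one blob
  expect_equal(max(EBImage::imageData(EBImage::bwlabel(EBImage::Image(m2 > 0.15)))), 1)
})

test_that("ROI refinement keeps correlated pixels and enforces the 26-pixel floor", {
  set.seed(32)
  h <- 20; w <- 20; nt <- 150
  mv <- array(rnorm(h * w * nt, 0, 1), dim = c(h, w, nt))
  sig <- rnorm(nt, 0, 4)
  # 60 signal pixels in a block, 40 noise pixels alongside
  block <- as.vector(outer(3:12, (3:8) - 1, function(r, c) c * h + r))[1:60]
  noise_px <- as.vector(outer(3:12, (9:12) - 1, function(r, c) c * h + r))
  for (t in seq_len(nt)) mv[, , t][block] <- mv[, , t][block] + sig[t]
  region <- c(block, noise_px)
  ref <- refine_roi(region, mv)
  expect_true(ref$accepted)
  expect_gte(length(intersect(ref$pixels, block)) / length(block), 0.9)
  expect_lte(length(intersect(ref$pixels, noise_px)) / length(noise_px), 0.2)
  # a region whose pixels all share one trace keeps every pixel
  mv2 <- array(0, dim = c(10, 10, 50))
  tr <- sin(seq_len(50))
  for (t in seq_len(50)) mv2[, , t][1:30] <- tr[t]
  ref2 <- refine_roi(1:30, mv2)
  expect_true(ref2$accepted)
  expect_setequal(ref2$pixels, 1:30)
  # 20 correlated pixels only: rejected below the 26-pixel floor
  mv3 <- array(rnorm(10 * 10 * 80), dim = c(10, 10, 80))
  for (t in seq_len(80)) mv3[, , t][1:20] <- mv3[, , t][1:20] + 5 * tr[t %% 50 + 1]
  ref3 <- refine_roi(1:20, mv3)
  expect_false(ref3$accepted)
  expect_match(ref3$reason, "26|9 pixels")
  expect_error(refine_roi(integer(0), mv3), "empty")
})

test_that("trace extraction averages ROI pixels exactly", {
  mv <- array(2.5, dim = c(6, 6, 8))
  expect_equal(extract_raw_traces(list(c(1, 8, 15)), mv),
               matrix(2.5, 1, 8))
  set.seed(33)
  mv2 <- array(rnorm(6 * 6 * 8), dim = c(6, 6, 8))
  # single-pixel ROI equals that pixel's series
  expect_equal(as.vector(extract_raw_traces(list(14L), mv2)), mv2[2, 3, ])
  # hand-computed average over a known pixel set
  px <- c(1L, 7L, 20L)
  M <- matrix(mv2, 36, 8)
  expect_equal(as.vector(extract_raw_traces(list(px), mv2)),
               colMeans(M[px, ]), tolerance = 1e-12)
  expect_error(extract_raw_traces(list(c(1L, 999L)), mv2), "bounds")
})

test_that("the full detection pipeline recovers synthetic ROIs", {
  fx <- movie_fixture()
  det <- suppressWarnings(detect_cells(fx$movie, register = FALSE))
  # emitted ROIs satisfy the structural invariants
  expect_true(all(vapply(det$pixels, length, integer(1)) >= 26L))
  all_px <- unlist(det$pixels)
  expect_equal(anyDuplicated(all_px), 0L)           # pairwise disjoint
  m <- roi_match_iou(det$pixels, fx$roi_masks)
  expect_gte(m$mean_iou, 0.7)
  expect_gte(m$matched_frac, 0.9)
})

test_that("a noise-free single-cell movie reproduces baseline + trace exactly", {
  d <- generate_dataset(simulation_config(n_neurons = 2, sa_duration_s = 30,
                                          n_trials = 1, noise_sd = 0, seed = 3))
  mv <- generate_movie(d, neurons = 1:2, fov = c(40, 40), cell_radius_px = 3,
                       psf_sigma_px = 0, photon_noise_scale = 0,
                       amplitude = 1, baseline = 20)
  px <- mv$roi_masks[[1]]
  hw <- 40 * 40
  for (t in c(1, 10, 30))
    expect_equal(unique(mv$movie[px + (t - 1) * hw]),
                 20 + d$traces[1, t], tolerance = 1e-12)
  # zero-amplitude traces: temporally constant movie
  mv0 <- generate_movie(d, amplitude = 0, fov = c(40, 40),
                        psf_sigma_px = 0, photon_noise_scale = 0)
  expect_equal(mv0$movie[, , 1], mv0$movie[, , 5])
})

test_that("movies survive the 16-bit TIFF round trip", {
  fx <- flashing_disk_movie(h = 16, w = 16, nt = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  q <- write_movie_tiff(fx$movie, path)
  back <- read_movie_tiff(path, offset = q$offset, scale = q$scale)
  expect_equal(dim(back), dim(fx$movie))
  expect_lt(max(abs(back - fx$movie)), (q$scale) / 65535 + 1e-9)
})
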