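make_ellipse_points <- function(centre, a, b, angle = 0, n = 40, jitter = 0,
                                seed = 1) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  pts <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  pts <- pts %*% t(R)
  pts[, 1] <- pts[, 1] + centre[1] + rnorm(n, 0, jitter)
  pts[, 2] <- pts[, 2] + centre[2] + rnorm(n, 0, jitter)
  pts
}

test_that("the ellipse fit recovers an analytic ellipse and its projection scale", {
  pts <- make_ellipse_points(c(200, 100), 100, 50)
  ax <- fit_ap_axis(pts)
  expect_equal(ax$centre, c(200, 100), tolerance = 1e-6)
  expect_equal(ax$semi_axes, c(100, 50), tolerance = 1e-6)
  # major axis along x; anterior = end nearer the origin
  expect_equal(abs(ax$u), c(1, 0), tolerance = 1e-6)
  expect_equal(ax$u[1], 1, tolerance = 1e-6)
  # 30 um along the axis from the centre maps to 0.65 of the span
  expect_equal(project_ap(ax, cbind(230, 100)), 0.65, tolerance = 1e-6)
})

test_that("the fitted axis is equivariant under rotation", {
  base <- make_ellipse_points(c(200, 100), 100, 50)
  ax0 <- fit_ap_axis(base)
  rot <- 30 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  ax1 <- fit_ap_axis(base %*% t(R))
  d_angle <- (ax1$angle_rad - ax0$angle_rad) %% pi
  expect_equal(min(d_angle, pi - d_angle), rot, tolerance = 1e-6)
})

test_that("noisy ellipse samples recover parameters within 5%", {
  pts <- make_ellipse_points(c(150, 80), 90, 45, angle = 0.4, n = 80,
                             jitter = 1.5, seed = 6)
  ax <- fit_ap_axis(pts)
  expect_lt(abs(ax$semi_axes[1] - 90) / 90, 0.05)
  expect_lt(abs(ax$semi_axes[2] - 45) / 45, 0.05)
  d_angle <- (ax$angle_rad - 0.4) %% pi
  expect_lt(min(d_angle, pi - d_angle), 0.05)
  expect_error(fit_ap_axis(cbind(1:10, 2 * (1:10))), "collinear")
})

test_that("disjoint perfectly coactive groups are found exactly", {
  set.seed(12)
  nt <- 300
  sched_a <- which(runif(nt) < 0.1)
  sched_b <- which(runif(nt) < 0.1)
  x <- matrix(rnorm(20 * nt, 0, 0.01), 20, nt)
  x[1:10, sched_a] <- x[1:10, sched_a] + 1
  x[11:20, sched_b] <- x[11:20, sched_b] + 1
  asm <- detect_assemblies(x, seq_len(nt), n_shuffles = 100, seed = 3)
  expect_length(asm, 2L)
  members <- lapply(asm, `[[`, "members")
  expect_setequal(vapply(members, paste, character(1), collapse = ","),
                  c(paste(1:10, collapse = ","), paste(11:20, collapse = ",")))
  # determinism
  asm2 <- detect_assemblies(x, seq_len(nt), n_shuffles = 100, seed = 3)
  expect_identical(lapply(asm2, `[[`, "members"), members)
})

test_that("generator assemblies are recovered with high Jaccard at low noise", {
  d <- lownoise_dataset()
  ep <- segment_epochs(d$stimulus_log, d$frame_rate_hz, ncol(d$traces),
                       d$sa_end_frame)
  asm <- detect_assemblies(d$traces, epoch_frames(ep, "SA"),
                           n_shuffles = 200, seed = 5, epoch = "SA")
  jac <- tectodyn:::membership_jaccard(asm, d$ground_truth$sa_assembly_membership)
  expect_gte(jac, 0.9)
})

test_that("assembly statistics reduce to simple arithmetic on toy cases", {
  pts <- make_ellipse_points(c(200, 100), 100, 50)
  ax <- fit_ap_axis(pts)
  # two members whose AP projections are 0.2 and 0.4 average to 0.3
  p1 <- c(200 - 0.6 * 100, 100)   # t = 0.2
  p2 <- c(200 - 0.2 * 100, 100)   # t = 0.4
  pos <- data.frame(neuron_id = 1:2, x_um = c(p1[1], p2[1]),
                    y_um = c(p1[2], p2[2]))
  asm <- structure(list(list(members = 1:2, epoch = "SA")),
                   class = "tecto_assemblies")
  st <- assembly_statistics(asm, pos, ax)
  expect_equal(st$com_ap, 0.3, tolerance = 1e-9)
  expect_true(is.na(st$coverage))                 # hull needs 3 members
  # preferred angles 80 and 100: mean 90, sample variance 200
  tun <- data.frame(neuron_id = 1:2, adj_r2 = c(0.9, 0.95),
                    preferred_deg = c(80, 100))
  st2 <- assembly_statistics(asm, pos, ax, tun)
  expect_equal(st2$mean_tuning_deg, 90)
  expect_equal(st2$tuning_variance_deg2, 200)
})

test_that("coverage matches a brute-force hull-area oracle", {
  set.seed(14)
  pos <- data.frame(neuron_id = 1:30, x_um = runif(30, 0, 200),
                    y_um = runif(30, 0, 100))
  ax <- fit_ap_axis(make_ellipse_points(c(100, 50), 110, 55))
  members <- sample(30, 8)
  asm <- structure(list(list(members = members, epoch = "SA")),
                   class = "tecto_assemblies")
  st <- assembly_statistics(asm, pos, ax)
  hull_area <- function(xy) {
    h <- chull(xy); xy <- xy[h, ]
    n <- nrow(xy); j <- c(n, 1:(n - 1))
    abs(sum(xy[j, 1] * xy[, 2] - xy[, 1] * xy[j, 2])) / 2
  }
  expect_equal(st$coverage,
               hull_area(as.matrix(pos[members, 2:3])) /
                 hull_area(as.matrix(pos[, 2:3])),
               tolerance = 1e-12)
})

test_that("com_ap is invariant under a rigid motion of positions and contour", {
  set.seed(15)
  contour <- make_ellipse_points(c(100, 60), 100, 50, angle = 0.3, n = 60)
  pos <- data.frame(neuron_id = 1:10, x_um = runif(10, 20, 180),
                    y_um = runif(10, 20, 100))
  asm <- structure(list(list(members = 1:5, epoch = "SA")),
                   class = "tecto_assemblies")
  st0 <- assembly_statistics(asm, pos, fit_ap_axis(contour))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(12, -8)
  pos2 <- pos
  xy2 <- as.matrix(pos[, 2:3]) %*% t(R)
  pos2$x_um <- xy2[, 1] + shift[1]; pos2$y_um <- xy2[, 2] + shift[2]
  c2 <- contour %*% t(R)
  c2[, 1] <- c2[, 1] + shift[1]; c2[, 2] <- c2[, 2] + shift[2]
  st1 <- assembly_statistics(asm, pos2, fit_ap_axis(c2))
  expect_equal(st1$com_ap, st0$com_ap, tolerance = 1e-6)
})

test_that("overlap normalizes by the smaller assembly and is bounded", {
  wrap <- function(...) structure(lapply(list(...), function(m)
    list(members = m)), class = "tecto_assemblies")
  expect_equal(assembly_overlap(wrap(1:10), wrap(6:15)), 0.5)
  expect_equal(assembly_overlap(wrap(1:10, 11:20), wrap(1:10, 11:20)), 1)
  expect_equal(assembly_overlap(wrap(1:10), wrap(11:20)), 0)
  expect_true(is.na(assembly_overlap(wrap(), wrap(1:3))))
  # subset containment also gives 1 under min-normalization
  expect_equal(assembly_overlap(wrap(1:5), wrap(1:20)), 1)
  expect_equal(assembly_overlap(wrap(1:10), wrap(6:15), method = "jaccard"),
               5 / 15)
})

test_that("measured overlap rises monotonically with the generator knob", {
  gt_overlap <- function(ov) {
    # 64 neurons -> assemblies of 8, so overlap fractions land exactly
    d <- generate_dataset(simulation_config(
      n_neurons = 64, sa_duration_s = 30, n_trials = 1, ea_sa_overlap = ov,
      seed = 4))
    wrap <- function(ms) structure(lapply(ms, function(m) list(members = m)),
                                   class = "tecto_assemblies")
    assembly_overlap(wrap(d$ground_truth$ea_ensemble_membership),
                     wrap(d$ground_truth$sa_assembly_membership))
  }
  vals <- vapply(c(0, 0.5, 1), gt_overlap, numeric(1))
  expect_equal(vals, c(0, 0.5, 1))
})
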