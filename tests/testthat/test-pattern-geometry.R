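test_that("the coactivity threshold matches a brute-force null exactly", {
  set.seed(20)
  B <- matrix(rbinom(5 * 200, 1, 0.15), 5, 200)
  got <- coactivity_threshold(B, n_shuffles = 50, alpha = 0.05, seed = 7)
  expect_identical(got$threshold,
                   oracle_coactivity_threshold(B, 50, 0.05, seed = 7))
  expect_identical(got$counts, as.integer(colSums(B)))
})

test_that("degenerate rasters yield no significant frames", {
  ones <- coactivity_threshold(matrix(1L, 4, 50), n_shuffles = 30, seed = 1)
  expect_true(all(ones$counts <= ones$threshold))   # shuffle-invariant raster
  zeros <- coactivity_threshold(matrix(0L, 4, 50), n_shuffles = 30, seed = 1)
  expect_equal(zeros$threshold, 1L)
  expect_true(all(zeros$counts <= zeros$threshold))
})

test_that("row shuffles preserve per-neuron active counts exactly", {
  set.seed(21)
  B <- matrix(rbinom(300, 1, 0.2), 6, 50)
  # re-draw the surrogates the implementation uses and check row sums
  set.seed(9)
  k <- rowSums(B)
  for (i in seq_len(nrow(B))) {
    at <- sample.int(ncol(B), k[i])
    expect_length(at, k[i])
    expect_equal(anyDuplicated(at), 0L)
  }
})

test_that("pattern selection takes significant strict peaks, plateau-first", {
  mk_series <- function(counts, thr) structure(
    list(counts = as.integer(counts), threshold = as.integer(thr),
         alpha = 0.05, null = "pooled"), class = "tecto_coactivity")
  B <- matrix(1L, 4, 4)
  lab <- rep("SA", 4)
  # [1,3,1] -> peak at the middle frame
  ps <- select_patterns(mk_series(c(1, 3, 1, 0), 2), B, lab)
  expect_equal(ps$SA$frames, 2L)
  # [1,3,3,1] -> first frame of the plateau
  ps2 <- select_patterns(mk_series(c(1, 3, 3, 1), 2), B, lab)
  expect_equal(ps2$SA$frames, 2L)
  # random series agrees with the naive scan oracle
  set.seed(22)
  counts <- rpois(400, 3)
  B2 <- matrix(1L, 2, 400)
  lab2 <- rep("SA", 400)
  ps3 <- select_patterns(mk_series(counts, 4), B2, lab2)
  expect_equal(ps3$SA$frames, oracle_peaks(counts, 4))
  # frames labelled none are discarded
  lab3 <- rep("none", 4)
  expect_length(select_patterns(mk_series(c(1, 3, 1, 0), 2), B, lab3), 0)
})

test_that("mean coactivity averages counts at the selected peaks", {
  series <- structure(list(counts = c(1L, 4L, 1L, 6L, 1L), threshold = 2L,
                           alpha = 0.05, null = "pooled"),
                      class = "tecto_coactivity")
  B <- matrix(1L, 8, 5)
  ps <- select_patterns(series, B, rep("SA", 5))
  expect_equal(unname(mean_coactivity(series, ps)["SA"]), 5)   # (4 + 6) / 2
  expect_true(is.na(mean_coactivity(series, ps)["EA"]))
})

test_that("PCA dimensionality honours an exact constructed spectrum", {
  # data built so the sample covariance has eigenvalues 5, 3, 1, 1:
  # 5 + 3 = 8 of 10 reaches the 80% target with 2 components
  n <- 40
  set.seed(23)
  Z <- qr.Q(qr(scale(matrix(rnorm(n * 4), n, 4), scale = FALSE)))
  X <- Z %*% diag(sqrt(c(5, 3, 1, 1) * (n - 1))) %*% t(random_basis(4, 4, 2))
  ev <- eigen(cov(X), symmetric = TRUE)$values   # oracle check of construction
  expect_equal(ev, c(5, 3, 1, 1), tolerance = 1e-8)
  expect_equal(pca_dimensionality(t(X), seq_len(n)), 2L)
  # rank-1 data needs exactly one component
  u <- rnorm(6); v <- rnorm(30)
  expect_equal(pca_dimensionality(outer(u, v)), 1L)
  # dimension never exceeds min(frames - 1, neurons)
  y <- matrix(rnorm(8 * 5), 8, 5)
  expect_lte(pca_dimensionality(y, variance_fraction = 0.999), 4L)
  expect_error(pca_dimensionality(matrix(1, 3, 10)), "zero total variance")
})

test_that("cosine similarity handles the analytic cases", {
  expect_equal(epoch_cosine_similarity(cbind(c(1, 1, 0)), cbind(c(1, 0, 1))), 0.5)
  expect_equal(epoch_cosine_similarity(cbind(c(1, 1, 0)), cbind(c(1, 1, 0))), 1)
  expect_equal(epoch_cosine_similarity(cbind(c(1, 0, 0)), cbind(c(0, 1, 1))), 0)
  # mean over all cross pairs
  A <- cbind(c(1, 0), c(0, 1)); B <- cbind(c(1, 0))
  expect_equal(epoch_cosine_similarity(A, B), 0.5)
})

test_that("subspace bases are orthonormal and projectors idempotent", {
  p1 <- c(1, 0, 0, 0); p2 <- c(0, 1, 0, 0)
  sub <- build_subspace(cbind(p1, p2))
  expect_equal(sub$K, 2L)
  expect_equal(projection_matrix(sub), diag(c(1, 1, 0, 0)), tolerance = 1e-12)
  expect_equal(build_subspace(cbind(p1, p1))$K, 1L)
  set.seed(24)
  P <- matrix(rbinom(200, 1, 0.3), 20, 10)
  sub2 <- build_subspace(P)
  expect_equal(crossprod(sub2$U), diag(sub2$K), tolerance = 1e-10)
  Pm <- projection_matrix(sub2)
  expect_lt(max(abs(Pm %*% Pm - Pm)), 1e-8)
  expect_equal(Pm, t(Pm), tolerance = 1e-10)
  expect_lte(sub2$K, min(dim(P)))
  expect_error(build_subspace(matrix(0, 4, 2)), "zero")
})

test_that("unexplained fractions obey the analytic values and Pythagoras", {
  sub <- build_subspace(cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unexplained_fraction(c(2, -1, 0), sub), 0)
  expect_equal(unexplained_fraction(c(0, 0, 3), sub), 1)
  expect_equal(unexplained_fraction(rep(1, 3) / sqrt(3), sub), 1 / sqrt(3),
               tolerance = 1e-12)
  # Pythagoras on 1000 random patterns against a random subspace
  U <- random_basis(30, 6, seed = 25)
  sub2 <- structure(list(U = U, K = 6L), class = "tecto_subspace")
  Pm <- projection_matrix(sub2)
  set.seed(26)
  X <- matrix(rnorm(30 * 1000), 30, 1000)
  inside <- colSums((Pm %*% X)^2)
  outside <- colSums(((diag(30) - Pm) %*% X)^2)
  expect_lt(max(abs(inside + outside - colSums(X^2))), 1e-8)
  fr <- unexplained_fraction(X, sub2)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(unexplained_fraction(c(0, 0, 0), sub), "non-zero")
})

test_that("balanced projection reproduces analytic containment and mixing", {
  set.seed(27)
  n <- 20
  U <- random_basis(n, 3, seed = 28)
  mix <- function(k) {
    w <- matrix(rnorm(3 * k), 3, k)
    U %*% sweep(w, 2, sqrt(colSums(w^2)), "/")   # unit vectors inside span(U)
  }
  sets0 <- list(EA = list(epoch = "EA", patterns = mix(8)),
                SA = list(epoch = "SA", patterns = mix(8)),
                SE = list(epoch = "SE", patterns = mix(8)))
  class(sets0) <- "tecto_pattern_sets"
  res0 <- balanced_projection_analysis(sets0, n_select = 5, n_repeats = 20,
                                       seed = 2)
  expect_lt(max(res0$pairs$mean_unexplained), 1e-8)
  # EA = SA patterns plus a fixed orthogonal component of relative size beta
  beta <- 0.75
  extra <- (diag(n) - tcrossprod(U)) %*% rnorm(n)
  extra <- extra / sqrt(sum(extra^2))
  sa_pats <- mix(8)
  sets1 <- sets0
  sets1$SA$patterns <- sa_pats
  sets1$EA$patterns <- sa_pats + beta * extra %*% t(rep(1, 8))
  res1 <- balanced_projection_analysis(sets1, n_select = 5, n_repeats = 20,
                                       seed = 2)
  got <- res1$pairs$mean_unexplained[res1$pairs$target_epoch == "EA" &
                                     res1$pairs$subspace_epoch == "SA"]
  expect_equal(got, beta / sqrt(1 + beta^2), tolerance = 1e-6)
  # determinism
  res2 <- balanced_projection_analysis(sets1, n_select = 5, n_repeats = 20,
                                       seed = 2)
  expect_identical(res1, res2)
  expect_error(balanced_projection_analysis(sets1, n_select = 50), "lower n_select")
})

test_that("larger balanced selections never explain less on average", {
  set.seed(29)
  n <- 25
  mk <- function(k) matrix(rbinom(n * k, 1, 0.3), n, k)
  sets <- list(EA = list(epoch = "EA", patterns = mk(15)),
               SA = list(epoch = "SA", patterns = mk(15)),
               SE = list(epoch = "SE", patterns = mk(15)))
  class(sets) <- "tecto_pattern_sets"
  m <- vapply(c(4, 8, 12), function(k)
    mean(balanced_projection_analysis(sets, n_select = k, n_repeats = 30,
                                      seed = 3)$aggregate), numeric(1))
  expect_true(all(diff(m) <= 1e-9))
})
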