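#' Coactivity series and shuffle-derived significance threshold
#'
#' Counts coactive neurons per frame, then builds a null by shuffling each
#' neuron's active time bins uniformly (independently per row, per-neuron
#' count preserved) `n_shuffles` times. With the pooled-frames null (default)
#' the threshold is the largest count c such that the fraction of surrogate
#' frames with count > c is still >= alpha; equivalently, frames with count
#' strictly above the threshold fall in the pooled tail of probability
#' < alpha. The alternative `"max"` null compares against the
#' `(1 - alpha)` quantile of the per-surrogate maximum count.
#'
#' @param raster `tecto_raster` or 0/1 matrix (neurons x frames).
#' @param n_shuffles number of surrogates, default 500.
#' @param alpha significance level, default 0.05.
#' @param seed integer seed.
#' @param null `"pooled"` (default) or `"max"`.
#' @return list of class `tecto_coactivity` with `counts` (per frame),
#'   `threshold` (integer, >= 1), `alpha`, `null`.
#' @export
coactivity_threshold <- function(raster, n_shuffles = 500L, alpha = 0.05,
                                 seed = 1L, null = c("pooled", "max")) {
  null <- match.arg(null)
  B <- if (inherits(raster, "tecto_raster")) raster$B else as.matrix(raster)
  if (length(B) == 0L) stopf("raster is empty")
  n <- nrow(B); nt <- ncol(B)
  counts <- as.integer(colSums(B))
  k_per <- as.integer(rowSums(B))

  set.seed(seed)
  if (null == "pooled") {
    tail_ge <- integer(n + 2L)  # pooled frame count of surrogate counts >= c
    total <- 0L
    for (s in seq_len(n_shuffles)) {
      cnt <- integer(nt)
      for (i in seq_len(n)) {
        if (k_per[i] == 0L) next
        at <- sample.int(nt, k_per[i])
        cnt[at] <- cnt[at] + 1L
      }
      tb <- tabulate(cnt + 1L, nbins = n + 1L)  # tb[v+1] = #frames with count v
      tail_ge <- tail_ge + c(rev(cumsum(rev(tb))), 0L)
      total <- total + nt
    }
    frac_ge <- tail_ge / total
    # smallest c with tail fraction < alpha; threshold is c - 1
    c_sig <- which(frac_ge < alpha)[1L] - 1L   # count value (index offset 1)
    thr <- max(c_sig - 1L, 1L)
  } else {
    maxima <- integer(n_shuffles)
    for (s in seq_len(n_shuffles)) {
      cnt <- integer(nt)
      for (i in seq_len(n)) {
        if (k_per[i] == 0L) next
        at <- sample.int(nt, k_per[i])
        cnt[at] <- cnt[at] + 1L
      }
      maxima[s] <- max(cnt)
    }
    thr <- max(as.integer(stats::quantile(maxima, 1 - alpha, type = 1L)), 1L)
  }
  structure(list(counts = counts, threshold = as.integer(thr),
                 alpha = alpha, null = null),
            class = "tecto_coactivity")
}

#' Select high-coactivity patterns at significant peaks
#'
#' A pattern is the binary population vector at a frame that is a strict
#' local maximum of the coactivity series (a plateau contributes its first
#' frame) and whose count strictly exceeds the significance threshold.
#' Patterns are grouped by the epoch label of their frame; frames labelled
#' `none` are discarded.
#'
#' @param series `tecto_coactivity`.
#' @param raster `tecto_raster` or 0/1 matrix.
#' @param epochs `tecto_epochs` (or a character vector of labels).
#' @param use_dff optional dF/F matrix: when given, patterns carry dF/F
#'   values at the active entries instead of 1s.
#' @return list of class `tecto_pattern_sets`: one element per epoch present
#'   (`SA`, `EA`, `SE`), each with `epoch`, `patterns` (neurons x K matrix),
#'   `frames`, `threshold`.
#' @export
select_patterns <- function(series, raster, epochs, use_dff = NULL) {
  B <- if (inherits(raster, "tecto_raster")) raster$B else as.matrix(raster)
  labels <- if (inherits(epochs, "tecto_epochs")) epochs$labels else epochs
  counts <- series$counts
  peaks <- peak_frames(counts)
  peaks <- peaks[counts[peaks] > series$threshold]
  out <- list()
  for (ep in c("SA", "EA", "SE")) {
    fr <- peaks[labels[peaks] == ep]
    if (length(fr) == 0L) next
    pat <- B[, fr, drop = FALSE]
    if (!is.null(use_dff)) pat <- pat * as.matrix(use_dff)[, fr, drop = FALSE]
    out[[ep]] <- list(epoch = ep, patterns = pat, frames = fr,
                      threshold = series$threshold)
  }
  structure(out, class = "tecto_pattern_sets")
}

# strict local maxima of an integer series; plateaus give their first frame.
# A run qualifies when the previous distinct value is lower (or the run opens
# the series) and the next distinct value is lower (or the run closes it).
peak_frames <- function(counts) {
  r <- rle(as.numeric(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  prev_lower <- c(TRUE, r$values[-k] < r$values[-1L])
  next_lower <- c(r$values[-k] > r$values[-1L], TRUE)
  starts[prev_lower & next_lower]
}

#' Mean coactivity at selected pattern frames, per epoch
#'
#' @param series `tecto_coactivity`.
#' @param pattern_sets `tecto_pattern_sets` from [select_patterns()].
#' @return named numeric vector (one entry per epoch present); epochs with
#'   no pattern are NA.
#' @export
mean_coactivity <- function(series, pattern_sets) {
  out <- c(SA = NA_real_, EA = NA_real_, SE = NA_real_)
  for (ep in names(pattern_sets))
    out[ep] <- mean(series$counts[pattern_sets[[ep]]$frames])
  out
}

#' Number of principal components explaining a variance fraction
#'
#' Eigendecomposition of the mean-centred covariance of the epoch-restricted
#' dF/F frames; returns the smallest number of components whose cumulative
#' explained-variance fraction reaches `variance_fraction`.
#'
#' @param dff dF/F matrix or `tecto_dff`.
#' @param frames epoch frame indices (>= 2).
#' @param variance_fraction default 0.8.
#' @return integer.
#' @export
pca_dimensionality <- function(dff, frames = NULL, variance_fraction = 0.8) {
  if (inherits(dff, "tecto_dff")) dff <- dff$dff
  dff <- as.matrix(dff)
  if (is.null(frames)) frames <- seq_len(ncol(dff))
  if (length(frames) < 2L) stopf("need at least 2 frames")
  X <- t(dff[, frames, drop = FALSE])
  X <- sweep(X, 2L, colMeans(X))
  d <- svd(X, nu = 0L, nv = 0L)$d
  ev <- d^2
  if (sum(ev) <= 0) stopf("zero total variance on the epoch")
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= variance_fraction)[1L])
}

#' Mean cross-epoch cosine similarity between pattern sets
#'
#' @param set_a,set_b elements of a `tecto_pattern_sets` (lists with a
#'   `patterns` matrix) or plain matrices with patterns in columns.
#' @return mean cosine similarity over all cross-set pairs; zero vectors are
#'   excluded with a warning.
#' @export
epoch_cosine_similarity <- function(set_a, set_b) {
  A <- if (is.list(set_a)) set_a$patterns else as.matrix(set_a)
  B <- if (is.list(set_b)) set_b$patterns else as.matrix(set_b)
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    warnf("zero pattern vectors excluded from cosine similarity")
    A <- A[, na > 0, drop = FALSE]; B <- B[, nb > 0, drop = FALSE]
    na <- na[na > 0]; nb <- nb[nb > 0]
  }
  if (ncol(A) == 0L || ncol(B) == 0L) return(NA_real_)
  An <- sweep(A, 2L, na, "/"); Bn <- sweep(B, 2L, nb, "/")
  mean(crossprod(An, Bn))
}

#' Orthonormal basis of the subspace spanned by a pattern set
#'
#' @param patterns matrix with patterns in columns (or a pattern-set list).
#' @param tol relative singular-value tolerance for the numerical rank,
#'   default 1e-10.
#' @return list of class `tecto_subspace` with `U` (orthonormal columns) and
#'   `K` (dimension).
#' @export
build_subspace <- function(patterns, tol = 1e-10) {
  P <- if (is.list(patterns)) patterns$patterns else as.matrix(patterns)
  P <- P[, colSums(P^2) > 0, drop = FALSE]
  if (ncol(P) == 0L) stopf("all patterns are zero vectors")
  sv <- svd(P)
  K <- sum(sv$d > tol * sv$d[1L])
  structure(list(U = sv$u[, seq_len(K), drop = FALSE], K = K),
            class = "tecto_subspace")
}

#' Projection matrix of a subspace
#'
#' @param subspace a `tecto_subspace`.
#' @return `U %*% t(U)`.
#' @export
projection_matrix <- function(subspace) tcrossprod(subspace$U)

#' Fraction of a pattern orthogonal to a subspace
#'
#' `||(I - P) p|| / ||p||`, computed stably from the coordinates of `p` in
#' the orthonormal basis.
#'
#' @param p pattern vector (non-zero), or a matrix of patterns in columns.
#' @param subspace a `tecto_subspace`.
#' @return scalar (or vector, one per column) in `[0, 1]`.
#' @export
unexplained_fraction <- function(p, subspace) {
  P <- as.matrix(p)
  nrm2 <- colSums(P^2)
  if (any(nrm2 == 0)) stopf("pattern vector must be non-zero")
  inside2 <- colSums(crossprod(subspace$U, P)^2)
  out <- sqrt(pmax(0, 1 - inside2 / nrm2))
  if (is.vector(p)) out[[1L]] else out
}

#' Balanced subspace-projection analysis across epochs
#'
#' For each of `n_repeats` repeats, an equal number of patterns is selected
#' per epoch: uniformly without replacement from the SA and SE pools, and as
#' a consecutive run (uniform random start, no wrap) from the EA pool, so
#' the EA selection covers all presented stimuli with roughly similar
#' representation. A subspace is built from each epoch's selection, every
#' pattern of each *other* epoch's full pool is projected, and unexplained
#' fractions are averaged over patterns, then over repeats.
#'
#' @param sets `tecto_pattern_sets` containing `EA`, `SA`, `SE`.
#' @param n_select patterns per epoch; default the minimum pool size.
#' @param n_repeats default 200.
#' @param seed integer seed.
#' @return list with `pairs` (data.frame `target_epoch`, `subspace_epoch`,
#'   `mean_unexplained`), `aggregate` (named vector `1-P_EA`, `1-P_SA`,
#'   `1-P_SE`: mean unexplained fraction of the other two epochs' patterns
#'   under each subspace), `n_select`, `n_repeats`.
#' @export
balanced_projection_analysis <- function(sets, n_select = NULL,
                                         n_repeats = 200L, seed = 1L) {
  eps <- c("EA", "SA", "SE")
  if (!all(eps %in% names(sets)))
    stopf("pattern sets for EA, SA and SE are all required")
  pools <- lapply(sets[eps], `[[`, "patterns")
  sizes <- vapply(pools, ncol, integer(1))
  if (is.null(n_select)) n_select <- min(sizes)
  if (any(sizes < n_select))
    stopf("n_select = %d exceeds a pool size (%s); lower n_select",
          n_select, paste(sprintf("%s = %d", eps, sizes), collapse = ", "))

  set.seed(seed)
  pair_sum <- matrix(0, 3L, 3L, dimnames = list(eps, eps))   # target x subspace
  agg_sum <- stats::setNames(numeric(3L), eps)
  for (rep_i in seq_len(n_repeats)) {
    sel <- list(
      EA = { s <- sample.int(sizes["EA"] - n_select + 1L, 1L); s:(s + n_select - 1L) },
      SA = sample.int(sizes["SA"], n_select),
      SE = sample.int(sizes["SE"], n_select))
    sub <- lapply(eps, function(e) build_subspace(pools[[e]][, sel[[e]], drop = FALSE]))
    names(sub) <- eps
    for (e_sub in eps) {
      others <- setdiff(eps, e_sub)
      all_fracs <- c()
      for (e_tgt in others) {
        fr <- unexplained_fraction(pools[[e_tgt]], sub[[e_sub]])
        pair_sum[e_tgt, e_sub] <- pair_sum[e_tgt, e_sub] + mean(fr)
        all_fracs <- c(all_fracs, fr)
      }
      agg_sum[e_sub] <- agg_sum[e_sub] + mean(all_fracs)
    }
  }
  pair_mean <- pair_sum / n_repeats
  pairs <- expand.grid(target_epoch = eps, subspace_epoch = eps,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target_epoch != pairs$subspace_epoch, ]
  pairs$mean_unexplained <- mapply(function(t, s) pair_mean[t, s],
                                   pairs$target_epoch, pairs$subspace_epoch)
  rownames(pairs) <- NULL
  list(pairs = pairs,
       aggregate = stats::setNames(agg_sum / n_repeats,
                                   paste0("1-P_", eps)),
       n_select = n_select, n_repeats = n_repeats)
}
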