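#' Pairwise Pearson correlations on an epoch
#'
#' @param dff dF/F matrix (neurons x frames) or `tecto_dff`.
#' @param frames frame indices of the epoch (default: all frames).
#' @param epoch optional label stored with the result.
#' @return list of class `tecto_cor` with `r` (N x N), `mask` (NULL until
#'   [shift_null_mask()] fills it), `null_q95`, `epoch`. Zero-variance
#'   neurons get NA rows/columns and are excluded downstream.
#' @export
pairwise_correlations <- function(dff, frames = NULL, epoch = NA_character_) {
  if (inherits(dff, "tecto_dff")) dff <- dff$dff
  dff <- as.matrix(dff)
  if (is.null(frames)) frames <- seq_len(ncol(dff))
  if (length(frames) < 2L) stopf("need at least 2 frames in the epoch")
  x <- dff[, frames, drop = FALSE]
  sdv <- apply(x, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(x)))
  r[sdv == 0, ] <- NA_real_
  r[, sdv == 0] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, mask = NULL, null_q95 = NA_real_, epoch = epoch),
            class = "tecto_cor")
}

#' SHIFT-null significance mask for pairwise correlations
#'
#' Builds a null distribution by circularly time-shifting each neuron's trace
#' by an independent uniform offset (at least one frame), recomputing all
#' pairwise correlations for each surrogate, and pooling them. Pairs whose
#' observed correlation exceeds the pooled 95th percentile are flagged
#' significant (one-sided, positive correlations).
#'
#' @param dff dF/F matrix or `tecto_dff`.
#' @param frames epoch frame indices (default all); must contain >= 10
#'   frames.
#' @param n_shuffles number of surrogates (>= 20), default 1000.
#' @param seed integer seed.
#' @param alpha tail probability, default 0.05.
#' @param epoch optional label stored with the result.
#' @return `tecto_cor` with `mask` and `null_q95` set.
#' @export
shift_null_mask <- function(dff, frames = NULL, n_shuffles = 1000L, seed = 1L,
                            alpha = 0.05, epoch = NA_character_) {
  if (inherits(dff, "tecto_dff")) dff <- dff$dff
  dff <- as.matrix(dff)
  if (is.null(frames)) frames <- seq_len(ncol(dff))
  if (length(frames) < 10L) stopf("epoch must contain at least 10 frames")
  if (n_shuffles < 20L) stopf("n_shuffles must be >= 20 for a stable percentile")
  res <- pairwise_correlations(dff, frames, epoch)
  x <- dff[, frames, drop = FALSE]
  n <- nrow(x); nt <- ncol(x)
  keep <- which(apply(x, 1L, stats::sd) > 0)
  ut <- upper.tri(matrix(0, length(keep), length(keep)))

  set.seed(seed)
  null_pool <- vector("list", n_shuffles)
  xs <- x[keep, , drop = FALSE]
  for (s in seq_len(n_shuffles)) {
    offs <- sample.int(nt - 1L, length(keep), replace = TRUE)
    shifted <- xs
    for (i in seq_along(keep)) shifted[i, ] <- circshift(xs[i, ], offs[i])
    rs <- stats::cor(t(shifted))
    null_pool[[s]] <- rs[ut]
  }
  q95 <- stats::quantile(unlist(null_pool), 1 - alpha, names = FALSE)

  mask <- res$r > q95
  mask[is.na(mask)] <- FALSE
  diag(mask) <- FALSE
  res$mask <- mask
  res$null_q95 <- q95
  res
}

#' Distance-binned profile of significant correlations
#'
#' Bins neuron pairs by Euclidean distance (half-open bins `[lo, hi)`) and
#' averages the correlation over significant pairs in each bin.
#'
#' @param result a `tecto_cor` with mask set (if the mask is NULL, all pairs
#'   are used).
#' @param positions data.frame with `x_um`, `y_um` for every neuron.
#' @param bin_width_um bin width, default 50.
#' @param bin_edges_um optional explicit edges (overrides `bin_width_um`).
#' @return data.frame with `bin_lo_um`, `bin_hi_um`, `mean_r`, `n_pairs`;
#'   empty bins have `mean_r = NA`.
#' @export
distance_binned_profile <- function(result, positions, bin_width_um = 50,
                                    bin_edges_um = NULL) {
  r <- result$r
  n <- nrow(r)
  if (nrow(positions) != n) stopf("positions must have one row per neuron")
  D <- as.matrix(stats::dist(positions[, c("x_um", "y_um")]))
  ut <- upper.tri(r)
  sel <- ut & !is.na(r)
  if (!is.null(result$mask)) sel <- sel & result$mask
  d <- D[sel]; rv <- r[sel]
  if (is.null(bin_edges_um)) {
    top <- max(D[ut])
    bin_edges_um <- seq(0, top + bin_width_um, by = bin_width_um)
  }
  k <- length(bin_edges_um) - 1L
  idx <- findInterval(d, bin_edges_um, rightmost.closed = FALSE)
  mean_r <- rep(NA_real_, k); n_pairs <- integer(k)
  for (b in seq_len(k)) {
    in_b <- idx == b
    n_pairs[b] <- sum(in_b)
    if (n_pairs[b] > 0) mean_r[b] <- mean(rv[in_b])
  }
  data.frame(bin_lo_um = bin_edges_um[-(k + 1L)], bin_hi_um = bin_edges_um[-1L],
             mean_r = mean_r, n_pairs = n_pairs)
}

#' Similarity between two correlation matrices
#'
#' Pearson correlation between the vectorized upper triangles (diagonal
#' excluded) of two correlation matrices over the same neuron set.
#'
#' @param result_a,result_b `tecto_cor` objects (or plain matrices) of equal
#'   dimension.
#' @param significant_only if TRUE, restrict to pairs significant in both.
#' @return scalar in `[-1, 1]`.
#' @export
matrix_similarity <- function(result_a, result_b, significant_only = FALSE) {
  ra <- if (inherits(result_a, "tecto_cor")) result_a$r else as.matrix(result_a)
  rb <- if (inherits(result_b, "tecto_cor")) result_b$r else as.matrix(result_b)
  if (!all(dim(ra) == dim(rb)))
    stopf("correlation matrices must cover the same neuron set")
  sel <- upper.tri(ra) & !is.na(ra) & !is.na(rb)
  if (significant_only) {
    if (is.null(result_a$mask) || is.null(result_b$mask))
      stopf("significant_only requires masks on both results")
    sel <- sel & result_a$mask & result_b$mask
  }
  stats::cor(ra[sel], rb[sel])
}
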