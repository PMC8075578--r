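#' Fit the anterior-posterior axis from a neuropil contour
#'
#' Fits an ellipse to the contour points by direct least squares (Halir &
#' Flusser's numerically stable formulation of the Fitzgibbon method). The
#' major axis defines the anterior-posterior (AP) axis; positions project
#' onto it and rescale linearly so the span of the major axis maps to
#' `[0, 1]`. By default the anterior end (0) is the axis endpoint nearer the
#' coordinate origin; set `anterior` to `"far"` to flip.
#'
#' @param contour two-column matrix of contour points (>= 6, non-collinear).
#' @param anterior `"near"` (default) or `"far"`: which axis endpoint is
#'   anterior.
#' @return list of class `tecto_ap_axis` with `centre`, `semi_axes`
#'   (major, minor), `angle_rad`, `u` (unit vector, anterior to posterior).
#' @export
fit_ap_axis <- function(contour, anterior = c("near", "far")) {
  anterior <- match.arg(anterior)
  contour <- as.matrix(contour)
  if (nrow(contour) < 6L) stopf("need at least 6 contour points")
  x <- contour[, 1]; y <- contour[, 2]
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  D1 <- cbind(xc^2, xc * yc, yc^2)
  D2 <- cbind(xc, yc, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (abs(det(S3)) < 1e-12) stopf("degenerate (collinear) contour")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0L) stopf("ellipse fit failed (no valid eigenvector)")
  a1 <- V[, idx[1]]
  coefs <- c(a1, Tm %*% a1)     # A B C D E F in centred coordinates
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  Dd <- coefs[4]; E <- coefs[5]; Ff <- coefs[6]
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2L, 2L), c(-Dd, -E))
  Fc <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    Dd * ctr[1] + E * ctr[2] + Ff
  Mq <- matrix(c(A, B / 2, B / 2, C), 2L, 2L)
  eq <- eigen(Mq, symmetric = TRUE)
  ax <- sqrt(-Fc / eq$values)          # semi-axes; larger first when values ascend
  ord <- order(ax, decreasing = TRUE)
  semi <- ax[ord]
  u <- eq$vectors[, ord[1]]
  u <- u / sqrt(sum(u^2))
  centre <- ctr + c(mx, my)
  ends <- rbind(centre - semi[1] * u, centre + semi[1] * u)
  d <- sqrt(rowSums(ends^2))
  flip <- if (anterior == "near") d[1] > d[2] else d[1] < d[2]
  if (flip) u <- -u
  structure(list(centre = centre, semi_axes = semi,
                 angle_rad = atan2(u[2], u[1]) %% pi, u = u),
            class = "tecto_ap_axis")
}

#' Project positions onto the AP axis
#'
#' @param ap_axis a `tecto_ap_axis`.
#' @param xy two-column matrix (or data.frame with `x_um`, `y_um`).
#' @param clamp_unit clamp the result into `[0, 1]` (default TRUE).
#' @return numeric vector: 0 = anterior end, 1 = posterior end of the fitted
#'   major axis.
#' @export
project_ap <- function(ap_axis, xy, clamp_unit = TRUE) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x_um", "y_um")])
  xy <- matrix(as.numeric(xy), ncol = 2L)
  t <- ((xy[, 1] - ap_axis$centre[1]) * ap_axis$u[1] +
        (xy[, 2] - ap_axis$centre[2]) * ap_axis$u[2] + ap_axis$semi_axes[1]) /
    (2 * ap_axis$semi_axes[1])
  if (clamp_unit) t <- clamp(t, 0, 1)
  t
}

#' Detect recurring coactive assemblies on an epoch
#'
#' Baseline detector: build the graph whose edges are the SHIFT-significant,
#' positively correlated neuron pairs on the epoch, then partition it by
#' modularity-maximizing (Louvain) community detection; communities smaller
#' than `min_size` are discarded. The detector is pluggable: pass a function
#' `function(graph) -> membership vector` to substitute another algorithm
#' (for example, the full graph-theoretic detector of earlier work on tectal
#' assemblies).
#'
#' Membership requires significant coactivation with at least `min_degree`
#' other members: after partitioning, neurons with fewer within-community
#' edges are pruned iteratively, which removes stragglers attached to an
#' assembly by a single spurious edge.
#'
#' @param activity dF/F matrix or `tecto_dff` (binary rasters also work).
#' @param frames epoch frame indices (>= 50).
#' @param detector `"graph-community"` or a function of an igraph graph.
#' @param min_size minimum assembly size, default 5.
#' @param min_degree minimum within-community degree of a member, default 2.
#' @param n_shuffles surrogates for the SHIFT mask, default 200.
#' @param seed integer seed (significance null and community detection).
#' @param corr optional precomputed `tecto_cor` with mask (skips the SHIFT
#'   step).
#' @param epoch label stored on each assembly.
#' @return list of class `tecto_assemblies`; each element has `members` and
#'   `epoch`.
#' @export
detect_assemblies <- function(activity, frames, detector = "graph-community",
                              min_size = 5L, min_degree = 2L,
                              n_shuffles = 200L, seed = 1L,
                              corr = NULL, epoch = NA_character_) {
  if (length(frames) < 50L) stopf("epoch must contain at least 50 frames")
  if (is.null(corr))
    corr <- shift_null_mask(activity, frames, n_shuffles = n_shuffles,
                            seed = seed, epoch = epoch)
  adj <- corr$mask & !is.na(corr$r) & corr$r > 0
  w <- corr$r * adj
  w[is.na(w)] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L)
    return(structure(list(), class = "tecto_assemblies"))
  membership <- if (is.function(detector)) {
    detector(g)
  } else {
    set.seed(seed)
    igraph::membership(igraph::cluster_louvain(g))
  }
  A <- (w > 0)
  out <- list()
  for (cm in sort(unique(membership))) {
    members <- sort(which(membership == cm))
    # prune weakly attached members: each needs enough in-community edges
    # and a within-community correlation mass comparable to the rest of the
    # community (spurious edges are individually weak)
    repeat {
      if (length(members) == 0L) break
      deg <- rowSums(A[members, members, drop = FALSE])
      wdeg <- rowSums(w[members, members, drop = FALSE])
      drop <- deg < min_degree | wdeg < 0.1 * stats::median(wdeg)
      if (!any(drop) || all(drop)) break
      members <- members[!drop]
    }
    if (length(members) >= min_size)
      out[[length(out) + 1L]] <- list(members = members, epoch = epoch)
  }
  structure(out, class = "tecto_assemblies")
}

#' Fill in spatial and tuning statistics for assemblies
#'
#' Computes for each assembly: the centre of mass, its projection on the AP
#' axis (in `[0, 1]`), the spatial coverage (convex-hull area of the members
#' divided by the hull area of all recorded cells), and --- over selective
#' members only --- the mean and sample variance of the preferred stimulus.
#'
#' @param assemblies `tecto_assemblies` (or a single assembly list).
#' @param positions data.frame `neuron_id`, `x_um`, `y_um` for all neurons.
#' @param ap_axis a `tecto_ap_axis`.
#' @param tuning optional data.frame from [fit_tuning()].
#' @return data.frame, one row per assembly: `epoch`, `n_members`, `com_x_um`,
#'   `com_y_um`, `com_ap`, `coverage`, `mean_tuning_deg`,
#'   `tuning_variance_deg2`, plus a `members` list-column.
#' @export
assembly_statistics <- function(assemblies, positions, ap_axis, tuning = NULL) {
  xy_all <- as.matrix(positions[, c("x_um", "y_um")])
  hull_all <- convex_hull_area(xy_all)
  rows <- lapply(assemblies, function(a) {
    xy <- xy_all[a$members, , drop = FALSE]
    com <- colMeans(xy)
    cov_frac <- if (length(a$members) >= 3L && !is.na(hull_all) && hull_all > 0)
      convex_hull_area(xy) / hull_all else NA_real_
    mt <- vt <- NA_real_
    if (!is.null(tuning)) {
      sel <- intersect(a$members, select_tuned(tuning))
      if (length(sel) >= 2L) {
        pv <- tuning$preferred_deg[sel]
        mt <- mean(pv); vt <- stats::var(pv)
      }
    }
    data.frame(epoch = a$epoch, n_members = length(a$members),
               com_x_um = com[1], com_y_um = com[2],
               com_ap = project_ap(ap_axis, matrix(com, ncol = 2L)),
               coverage = cov_frac, mean_tuning_deg = mt,
               tuning_variance_deg2 = vt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$members <- lapply(assemblies, `[[`, "members")
  out
}

#' Mean membership overlap between two assembly sets
#'
#' `overlap(A, B) = |A intersect B| / min(|A|, |B|)` (or Jaccard); each
#' assembly in `set_a` is matched to its best partner in `set_b` and the
#' maxima are averaged over `set_a`.
#'
#' @param set_a,set_b `tecto_assemblies` (typically evoked and spontaneous).
#' @param method `"min"` (default; normalize by the smaller assembly) or
#'   `"jaccard"`.
#' @return mean best-match overlap in `[0, 1]`, or NA if either set is
#'   empty.
#' @export
assembly_overlap <- function(set_a, set_b, method = c("min", "jaccard")) {
  method <- match.arg(method)
  if (length(set_a) == 0L || length(set_b) == 0L) return(NA_real_)
  best <- vapply(set_a, function(a) {
    max(vapply(set_b, function(b) {
      inter <- length(intersect(a$members, b$members))
      if (method == "min") inter / min(length(a$members), length(b$members))
      else inter / length(union(a$members, b$members))
    }, numeric(1)))
  }, numeric(1))
  mean(best)
}

# best-match Jaccard of detected vs true memberships (recovery diagnostics)
membership_jaccard <- function(detected, truth) {
  if (length(detected) == 0L || length(truth) == 0L) return(NA_real_)
  det <- lapply(detected, function(a) if (is.list(a)) a$members else a)
  mean(vapply(truth, function(tr) {
    max(vapply(det, function(d)
      length(intersect(d, tr)) / length(union(d, tr)), numeric(1)))
  }, numeric(1)))
}
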