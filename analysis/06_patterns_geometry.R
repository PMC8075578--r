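#!/usr/bin/env Rscript
# High-coactivity patterns and their geometry: shuffle-calibrated coactivity
# threshold, pattern selection at significant peaks, per-epoch mean
# coactivity, PCA dimensionality at 80% variance, cross-epoch cosine
# similarity, and the balanced subspace-projection analysis (equal pattern
# counts per epoch, consecutive EA runs, 200 resamples).
#
# Writes results/<name>_geometry.csv and results/<name>_projection_pairs.csv.

suppressMessages(library(tectodyn))

for (name in c("convergent", "divergent")) {
  d <- read_dataset(file.path("results/datasets", name))
  ep <- segment_epochs(d$stimulus_log, d$frame_rate_hz, ncol(d$traces),
                       d$sa_end_frame)
  r <- binarize(d$traces)
  co <- coactivity_threshold(r, n_shuffles = 500, seed = 61)
  ps <- select_patterns(co, r, ep)
  mc <- mean_coactivity(co, ps)
  k80 <- vapply(c(SA = "SA", EA = "EA", SE = "SE"), function(e)
    pca_dimensionality(d$traces, epoch_frames(ep, e)), integer(1))
  cosines <- c(EA_SA = epoch_cosine_similarity(ps$EA, ps$SA),
               EA_SE = epoch_cosine_similarity(ps$EA, ps$SE),
               SA_SE = epoch_cosine_similarity(ps$SA, ps$SE))
  bp <- balanced_projection_analysis(ps, n_repeats = 200, seed = 62)
  write.csv(bp$pairs, sprintf("results/%s_projection_pairs.csv", name),
            row.names = FALSE)
  write.csv(data.frame(
    metric = c("coactivity_threshold",
               paste0("mean_coactivity_", names(mc)),
               paste0("k80_", names(k80)),
               paste0("cosine_", names(cosines)),
               names(bp$aggregate)),
    value = c(co$threshold, mc, k80, cosines, bp$aggregate)),
    sprintf("results/%s_geometry.csv", name), row.names = FALSE)
  cat(sprintf("%s: threshold=%d; mean coactivity EA=%.1f SA=%.1f; K80 EA=%d SA=%d; cosine EA-SA=%.3f; 1-P_SA=%.3f\n",
              name, co$threshold, mc["EA"], mc["SA"], k80["EA"], k80["SA"],
              cosines["EA_SA"], bp$aggregate["1-P_SA"]))
}
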