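#!/usr/bin/env Rscript
# Assembly analysis: detect recurring coactive groups separately in SA and
# TEA (graph of SHIFT-significant positive correlations partitioned by
# Louvain communities), then compute the per-assembly statistics behind the
# developmental comparisons: size, centre of mass on the anterior-posterior
# axis (from the ellipse fitted to the neuropil contour), spatial coverage,
# tuning mean/variance, and the TEA-SA membership overlap.
#
# Writes results/<name>_assemblies.csv.

suppressMessages(library(tectodyn))

for (name in c("convergent", "divergent")) {
  d <- read_dataset(file.path("results/datasets", name))
  ep <- segment_epochs(d$stimulus_log, d$frame_rate_hz, ncol(d$traces),
                       d$sa_end_frame)
  tun <- fit_tuning(d$traces, d$stimulus_log)
  ax <- fit_ap_axis(d$neuropil_contour)
  asm <- list(
    SA = detect_assemblies(d$traces, epoch_frames(ep, "SA"),
                           n_shuffles = 200, seed = 51, epoch = "SA"),
    TEA = detect_assemblies(d$traces, epoch_frames(ep, "TEA"),
                            n_shuffles = 200, seed = 52, epoch = "TEA"))
  tabs <- lapply(asm, function(a)
    if (length(a)) assembly_statistics(a, d$positions, ax, tun) else NULL)
  tab <- do.call(rbind, tabs)
  tab$members <- vapply(tab$members, paste, character(1), collapse = ";")
  write.csv(tab, sprintf("results/%s_assemblies.csv", name), row.names = FALSE)
  jac <- tectodyn:::membership_jaccard(asm$SA,
                                       d$ground_truth$sa_assembly_membership)
  cat(sprintf("%s: %d SA + %d TEA assemblies; SA recovery Jaccard %.2f; TEA-SA overlap %.2f\n",
              name, length(asm$SA), length(asm$TEA), jac,
              assembly_overlap(asm$TEA, asm$SA)))
}
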