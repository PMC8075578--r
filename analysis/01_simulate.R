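#!/usr/bin/env Rscript
# Generate the two synthetic recordings used throughout the analysis: a
# "convergent" fish whose evoked ensembles share half their members with the
# spontaneous assemblies, and a "divergent" fish whose ensembles are disjoint
# from them. Both follow the standard protocol shape (dark spontaneous epoch,
# then trials of nine spots at 45-165 degrees), scaled down to desk size:
# ~6.7 min of spontaneous activity and 5 trials at 2.2 Hz.
#
# Writes results/datasets/<name>/ (traces, positions, stimulus log, ground
# truth) for the downstream scripts.

suppressMessages(library(tectodyn))

out_root <- "results/datasets"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

base <- function(overlap, seed) simulation_config(
  n_neurons = 80, sa_duration_s = 400, n_trials = 5, noise_sd = 0.03,
  assembly_event_rate_hz = 0.03, ea_sa_overlap = overlap, seed = seed)

configs <- list(convergent = base(0.5, 9), divergent = base(0, 109))

for (name in names(configs)) {
  d <- generate_dataset(configs[[name]])
  write_dataset(d, file.path(out_root, name))
  cat(sprintf("%s: %d neurons x %d frames, %d presentations, SA ends at frame %d\n",
              name, nrow(d$traces), ncol(d$traces), nrow(d$stimulus_log),
              d$sa_end_frame))
}
cat("datasets written under", out_root, "\n")
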