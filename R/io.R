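#' Write a synthetic dataset to plain-text files
#'
#' Writes `traces.csv` (neurons x frames, header row of frame times in
#' seconds), `positions.csv`, `stimulus_log.csv` and `ground_truth.json`
#' into a directory.
#'
#' @param dataset a `tecto_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nt <- ncol(dataset$traces)
  times <- (seq_len(nt) - 1L) / dataset$frame_rate_hz
  tr <- as.data.frame(dataset$traces)
  names(tr) <- sprintf("t%.6f", times)
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(dataset$positions, file.path(dir, "positions.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$stimulus_log, file.path(dir, "stimulus_log.csv"),
                   row.names = FALSE)
  gt <- dataset$ground_truth
  meta <- list(frame_rate_hz = dataset$frame_rate_hz,
               sa_end_frame = dataset$sa_end_frame,
               neuropil_contour = dataset$neuropil_contour,
               ground_truth = gt)
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files.
#' @return a `tecto_dataset` (config slot is NULL for data read from disk).
#' @export
read_dataset <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  traces <- unname(as.matrix(tr))
  positions <- utils::read.csv(file.path(dir, "positions.csv"))
  stim <- utils::read.csv(file.path(dir, "stimulus_log.csv"))
  meta <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  gt <- meta$ground_truth
  # equal-length membership lists come back simplified to a matrix; ragged
  # ones as a list of arrays -- normalise both to a list of integer vectors
  for (f in c("sa_assembly_membership", "ea_ensemble_membership")) {
    m <- gt[[f]]
    if (is.null(m)) next
    gt[[f]] <- if (is.matrix(m)) lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
    else lapply(m, as.integer)
  }
  structure(list(
    traces = traces, positions = positions,
    neuropil_contour = as.matrix(meta$neuropil_contour),
    stimulus_log = stim, frame_rate_hz = meta$frame_rate_hz,
    sa_end_frame = meta$sa_end_frame, ground_truth = gt, config = NULL),
    class = "tecto_dataset")
}
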