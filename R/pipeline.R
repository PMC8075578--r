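#' Run the full analysis pipeline on one recording
#'
#' Orchestrates every stage in dependency order: epoch segmentation,
#' correlation structure (with SHIFT-null significance, distance profiles
#' and SA-vs-TEA matrix similarity), tuning-curve fits, assembly detection
#' and statistics on SA and TEA, binarization, the coactivity threshold,
#' pattern selection, per-epoch mean coactivity, PCA dimensionality,
#' cross-epoch cosine similarities, and the balanced subspace-projection
#' analysis. Re-running with an identical config and seed reproduces every
#' numeric output exactly.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{simulate}{a [simulation_config()]; ignored when `dataset` is
#'       given.}
#'     \item{dataset}{optionally, a ready `tecto_dataset` (user data).}
#'     \item{seed}{integer seed for every stochastic stage.}
#'     \item{n_shuffles_corr}{SHIFT surrogates, default 1000.}
#'     \item{n_shuffles_coactivity}{row shuffles, default 500.}
#'     \item{n_repeats_projection}{balanced resampling repeats, default 200.}
#'     \item{min_assembly_size}{default 5.}
#'     \item{n_select}{patterns per epoch for the projection analysis;
#'       default the minimum pool size.}
#'     \item{match_sa_length}{when TRUE, truncate SA to the EA frame count
#'       before pattern selection (matched-length control).}
#'     \item{out_dir}{optional; when set, the report and per-stage tables
#'       are written there.}
#'   }
#' @return list of class `tecto_report` with the metric families plus
#'   `seed`, `config_hash` and `version`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(seed = 1L, n_shuffles_corr = 1000L,
                   n_shuffles_coactivity = 500L, n_repeats_projection = 200L,
                   min_assembly_size = 5L, n_select = NULL,
                   match_sa_length = FALSE, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  seed <- config$seed

  dataset <- if (!is.null(config$dataset)) config$dataset
  else generate_dataset(config$simulate)
  dff <- dataset$traces
  nt <- ncol(dff)

  epochs <- segment_epochs(dataset$stimulus_log, dataset$frame_rate_hz, nt,
                           dataset$sa_end_frame)
  fr <- list(SA = epoch_frames(epochs, "SA"), EA = epoch_frames(epochs, "EA"),
             SE = epoch_frames(epochs, "SE"), TEA = epoch_frames(epochs, "TEA"))

  # correlation structure: SA vs TEA
  cors <- list(
    SA = shift_null_mask(dff, fr$SA, n_shuffles = config$n_shuffles_corr,
                         seed = stage_seed(seed, "corr-SA"), epoch = "SA"),
    TEA = shift_null_mask(dff, fr$TEA, n_shuffles = config$n_shuffles_corr,
                          seed = stage_seed(seed, "corr-TEA"), epoch = "TEA"))
  profiles <- lapply(cors, distance_binned_profile, positions = dataset$positions)
  mat_sim <- matrix_similarity(cors$TEA, cors$SA)

  tuning <- fit_tuning(dff, dataset$stimulus_log)

  ap <- fit_ap_axis(dataset$neuropil_contour)
  assemblies <- list(
    SA = detect_assemblies(dff, fr$SA, min_size = config$min_assembly_size,
                           seed = stage_seed(seed, "asm-SA"), corr = cors$SA,
                           epoch = "SA"),
    TEA = detect_assemblies(dff, fr$TEA, min_size = config$min_assembly_size,
                            seed = stage_seed(seed, "asm-TEA"),
                            corr = cors$TEA, epoch = "TEA"))
  asm_tables <- lapply(assemblies, function(a)
    if (length(a) > 0) assembly_statistics(a, dataset$positions, ap, tuning)
    else NULL)
  overlap <- assembly_overlap(assemblies$TEA, assemblies$SA)

  # coactivity patterns and geometry
  raster <- binarize(dff)
  labels_used <- epochs
  if (isTRUE(config$match_sa_length) && length(fr$SA) > length(fr$EA)) {
    trunc <- fr$SA[seq_len(length(fr$SA) - length(fr$EA))]
    labels_used$labels[trunc] <- "none"
  }
  coact <- coactivity_threshold(raster,
                                n_shuffles = config$n_shuffles_coactivity,
                                seed = stage_seed(seed, "coactivity"))
  patterns <- select_patterns(coact, raster, labels_used)
  coact_means <- mean_coactivity(coact, patterns)

  k80 <- vapply(c(SA = "SA", EA = "EA", SE = "SE"), function(e)
    if (length(fr[[e]]) >= 2L) pca_dimensionality(dff, fr[[e]]) else NA_integer_,
    integer(1))

  cosines <- c(EA_SA = NA_real_, EA_SE = NA_real_, SA_SE = NA_real_)
  if (!is.null(patterns$EA) && !is.null(patterns$SA))
    cosines["EA_SA"] <- epoch_cosine_similarity(patterns$EA, patterns$SA)
  if (!is.null(patterns$EA) && !is.null(patterns$SE))
    cosines["EA_SE"] <- epoch_cosine_similarity(patterns$EA, patterns$SE)
  if (!is.null(patterns$SA) && !is.null(patterns$SE))
    cosines["SA_SE"] <- epoch_cosine_similarity(patterns$SA, patterns$SE)

  projection <- NULL
  if (all(c("EA", "SA", "SE") %in% names(patterns))) {
    sizes <- vapply(patterns[c("EA", "SA", "SE")],
                    function(p) ncol(p$patterns), integer(1))
    n_sel <- if (is.null(config$n_select)) min(sizes) else config$n_select
    if (n_sel >= 1L && all(sizes >= n_sel))
      projection <- balanced_projection_analysis(
        patterns, n_select = n_sel,
        n_repeats = config$n_repeats_projection,
        seed = stage_seed(seed, "projection"))
  }

  cfg_for_hash <- config[setdiff(names(config), c("dataset", "out_dir"))]
  report <- structure(list(
    n_neurons = nrow(dff), n_frames = nt,
    epoch_frame_counts = vapply(fr, length, integer(1)),
    distance_profiles = profiles,
    matrix_similarity_tea_sa = mat_sim,
    tuning = tuning,
    n_selective = length(select_tuned(tuning)),
    assembly_tables = asm_tables,
    assembly_overlap_tea_sa = overlap,
    coactivity_threshold = coact$threshold,
    mean_coactivity = coact_means,
    n_patterns = vapply(patterns, function(p) ncol(p$patterns), integer(1)),
    k80 = k80,
    cosine_similarity = cosines,
    projection = projection,
    seed = seed,
    config_hash = fnv1a_hex(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE,
                                             digits = 10, force = TRUE)),
    version = as.character(utils::packageVersion("tectodyn"))),
    class = "tecto_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report as JSON plus per-table CSVs
#'
#' @param report a `tecto_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$tuning, file.path(dir, "tuning.csv"), row.names = FALSE)
  for (ep in names(report$assembly_tables)) {
    tb <- report$assembly_tables[[ep]]
    if (is.null(tb)) next
    tb$members <- vapply(tb$members, paste, character(1), collapse = ";")
    utils::write.csv(tb, file.path(dir, sprintf("assemblies_%s.csv", ep)),
                     row.names = FALSE)
  }
  for (ep in names(report$distance_profiles))
    utils::write.csv(report$distance_profiles[[ep]],
                     file.path(dir, sprintf("correlation_profile_%s.csv", ep)),
                     row.names = FALSE)
  if (!is.null(report$projection))
    utils::write.csv(report$projection$pairs,
                     file.path(dir, "projection_pairs.csv"), row.names = FALSE)
  slim <- report[c("n_neurons", "n_frames", "epoch_frame_counts",
                   "matrix_similarity_tea_sa", "n_selective",
                   "assembly_overlap_tea_sa", "coactivity_threshold",
                   "mean_coactivity", "n_patterns", "k80",
                   "cosine_similarity", "seed", "config_hash", "version")]
  if (!is.null(report$projection))
    slim$projection_aggregate <- as.list(report$projection$aggregate)
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.tecto_report <- function(x, ...) {
  cat(sprintf("<tecto_report> %d neurons, %d frames (seed %d, config %s)\n",
              x$n_neurons, x$n_frames, x$seed, x$config_hash))
  cat(sprintf("  TEA-SA matrix similarity: %.3f; assembly overlap: %.3f\n",
              x$matrix_similarity_tea_sa, x$assembly_overlap_tea_sa))
  cat("  K80:", paste(names(x$k80), x$k80, sep = "=", collapse = " "), "\n")
  cat("  cosine:", paste(names(x$cosine_similarity),
                         round(x$cosine_similarity, 3), sep = "=", collapse = " "), "\n")
  if (!is.null(x$projection))
    cat("  ", paste(names(x$projection$aggregate),
                    round(x$projection$aggregate, 3), sep = "=", collapse = " "), "\n")
  invisible(x)
}
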