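# The reference beam-time study: per-scan bookkeeping of the coarse scans
# the simulator emulates (sample type, scan grid, dwell time, extracted
# region and cell counts), and a generator that reproduces the study
# in silico.

#' Bookkeeping table of the reference coarse-scan study
#'
#' One row per coarse scan of the reference beam-time study: scans 1-3
#' contain only healthy (type A) cells, scans 4-5 only ethanol-poisoned
#' (type B) cells — together 81 A + 25 B = 106 extracted cells — and scans
#' 6-8 rescan one azide/copper-treated (type C) area at decreasing dwell
#' times. `n_regions` counts connected components before artifact
#' rejection, `n_cells` the cells kept afterwards.
#'
#' @return data.frame with columns `scan_index`, `sample_type`, `rows`,
#'   `cols`, `dwell_time_ms`, `n_regions`, `n_cells`.
#' @export
reference_study <- function() {
  path <- system.file("extdata", "reference_study_scans.csv",
                      package = "xrfroi", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate the reference study's coarse scans
#'
#' Generates one synthetic scan per requested study row, matching that
#' row's grid size, dwell time, sample type and extracted-cell count, and
#' planting `n_regions - n_cells` speckle artifacts.
#'
#' @param seed Integer master seed; each scan gets a derived child seed.
#' @param scans Study rows to simulate (default the five A/B scans).
#' @param profiles Intensity profiles, see [default_profiles()].
#' @return List with `map_sets` and `ground_truths` (both named
#'   `scan<index>`), and `study` (the selected bookkeeping rows).
#' @export
simulate_reference_study <- function(seed = 1, scans = 1:5,
                                     profiles = default_profiles()) {
  study <- reference_study()
  study <- study[match(scans, study$scan_index), , drop = FALSE]
  if (anyNA(study$scan_index)) stopf("unknown study scan index")
  seeds <- derive_seeds(seed, nrow(study))
  map_sets <- list(); ground_truths <- list()
  for (i in seq_len(nrow(study))) {
    row <- study[i, ]
    n_cells <- stats::setNames(row$n_cells, row$sample_type)
    sim <- generate_scan(
      shape = c(row$rows, row$cols),
      n_cells_by_type = n_cells,
      dwell_time = row$dwell_time_ms,
      profiles = profiles,
      artifact_count = max(0L, row$n_regions - row$n_cells),
      seed = seeds[i],
      scan_id = paste0("scan", row$scan_index)
    )
    map_sets[[paste0("scan", row$scan_index)]] <- sim$map_set
    ground_truths[[paste0("scan", row$scan_index)]] <- sim$ground_truth
  }
  list(map_sets = map_sets, ground_truths = ground_truths, study = study)
}

#' Simulate the reference study and extract its labeled cell table
#'
#' Runs [simulate_reference_study()] and the segmentation + feature stages
#' on every simulated scan, attaching each recovered cell's ground-truth
#' type as `true_label` (by maximum-overlap matching against the planted
#' cells).
#'
#' @inheritParams simulate_reference_study
#' @param config Pipeline configuration, see [pipeline_config()].
#' @return List with `features` (labeled feature table pooled over scans),
#'   `per_scan` (data.frame of per-scan region/cell bookkeeping) and
#'   `study` (the bookkeeping rows simulated).
#' @export
simulate_reference_cells <- function(seed = 1, scans = 1:5,
                                     config = pipeline_config(),
                                     profiles = default_profiles()) {
  sims <- simulate_reference_study(seed, scans, profiles)
  tabs <- list(); per_scan <- list()
  for (sid in names(sims$map_sets)) {
    seg <- segment_scan(sims$map_sets[[sid]], config)
    tab <- build_feature_table(seg$rois, sims$map_sets[[sid]],
                               elements = config$elements,
                               aggregator = config$aggregator)
    truth <- match_rois_to_truth(seg$rois, sims$ground_truths[[sid]])
    tab$true_label <- truth$true_label
    tabs[[sid]] <- tab
    per_scan[[sid]] <- data.frame(
      scan_id = sid,
      n_regions_found = attr(seg$rois, "n_regions"),
      n_rejected = attr(seg$rois, "n_rejected"),
      n_cells = length(seg$rois), stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, tabs)
  rownames(features) <- NULL
  attr(features, "elements") <- config$elements
  attr(features, "aggregator") <- config$aggregator
  list(features = features, per_scan = do.call(rbind, per_scan),
       study = sims$study)
}
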