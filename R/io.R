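#' Write / read an RF frame as a plain-text container
#'
#' A two-file pair: `<stem>.rf.tsv` holds the sample matrix (axial samples x
#' lines, tab-separated) and `<stem>.json` the acquisition attributes
#' (`sampling_rate_hz`, `num_lines`, `lateral_fov_cm`, `speed_of_sound_mps`,
#' `focal_depth_cm`, `attenuation_db_cm_mhz`) plus, for phantoms, the
#' reference backscatter curve. Plain text replaces a binary container so
#' artifacts stay diffable and portable.
#'
#' @param frame an `rf_frame`.
#' @param stem path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_rf_frame <- function(frame, stem) {
  utils::write.table(frame$rf, paste0(stem, ".rf.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  acq <- frame$acquisition
  meta <- list(sampling_rate_hz = acq$sampling_rate_hz,
               num_lines = acq$num_lines,
               lateral_fov_cm = acq$lateral_fov_cm,
               max_depth_cm = acq$max_depth_cm,
               pulse_center_hz = acq$pulse_center_hz,
               pulse_fractional_bandwidth = acq$pulse_fractional_bandwidth,
               speed_of_sound_mps = acq$speed_of_sound_mps,
               focal_depth_cm = frame$focal_depth_cm,
               attenuation_db_cm_mhz = frame$attenuation_db_cm_mhz,
               ground_truth = frame$ground_truth)
  if (!is.null(frame$reference_bsc))
    meta$reference_bsc <- as.list(frame$reference_bsc)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_rf_frame
#' @return for `read_rf_frame`: the reconstructed `rf_frame`.
#' @export
read_rf_frame <- function(stem) {
  rf <- as.matrix(utils::read.table(paste0(stem, ".rf.tsv"), sep = "\t"))
  dimnames(rf) <- NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  acq <- acquisition_spec(meta$sampling_rate_hz, meta$num_lines,
                          meta$lateral_fov_cm, meta$max_depth_cm,
                          meta$pulse_center_hz,
                          meta$pulse_fractional_bandwidth,
                          meta$speed_of_sound_mps)
  fr <- structure(list(rf = rf, acquisition = acq,
                       focal_depth_cm = meta$focal_depth_cm,
                       attenuation_db_cm_mhz = meta$attenuation_db_cm_mhz,
                       ground_truth = meta$ground_truth),
                  class = "rf_frame")
  if (!is.null(meta$reference_bsc))
    fr$reference_bsc <- as.data.frame(meta$reference_bsc)
  fr
}

#' Write / read a cohort dataset as wide CSV
#'
#' Columns: `patient_id`, `label`, then feature columns. Feature names
#' round-trip unchanged.
#'
#' @param dataset a `cohort_dataset`; `path` CSV path.
#' @param path CSV file path.
#' @return the path / the dataset.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  class(df) <- c("cohort_dataset", class(df))
  df
}

#' Write a cohort manifest as CSV
#' @param cohort a `synthetic_cohort`; `path` CSV path.
#' @param path CSV file path.
#' @export
write_manifest_csv <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a model report (and its ROC curves) to a directory
#'
#' Emits `<prefix>_table.csv` shaped like the published comparison tables
#' (one row per model size, metric columns), `<prefix>_selected.json`, and
#' `<prefix>_roc_<size>.csv`.
#'
#' @param report a `model_report` from [run_pipeline()].
#' @param dir output directory; `prefix` file prefix.
#' @param prefix file-name prefix.
#' @export
write_model_report <- function(report, dir, prefix = "model") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, paste0(prefix, "_table.csv")),
                   row.names = FALSE)
  jsonlite::write_json(list(selected = report$selected,
                            classifier = report$config$classifier,
                            seed = report$config$seed),
                       file.path(dir, paste0(prefix, "_selected.json")),
                       auto_unbox = TRUE)
  for (sz in seq_along(report$roc)) {
    if (!is.null(report$roc[[sz]]))
      utils::write.csv(report$roc[[sz]],
                       file.path(dir, sprintf("%s_roc_%d.csv", prefix, sz)),
                       row.names = FALSE)
  }
  invisible(dir)
}
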