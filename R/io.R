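# Disk interfaces: 16-bit TIFF slices with an HU sidecar, CSV manifests,
# JSONL slice/bag indexes.

HU_OFFSET <- -1024
HU_SLOPE <- 1
HU_MAX_STORED <- 65535

#' Write a cohort to disk
#'
#' Slices are stored as 16-bit grayscale TIFFs with stored value
#' `(HU - hu_offset) / hu_slope`, plus a JSON sidecar recording the
#' transform; the manifest as CSV (`patient_id`, `artery`,
#' `stenosis_percent`, `label`); the slice index (with ground truth, when
#' present) as JSONL.
#'
#' @param cohort A `milcta_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "slices"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(hu_offset = HU_OFFSET, hu_slope = HU_SLOPE),
                       file.path(dir, "hu_sidecar.json"), auto_unbox = TRUE)
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  con <- file(file.path(dir, "slice_index.jsonl"), "w")
  on.exit(close(con))
  for (pid in names(cohort$slices)) {
    for (i in seq_along(cohort$slices[[pid]])) {
      fn <- sprintf("%s_%04d.tif", pid, i - 1L)
      stored <- (cohort$slices[[pid]][[i]] - HU_OFFSET) / HU_SLOPE
      tiff::writeTIFF(pmin(pmax(stored, 0), HU_MAX_STORED) / HU_MAX_STORED,
                      file.path(dir, "slices", fn), bits.per.sample = 16L)
      tr <- cohort$truth[cohort$truth$patient_id == pid &
                           cohort$truth$slice_index == i - 1L, ]
      rec <- list(patient_id = pid, slice_index = i - 1L, file = fn)
      if (nrow(tr) == 1) {
        rec$has_plaque <- tr$has_plaque
        rec$plaque_kind <- tr$plaque_kind
      }
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `milcta_cohort` (without generator configuration).
#' @export
read_cohort <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "hu_sidecar.json"))
  manifest <- as_tibble(read.csv(file.path(dir, "manifest.csv"),
                                 stringsAsFactors = FALSE))
  idx <- lapply(readLines(file.path(dir, "slice_index.jsonl")),
                jsonlite::fromJSON)
  slices <- list()
  truth <- list()
  for (rec in idx) {
    m <- tiff::readTIFF(file.path(dir, "slices", rec$file))
    hu <- m * HU_MAX_STORED * side$hu_slope + side$hu_offset
    slices[[rec$patient_id]][[rec$slice_index + 1L]] <- hu
    truth[[length(truth) + 1L]] <- tibble(
      patient_id = rec$patient_id, slice_index = rec$slice_index,
      has_plaque = rec$has_plaque %||% NA,
      plaque_kind = rec$plaque_kind %||% NA_character_)
  }
  manifest$n_slices <- vapply(slices[manifest$patient_id], length, integer(1))
  structure(list(manifest = manifest, truth = bind_rows(truth),
                 slices = slices, config = NULL),
            class = "milcta_cohort")
}

#' Write bag manifests as JSONL
#'
#' One bag per line: `patient_id`, `bag_index`, `entries`, `replicated`,
#' `label`.
#'
#' @param bags Bag tibble from [cohort_bags()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bags_jsonl <- function(bags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(bags))) {
    writeLines(jsonlite::toJSON(list(
      patient_id = bags$patient_id[i], bag_index = bags$bag_index[i],
      entries = bags$entries[[i]], replicated = bags$replicated[[i]],
      label = bags$label[i]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Save / load a trained model
#'
#' A checkpoint is a single RDS archive holding the model configuration,
#' all parameter tensors, the frozen-parameter set and (optionally) the
#' training history; [mil_load()] restores a fully functional
#' `milcta_model`.
#'
#' @param model A `milcta_model`.
#' @param path Checkpoint file path.
#' @param history Optional training history tibble to store alongside.
#' @return `path`, invisibly ([mil_save()]); a `milcta_model` with
#'   attribute `history` ([mil_load()]).
#' @export
mil_save <- function(model, path, history = NULL) {
  saveRDS(list(config = model$config, params = model$params,
               frozen = model$frozen, history = history), path)
  invisible(path)
}

#' @rdname mil_save
#' @export
mil_load <- function(path) {
  ck <- readRDS(path)
  model <- mil_init(ck$config, seed = 1L)
  model$params <- ck$params
  model$frozen <- ck$frozen
  attr(model, "history") <- ck$history
  model
}

#' Write experiment artifacts
#'
#' Writes predictions CSV, per-repeat and aggregate metrics JSON,
#' calibration CSV, threshold-sweep CSV, and an attention report (top
#' slice per test case) as JSONL.
#'
#' @param experiment A `milcta_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(experiment$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(folds = experiment$folds, summary = experiment$summary,
         attention_hit_rate = attention_hit_rate(experiment)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  write.csv(calibration_table(experiment$predictions$label,
                              experiment$predictions$prob),
            file.path(dir, "calibration.csv"), row.names = FALSE)
  write.csv(threshold_sweep(experiment$predictions$label,
                            experiment$predictions$prob),
            file.path(dir, "sweep.csv"), row.names = FALSE)
  con <- file(file.path(dir, "attention.jsonl"), "w")
  for (i in seq_len(nrow(experiment$predictions))) {
    p <- experiment$predictions[i, ]
    writeLines(jsonlite::toJSON(list(
      patient_id = p$patient_id, repeat_id = p$repeat_id,
      top_slice_index = p$top_slice_index,
      top_slice_has_plaque = p$top_slice_has_plaque), auto_unbox = TRUE), con)
  }
  close(con)
  invisible(dir)
}
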