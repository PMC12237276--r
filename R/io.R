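#' Write a multi-subject epoch collection to a directory
#'
#' One RDS file per subject (the epochs as a `ch x T x n` array, the integer
#' labels, and the sample rate) plus a `manifest.json` listing the subjects
#' and shapes. The round trip through [read_epoch_dir()] is bit-exact.
#'
#' @param data List of [epoch_set()] objects.
#' @param dir Output directory (created if needed).
#' @param provenance Optional named list stored verbatim in the manifest
#'   (e.g. the generating [population_spec()]).
#' @return `dir`, invisibly.
#' @export
write_epoch_dir <- function(data, dir, provenance = NULL) {
  stopifnot(is.list(data),
            all(vapply(data, inherits, logical(1), "epoch_set")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(data, function(e) {
    d <- dim(e$epochs[[1]])
    arr <- array(unlist(e$epochs), dim = c(d[1], d[2], length(e$epochs)))
    file <- paste0(e$subject_id, ".rds")
    saveRDS(list(subject_id = e$subject_id, epochs = arr,
                 labels = e$labels, sample_rate = e$sample_rate),
            file.path(dir, file))
    list(subject_id = e$subject_id, file = file,
         ch = d[1], n_samples = d[2], n_epochs = length(e$epochs),
         sample_rate = e$sample_rate)
  })
  manifest <- list(format = "farka-epoch-dir", version = 1L,
                   subjects = entries)
  if (!is.null(provenance)) manifest$provenance <- provenance
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multi-subject epoch collection from a directory
#'
#' @param dir A directory written by [write_epoch_dir()].
#' @return A list of [epoch_set()] objects in manifest order.
#' @export
read_epoch_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no manifest.json in %s", dir), call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  if (!identical(manifest$format, "farka-epoch-dir")) {
    stop("directory is not a farka epoch container", call. = FALSE)
  }
  lapply(manifest$subjects, function(entry) {
    raw <- readRDS(file.path(dir, entry$file))
    n <- dim(raw$epochs)[3]
    epochs <- lapply(seq_len(n), function(i) raw$epochs[, , i])
    epoch_set(raw$subject_id, epochs, raw$labels, raw$sample_rate)
  })
}

#' Write an evaluation report as structured JSON
#'
#' Per-task rows plus the aggregate, suitable for downstream tooling.
#'
#' @param report A `farka_eval` from [run_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  stopifnot(inherits(report, "farka_eval"))
  payload <- list(
    tasks = report$tasks,
    mean_accuracy = report$mean_accuracy,
    params = list(
      alignment = if (identical(report$params$alignment_space, "none")) "none"
                  else report$params$alignment_space$space,
      kernel = report$params$kernel$family,
      gamma = report$params$kernel$gamma,
      mu = report$params$mu, eta = report$params$eta,
      train_on = report$params$train_on
    ),
    warnings = report$warnings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
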