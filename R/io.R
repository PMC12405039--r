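# Readers and writers for the package's plain-text interchange formats:
# ROI time series, connectivity matrices, distance matrices, cohort
# manifests and embeddings.  All CSV output is comma-separated UTF-8 with
# "." as decimal mark.

#' Read ROI time series from a delimited file
#'
#' Header row = ROI labels, one row per time point; empty cells or the
#' string `NaN` mark missing values.  `.tsv` extensions are read as
#' tab-separated.
#'
#' @param path File path.
#' @return A tibble, one column per ROI.
#' @export
read_roi_timeseries <- function(path) {
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) readr::read_tsv else readr::read_csv
  reader(path, na = c("", "NA", "NaN"), show_col_types = FALSE,
         progress = FALSE)
}

#' Read a connectivity matrix CSV
#'
#' ROI labels as both the header row and the first column.
#'
#' @param path File path.
#' @param ... Passed to [as_connectivity()] (e.g. `fisher = TRUE`).
#' @return A validated connectivity matrix.
#' @export
read_connectivity <- function(path, ...) {
  df <- readr::read_csv(path, na = c("", "NA", "NaN"), show_col_types = FALSE,
                        progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_connectivity(m, ...)
}

#' Write a connectivity (or distance) matrix as CSV
#' @param m Labelled square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(m, path) {
  df <- as_tibble(as.data.frame(m), rownames = "roi")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a distance matrix CSV (state ids as header row/column)
#' @param path File path.
#' @return Symmetric numeric matrix with state-id dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  attr(m, "metric") <- "frobenius"
  m
}

#' Write a distance matrix as CSV
#' @param d Distance matrix from [state_distances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- as_tibble(as.data.frame(unclass(d)), rownames = "state_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a cohort manifest (CSV or YAML)
#'
#' Required columns/keys: `state_id`, `subject_id`, `timepoint`,
#' `diagnosis`, `age`, `sex`, `path`, `input_kind`
#' (`"timeseries"` or `"matrix"`).
#'
#' @param path Manifest file (`.csv`, `.yml` or `.yaml`).
#' @return A tibble with the columns above.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    records <- yaml::read_yaml(path)
    if (!is.null(records$states)) records <- records$states
    manifest <- dplyr::bind_rows(lapply(records, as_tibble))
  } else {
    manifest <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("state_id", "subject_id", "timepoint", "diagnosis",
                "age", "sex", "path", "input_kind")
  miss <- setdiff(required, names(manifest))
  if (length(miss) > 0) {
    abort(paste0("manifest is missing required columns: ",
                 paste(miss, collapse = ", ")))
  }
  bad <- !manifest$input_kind %in% c("timeseries", "matrix")
  if (any(bad)) {
    abort(paste0("unknown input_kind '", manifest$input_kind[bad][1],
                 "' for state ", manifest$state_id[bad][1]))
  }
  manifest
}

#' Build brain states from a manifest
#'
#' Reads each referenced file (time series are correlated with
#' [compute_connectivity()]; precomputed matrices pass the same
#' validators) and attaches the manifest metadata.  All files are checked
#' for existence up front so nothing is half-read.
#'
#' @param manifest Manifest tibble (or path, read with [read_manifest()]).
#' @param base_dir Directory `path` entries are relative to; defaults to
#'   the manifest's own directory when `manifest` is a path.
#' @param transform Connectivity transform for time-series inputs.
#' @return List of [brain_state()] objects.
#' @export
build_states <- function(manifest, base_dir = ".",
                         transform = c("pearson", "fisher_z")) {
  transform <- match.arg(transform)
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  files <- file.path(base_dir, manifest$path)
  missing <- !file.exists(files)
  if (any(missing)) {
    abort(paste0("input file not found: '", manifest$path[missing][1],
                 "' (state ", manifest$state_id[missing][1], ")"))
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    m <- if (row$input_kind == "timeseries") {
      compute_connectivity(read_roi_timeseries(files[i]), transform = transform)
    } else {
      read_connectivity(files[i])
    }
    brain_state(m, state_id = row$state_id, subject_id = row$subject_id,
                timepoint = row$timepoint, diagnosis = row$diagnosis,
                age = row$age, sex = row$sex, validate = FALSE)
  })
}

#' Write an embedding as CSV plus a JSON sidecar
#'
#' The CSV holds `state_id`, `dim_1` ... `dim_D`; the sidecar (same path
#' with `.json`) records method, seed, stress and the distance metric.
#'
#' @param embedding A `brain_embedding`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  readr::write_csv(as_tibble(embedding), path)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(method = attr(embedding, "method"),
         seed = attr(embedding, "seed"),
         stress = attr(embedding, "stress"),
         dims = attr(embedding, "dims"),
         metric = "frobenius"),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path CSV path (the JSON sidecar is picked up automatically).
#' @return A `brain_embedding`.
#' @export
read_embedding <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- structure(as_tibble(out), class = c("brain_embedding", class(tibble())))
  sidecar <- sub("\\.csv$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "method") <- meta$method
    attr(out, "seed") <- meta$seed
    attr(out, "stress") <- meta$stress
    attr(out, "dims") <- meta$dims
  } else {
    attr(out, "dims") <- length(grep("^dim_", names(out)))
  }
  out
}
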