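# Building validated brain states (connectivity matrices + metadata) from
# ROI time series or precomputed matrices, and harmonizing a cohort to the
# ROIs present in every state.

#' Compute a functional connectivity matrix from ROI time series
#'
#' Pearson-correlates every pair of ROI columns of a time-series table to
#' produce a symmetric connectivity matrix with unit diagonal.  A column
#' that is entirely missing (`NA`) marks a missing ROI: its whole row and
#' column of the output are `NA`.  Partially missing columns are rejected.
#'
#' @param ts A data frame or matrix with one row per time point and one
#'   named column per ROI. At least 3 time points and 2 present ROIs.
#' @param transform `"pearson"` (default) leaves correlations in
#'   \eqn{[-1, 1]}; `"fisher_z"` applies the Fisher z transform
#'   \eqn{\mathrm{atanh}(r)} to the off-diagonal entries (the diagonal
#'   stays 1, and the \eqn{[-1,1]} range no longer applies).
#'
#' @return An N x N numeric matrix with ROI labels as dimnames.
#' @examples
#' ts <- tibble::tibble(a = sin(1:20), b = cos(1:20), c = sin(1:20 + 1))
#' compute_connectivity(ts)
#' @export
compute_connectivity <- function(ts, transform = c("pearson", "fisher_z")) {
  transform <- match.arg(transform)
  x <- as.matrix(ts)
  storage.mode(x) <- "double"
  labels <- colnames(x)
  if (is.null(labels) || anyDuplicated(labels) > 0) {
    abort("time series must have unique ROI column names")
  }
  if (nrow(x) < 3) abort("need at least 3 time points to correlate (T >= 3)")
  n_na <- colSums(is.na(x))
  partial <- n_na > 0 & n_na < nrow(x)
  if (any(partial)) {
    abort(paste0("ROI '", labels[which(partial)[1]],
                 "' is partially missing; a column must be fully observed or fully NA"))
  }
  missing_roi <- n_na == nrow(x)
  if (sum(!missing_roi) < 2) abort("need at least 2 non-missing ROIs")
  sds <- apply(x[, !missing_roi, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("ROI '", labels[!missing_roi][which(sds == 0)[1]],
                 "' has zero variance; cannot correlate"))
  }
  n <- length(labels)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  r <- stats::cor(x[, !missing_roi, drop = FALSE])
  if (transform == "fisher_z") {
    off <- row(r) != col(r)
    r[off] <- atanh(pmin(pmax(r[off], -1 + 1e-15), 1 - 1e-15))
  }
  diag(r) <- 1
  m[!missing_roi, !missing_roi] <- r
  m
}

#' Validate (and lightly repair) a precomputed connectivity matrix
#'
#' Checks the invariants a connectivity matrix must satisfy: square with
#' matching unique ROI dimnames, symmetric within `tol_sym`, missing ROIs
#' expressed as whole-row-and-column `NA`, unit diagonal for present ROIs,
#' and (unless `fisher = TRUE`) entries in \eqn{[-1, 1]}.  Entries within
#' `clamp_tol` beyond the bounds are clamped; anything further is an error.
#'
#' @param values Square numeric matrix; ROI labels as dimnames (or supplied
#'   via `roi_labels`).
#' @param roi_labels Optional character vector of ROI labels.
#' @param tol_sym Symmetry tolerance (default 1e-12).
#' @param clamp_tol How far beyond \eqn{\pm 1} an entry may lie and still
#'   be clamped rather than rejected (default 1e-9).
#' @param fisher Set `TRUE` if entries are Fisher z values (range check off).
#' @return The validated matrix (symmetrized to machine precision, clamped,
#'   diagonal fixed at 1 for present ROIs).
#' @export
as_connectivity <- function(values, roi_labels = NULL, tol_sym = 1e-12,
                            clamp_tol = 1e-9, fisher = FALSE) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) abort("connectivity matrix must be square")
  if (!is.null(roi_labels)) dimnames(m) <- list(roi_labels, roi_labels)
  labels <- trimws(rownames(m) %||% abort("connectivity matrix needs ROI labels"))
  if (!identical(labels, trimws(colnames(m)))) {
    abort("row and column ROI labels differ")
  }
  if (anyDuplicated(labels) > 0) abort("ROI labels must be unique")
  dimnames(m) <- list(labels, labels)

  row_na <- apply(m, 1, function(r) all(is.na(r)))
  col_na <- apply(m, 2, function(r) all(is.na(r)))
  if (!identical(row_na, col_na)) {
    abort("a missing ROI must have its entire row AND column missing")
  }
  present <- !row_na
  sub <- m[present, present, drop = FALSE]
  if (anyNA(sub)) {
    abort("stray NA entries among present ROIs (ROI i missing must mean row i and column i all-NA)")
  }
  if (max(abs(sub - t(sub))) > tol_sym) {
    abort(sprintf("matrix not symmetric within %g", tol_sym))
  }
  sub <- (sub + t(sub)) / 2
  if (!fisher) {
    over <- abs(sub) > 1
    if (any(abs(sub[over]) > 1 + clamp_tol)) {
      abort(sprintf("entries outside [-1, 1] by more than %g", clamp_tol))
    }
    sub[over] <- sign(sub[over])
  }
  if (max(abs(diag(sub) - 1)) > clamp_tol) {
    abort("diagonal of present ROIs must equal 1")
  }
  diag(sub) <- 1
  m[present, present] <- sub
  m
}

#' Construct a brain state
#'
#' Bundles one subject-at-timepoint connectivity matrix with its metadata.
#'
#' @param matrix Connectivity matrix (validated with [as_connectivity()]).
#' @param state_id,subject_id Identifiers; `subject_id` defaults to
#'   `state_id`.
#' @param timepoint Ordinal visit label, e.g. `"baseline"`, `"FU1"`.
#' @param diagnosis Diagnosis label, e.g. `"normal"`, `"PD"`, `"AD"`.
#' @param age,sex Optional demographics.
#' @param validate Set `FALSE` to skip revalidation of an already-checked
#'   matrix.
#' @return An object of class `brain_state`.
#' @export
brain_state <- function(matrix, state_id, subject_id = state_id,
                        timepoint = "baseline", diagnosis = "unknown",
                        age = NA_real_, sex = NA_character_, validate = TRUE) {
  if (validate) matrix <- as_connectivity(matrix)
  structure(
    list(state_id = as.character(state_id),
         subject_id = as.character(subject_id),
         timepoint = as.character(timepoint),
         diagnosis = as.character(diagnosis),
         age = as.numeric(age), sex = as.character(sex),
         matrix = matrix),
    class = "brain_state"
  )
}

#' @export
print.brain_state <- function(x, ...) {
  present <- sum(!apply(x$matrix, 1, function(r) all(is.na(r))))
  cat(sprintf("<brain_state> %s  subject=%s  timepoint=%s  diagnosis=%s  ROIs=%d/%d present\n",
              x$state_id, x$subject_id, x$timepoint, x$diagnosis,
              present, nrow(x$matrix)))
  invisible(x)
}

roi_present <- function(m) {
  all_na <- apply(m, 1, function(r) all(is.na(r)))
  # an entirely zero row+column also counts as an empty ROI
  all_zero <- apply(m, 1, function(r) all(!is.na(r) & r == 0)) &
    apply(m, 2, function(r) all(!is.na(r) & r == 0))
  !(all_na | all_zero)
}

#' Harmonize a set of brain states to their common ROIs
#'
#' Restricts every state's matrix to the ROIs present (non-missing and
#' non-empty) in *all* states, in the ROI order of the first state, and
#' returns the cohort object every downstream stage consumes.  The number
#' of ROIs dropped from each state is recorded in the result.
#'
#' @param states A list of [brain_state()] objects (at least 2).
#' @param quiet Suppress the informational message about removed ROIs.
#' @return A `brain_cohort`: list with `states` (metadata tibble),
#'   `matrices` (named list of harmonized matrices), `roi_labels`
#'   (common ROIs) and `dropped` (per-state removal counts).
#' @export
harmonize_states <- function(states, quiet = FALSE) {
  if (inherits(states, "brain_state")) states <- list(states)
  if (length(states) < 2) abort("need at least 2 brain states to harmonize")
  stopifnot(all(vapply(states, inherits, logical(1), "brain_state")))

  present_list <- lapply(states, function(s) rownames(s$matrix)[roi_present(s$matrix)])
  common <- present_list[[1]]
  for (p in present_list[-1]) common <- common[common %in% p]
  if (length(common) < 2) {
    abort("fewer than 2 ROIs are present in every state; no brain space can be built")
  }

  meta <- dplyr::bind_rows(lapply(states, function(s) {
    tibble(state_id = s$state_id, subject_id = s$subject_id,
           timepoint = s$timepoint, diagnosis = s$diagnosis,
           age = s$age, sex = s$sex)
  }))
  if (anyDuplicated(meta$state_id) > 0) abort("state_id values must be unique")
  dup <- duplicated(meta[, c("subject_id", "timepoint")])
  if (any(dup)) {
    abort(sprintf("duplicate (subject_id, timepoint): %s/%s",
                  meta$subject_id[dup][1], meta$timepoint[dup][1]))
  }

  matrices <- lapply(states, function(s) s$matrix[common, common, drop = FALSE])
  names(matrices) <- meta$state_id
  dropped <- tibble(
    state_id = meta$state_id,
    n_rois = vapply(states, function(s) nrow(s$matrix), integer(1)),
    n_dropped = vapply(states, function(s) nrow(s$matrix), integer(1)) - length(common)
  )
  if (!quiet) {
    inform(sprintf("harmonized %d states: %d common ROIs retained (max %d dropped from a state)",
                   length(states), length(common), max(dropped$n_dropped)))
  }
  structure(
    list(states = meta, matrices = matrices, roi_labels = common,
         dropped = dropped),
    class = "brain_cohort"
  )
}

#' @export
print.brain_cohort <- function(x, ...) {
  cat(sprintf("<brain_cohort> %d states x %d common ROIs; diagnoses: %s\n",
              nrow(x$states), length(x$roi_labels),
              paste(unique(x$states$diagnosis), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.brain_cohort <- function(x, ...) x$states

#' Cohort state identifiers
#' @param cohort A `brain_cohort`.
#' @return Character vector of state ids.
#' @export
state_ids <- function(cohort) cohort$states$state_id

#' Extract one harmonized matrix from a cohort
#' @param cohort A `brain_cohort`.
#' @param state_id One state id.
#' @return The state's harmonized connectivity matrix.
#' @export
get_matrix <- function(cohort, state_id) {
  m <- cohort$matrices[[state_id]]
  if (is.null(m)) abort(paste0("unknown state_id: ", state_id))
  m
}
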