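# Synthetic cohorts with known ground truth: block-structured healthy
# correlation template, group perturbations, longitudinal follow-up
# deltas, latent Gaussian time series, and optional missing ROIs.
# Sampling goes through latent time series (not direct matrix noise) so
# every generated matrix is a realizable correlation matrix, mirroring
# the fMRI provenance of real connectomes.

#' Configuration of a synthetic cohort
#'
#' @param n_rois Number of ROIs (default 20).
#' @param block_sizes Community sizes summing to `n_rois`; default 4
#'   equal blocks.
#' @param n_subjects_per_group Subjects per diagnosis group (default 8).
#' @param groups List of group specs (see [default_groups()]); each has
#'   `label`, `perturbation` (symmetric matrix or edit tibble or `NULL`)
#'   and `followup_delta` (same, or `NULL` for no follow-up visit).
#' @param series_length Time points per simulated scan (default 500).
#' @param noise_scale Standard deviation of additive white sensor noise on
#'   the latent signal (default 0: finite-series sampling noise only).
#' @param missing_roi_rate Per-ROI probability of being absent from a
#'   scan (default 0).
#' @param within_block,between_block Correlation inside/between blocks of
#'   the healthy template (defaults 0.6 and 0.05).
#' @param seed Base seed; every sampled state derives its own stream
#'   deterministically from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_rois = 20, block_sizes = NULL,
                          n_subjects_per_group = 8, groups = NULL,
                          series_length = 500, noise_scale = 0,
                          missing_roi_rate = 0, within_block = 0.6,
                          between_block = 0.05, seed = 1) {
  if (is.null(block_sizes)) {
    b <- max(1L, n_rois %/% 5L)
    block_sizes <- rep(n_rois %/% b, b)
    block_sizes[seq_len(n_rois - sum(block_sizes))] <-
      block_sizes[seq_len(max(0L, n_rois - sum(block_sizes)))] + 1L
  }
  if (sum(block_sizes) != n_rois) abort("block_sizes must sum to n_rois")
  if (is.null(groups)) groups <- default_groups(block_sizes)
  cfg <- list(n_rois = n_rois, block_sizes = block_sizes,
              n_subjects_per_group = n_subjects_per_group, groups = groups,
              series_length = series_length, noise_scale = noise_scale,
              missing_roi_rate = missing_roi_rate,
              within_block = within_block, between_block = between_block,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Edit specification for a group perturbation
#'
#' @param idx_i,idx_j ROI indices of the edited pairs (i < j recommended).
#' @param delta Additive change applied symmetrically to each pair.
#' @return Tibble usable as `perturbation`/`followup_delta` in
#'   [cohort_config()].
#' @export
pair_edits <- function(idx_i, idx_j, delta) {
  tibble(idx_i = as.integer(idx_i), idx_j = as.integer(idx_j),
         delta = as.numeric(delta))
}

#' Default three-group design: healthy, PD-like, AD-like
#'
#' The PD-like group weakens all within-block couplings of the second
#' community by 0.4; the AD-like group does the same to the last
#' community.  The PD-like group additionally carries a follow-up visit
#' whose ground truth differs from its baseline at a single pair (the
#' first two ROIs of the second community, -0.35), so the true additive
#' K-operator is known exactly.
#'
#' @param block_sizes Community sizes of the template.
#' @return List of group specs for [cohort_config()].
#' @export
default_groups <- function(block_sizes = rep(5, 4)) {
  starts <- cumsum(c(1, utils::head(block_sizes, -1)))
  block_idx <- function(b) seq(starts[b], length.out = block_sizes[b])
  within_pairs <- function(rois) {
    cmb <- utils::combn(rois, 2)
    pair_edits(cmb[1, ], cmb[2, ], -0.4)
  }
  b2 <- block_idx(min(2, length(block_sizes)))
  blast <- block_idx(length(block_sizes))
  list(
    list(label = "healthy", perturbation = NULL, followup_delta = NULL),
    list(label = "PD-like", perturbation = within_pairs(b2),
         followup_delta = pair_edits(b2[1], b2[2], -0.35)),
    list(label = "AD-like", perturbation = within_pairs(blast),
         followup_delta = NULL)
  )
}

roi_names <- function(n) sprintf("ROI_%03d", seq_len(n))

edits_to_matrix <- function(edits, n) {
  if (is.null(edits)) return(matrix(0, n, n))
  if (is.matrix(edits)) {
    if (!isTRUE(all.equal(edits, t(edits)))) abort("perturbation matrix must be symmetric")
    return(edits)
  }
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(edits))) {
    i <- edits$idx_i[r]; j <- edits$idx_j[r]
    m[i, j] <- m[i, j] + edits$delta[r]
    m[j, i] <- m[i, j]
  }
  m
}

template_correlation <- function(config) {
  n <- config$n_rois
  block <- rep(seq_along(config$block_sizes), config$block_sizes)
  m <- matrix(config$between_block, n, n)
  same <- outer(block, block, "==")
  m[same] <- config$within_block
  diag(m) <- 1
  dimnames(m) <- list(roi_names(n), roi_names(n))
  m
}

project_correlation <- function(m, tol = 1e-8, maxit = 1000) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10 && max(abs(diag(m) - 1)) < 1e-12) return(m)
  fit <- tryCatch(
    Matrix::nearPD(m, corr = TRUE, conv.tol = tol, maxit = maxit,
                   keepDiag = TRUE),
    error = function(e) abort(paste0("nearest-correlation projection failed: ",
                                     conditionMessage(e))))
  out <- as.matrix(fit$mat)
  dimnames(out) <- dimnames(m)
  out
}

find_group <- function(config, group) {
  labels <- vapply(config$groups, `[[`, character(1), "label")
  if (is.numeric(group)) return(config$groups[[group]])
  g <- config$groups[[match(group, labels)]]
  if (is.null(g)) abort(paste0("unknown group: ", group))
  g
}

#' Ground-truth correlation matrix of a group
#'
#' Healthy block template plus the group's perturbation, re-projected to
#' the nearest valid correlation matrix whenever the edit breaks positive
#' semi-definiteness (a PSD edit is returned exactly).
#'
#' @param config A [cohort_config()].
#' @param group Group label or index.
#' @param timepoint `"baseline"` or `"followup"` (adds the group's
#'   `followup_delta` on top).
#' @return N x N correlation matrix with ROI dimnames.
#' @export
ground_truth_matrix <- function(config, group, timepoint = "baseline") {
  g <- find_group(config, group)
  m <- template_correlation(config) + edits_to_matrix(g$perturbation, config$n_rois)
  if (timepoint != "baseline") {
    if (is.null(g$followup_delta)) abort(paste0("group '", g$label, "' has no follow-up delta"))
    m <- m + edits_to_matrix(g$followup_delta, config$n_rois)
  }
  project_correlation(m)
}

local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample one synthetic brain state
#'
#' Simulates `series_length` multivariate-normal time points with the
#' group's ground-truth covariance (plus optional white sensor noise),
#' optionally blanks ROIs at `missing_roi_rate`, and runs the standard
#' connectivity computation, so the state is exactly what the pipeline
#' would see from a real scan of a brain with that ground truth.
#'
#' @inheritParams ground_truth_matrix
#' @param subject Subject index or label within the group.
#' @param seed Integer seed; identical arguments give a bit-identical
#'   state.
#' @return A [brain_state()].
#' @export
sample_state <- function(config, group, subject, timepoint = "baseline",
                         seed = config$seed) {
  g <- find_group(config, group)
  truth <- ground_truth_matrix(config, group, timepoint)
  n <- config$n_rois
  if (config$series_length < n) {
    inform(sprintf("series_length (%d) < n_rois (%d): correlation estimates will be noisy",
                   config$series_length, n))
  }
  sigma <- truth + diag(config$noise_scale^2, n)
  local_seed(seed, {
    x <- MASS::mvrnorm(config$series_length, mu = rep(0, n), Sigma = sigma)
    colnames(x) <- rownames(truth)
    if (config$missing_roi_rate > 0) {
      drop <- which(stats::runif(n) < config$missing_roi_rate)
      if (n - length(drop) < 2) drop <- drop[seq_len(max(0, n - 2))]
      x[, drop] <- NA_real_
    }
    age <- round(stats::runif(1, 50, 85))
    sex <- sample(c("male", "female"), 1)
    subject_id <- sprintf("%s_S%02d", g$label, as.integer(subject))
    state_id <- paste0(subject_id, if (timepoint == "baseline") "" else "_FU")
    brain_state(compute_connectivity(x), state_id = state_id,
                subject_id = subject_id, timepoint = timepoint,
                diagnosis = g$label, age = age, sex = sex, validate = FALSE)
  })
}

#' Simulate a full cohort with known ground truth
#'
#' One baseline state per subject per group, plus a follow-up state for
#' every subject of a group declaring a `followup_delta`.  Per-state
#' seeds are derived deterministically from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `states` (list of
#'   [brain_state()]), `truth` (per-group ground-truth matrices, the
#'   follow-up deltas and true additive K matrices) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  states <- list()
  truth <- list()
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    as.integer((as.numeric(config$seed) * 7919 + counter * 104729) %% 2147483647)
  }
  for (g in config$groups) {
    gt <- ground_truth_matrix(config, g$label, "baseline")
    entry <- list(baseline = gt)
    if (!is.null(g$followup_delta)) {
      gt_fu <- ground_truth_matrix(config, g$label, "followup")
      entry$followup <- gt_fu
      entry$true_k <- gt_fu - gt
      entry$followup_delta <- g$followup_delta
    }
    truth[[g$label]] <- entry
    for (s in seq_len(config$n_subjects_per_group)) {
      states[[length(states) + 1L]] <-
        sample_state(config, g$label, s, "baseline", seed = next_seed())
      if (!is.null(g$followup_delta)) {
        states[[length(states) + 1L]] <-
          sample_state(config, g$label, s, "followup", seed = next_seed())
      }
    }
  }
  structure(list(states = states, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d states, %d ROIs, groups: %s\n",
              length(x$states), x$config$n_rois,
              paste(vapply(x$config$groups, `[[`, character(1), "label"),
                    collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Produces a directory the pipeline can consume: `manifest.csv`, one
#' connectivity CSV per state under `states/`, and `ground_truth.json`
#' with the group templates and true K deltas.
#'
#' @param sim A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(file.path(dir, "states"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(sim$states, function(s) {
    rel <- file.path("states", paste0(s$state_id, ".csv"))
    write_connectivity(s$matrix, file.path(dir, rel))
    tibble(state_id = s$state_id, subject_id = s$subject_id,
           timepoint = s$timepoint, diagnosis = s$diagnosis,
           age = s$age, sex = s$sex, path = rel, input_kind = "matrix")
  })
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  jsonlite::write_json(
    lapply(sim$truth, function(e) lapply(e, function(v) {
      if (is.matrix(v)) unclass(as.data.frame(v)) else v
    })),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(manifest_path)
}
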