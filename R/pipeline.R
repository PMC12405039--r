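# End-to-end pipeline: manifest -> states -> distances -> embedding ->
# attribution -> K-operators for longitudinal pairs -> diagnosis
# subspaces, with every artefact written as plain text.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
          parent = e)
  })
}

#' Run the full brain-space pipeline
#'
#' Executes every stage on a cohort manifest and writes the artefact set:
#' `distance_matrix.csv`, `embedding.csv` (+ `.json` sidecar),
#' `pair_axis_correlations.csv`, `pair_variances.csv`, `roi_impacts.csv`,
#' `top_rois.csv`, one `k_<source>__<target>.csv` and
#' `reduced_path_<source>__<target>.json` per longitudinal pair,
#' `subspaces.json`, optionally `trajectories.csv`, and `run_log.json`
#' (seed, metric, retained-ROI count, per-state drop counts).  Re-running
#' with the same inputs and seed reproduces every file bit for bit.
#'
#' @param manifest Manifest path or tibble (see [read_manifest()]).
#' @param output_dir Directory for the artefacts (created if needed).
#' @param base_dir Directory manifest paths are relative to (defaults to
#'   the manifest's directory when a path is given).
#' @param dims Embedding dimensions (default 3).
#' @param mds_method `"classical"` or `"smacof"`.
#' @param seed Seed recorded in the log and used by SMACOF.
#' @param connectivity_transform `"pearson"` or `"fisher_z"` for
#'   time-series inputs.
#' @param k_mode K-operator mode for longitudinal pairs.
#' @param top_k Rows in the top-ROI table (default 5).
#' @param healthy_label Diagnosis defining the healthy subspace for
#'   trajectory verdicts; `NULL` (default) auto-detects `"healthy"` or
#'   `"normal"` and skips verdicts if neither occurs.
#' @param tol Geometry tolerance for subspace membership.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `embedding`, `attribution`, `k_operators`, `subspaces`, `log`).
#' @export
run_pipeline <- function(manifest, output_dir, base_dir = ".", dims = 3,
                         mds_method = c("classical", "smacof"), seed = 1,
                         connectivity_transform = c("pearson", "fisher_z"),
                         k_mode = c("additive", "multiplicative"),
                         top_k = 5, healthy_label = NULL, tol = 1e-9,
                         quiet = TRUE) {
  mds_method <- match.arg(mds_method)
  k_mode <- match.arg(k_mode)
  connectivity_transform <- match.arg(connectivity_transform)

  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- with_stage("manifest", read_manifest(manifest))
  }
  # validate inputs before anything is written
  states <- with_stage("state_builder",
                       build_states(manifest, base_dir, transform = connectivity_transform))
  cohort <- with_stage("state_builder", harmonize_states(states, quiet = quiet))
  d <- with_stage("brain_space", state_distances(cohort))
  embedding <- with_stage("brain_space",
                          embed_states(d, dims = dims, method = mds_method, seed = seed))
  attribution <- with_stage("attribution",
                            attribute_axes(cohort, embedding, k = top_k))

  pairs <- longitudinal_pairs(cohort)
  k_ops <- list()
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$source_id[i]; tid <- pairs$target_id[i]
    k_ops[[paste(sid, tid, sep = "__")]] <- with_stage(
      "k_operator",
      compute_k(brain_state(get_matrix(cohort, sid), sid, validate = FALSE),
                brain_state(get_matrix(cohort, tid), tid, validate = FALSE),
                mode = k_mode))
  }

  diagnoses <- unique(cohort$states$diagnosis)
  subspaces <- with_stage("subspaces", lapply(
    setNames(diagnoses, diagnoses),
    function(lab) build_subspace(embedding, cohort, lab)))

  if (is.null(healthy_label)) {
    healthy_label <- intersect(c("healthy", "normal"), diagnoses)[1]
  }
  verdicts <- NULL
  if (!is.na(healthy_label) && !is.null(healthy_label) &&
      healthy_label %in% diagnoses) {
    verdicts <- with_stage("subspaces",
                           classify_cohort_trajectories(embedding, cohort,
                                                        healthy_label, tol = tol))
  }

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(output_dir, f)
  write_distance_matrix(d, out("distance_matrix.csv"))
  write_embedding(embedding, out("embedding.csv"))
  readr::write_csv(attribution$correlations, out("pair_axis_correlations.csv"))
  readr::write_csv(attribution$variances, out("pair_variances.csv"))
  readr::write_csv(attribution$impacts, out("roi_impacts.csv"))
  readr::write_csv(attribution$top_rois, out("top_rois.csv"))
  for (nm in names(k_ops)) {
    k <- k_ops[[nm]]
    write_connectivity(k$values, out(paste0("k_", nm, ".csv")))
    rp <- reduced_path(embedding, k$source_state_id, k$target_state_id)
    jsonlite::write_json(
      list(source = k$source_state_id, target = k$target_state_id,
           source_coords = rp$source, target_coords = rp$target,
           abs_change = rp$abs_change, pct_variation = rp$pct_variation),
      out(paste0("reduced_path_", nm, ".json")),
      digits = NA, auto_unbox = TRUE, null = "null", na = "null")
  }
  jsonlite::write_json(
    lapply(subspaces, function(s) list(
      label = s$label, member_state_ids = s$member_state_ids,
      vertices = apply(s$vertices, 1, as.numeric, simplify = FALSE),
      degenerate = s$degenerate)),
    out("subspaces.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(verdicts)) readr::write_csv(verdicts, out("trajectories.csv"))

  log <- list(seed = seed, metric = "frobenius", dims = dims,
              mds_method = mds_method,
              connectivity_transform = connectivity_transform,
              k_mode = k_mode, n_states = nrow(cohort$states),
              retained_rois = length(cohort$roi_labels),
              stress = attr(embedding, "stress"),
              dropped = cohort$dropped)
  jsonlite::write_json(log, out("run_log.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")

  invisible(list(cohort = cohort, embedding = embedding,
                 attribution = attribution, k_operators = k_ops,
                 subspaces = subspaces, verdicts = verdicts, log = log))
}
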