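# Ground-truth recovery experiment on synthetic cohorts: can the
# embedding separate the diagnosis groups, are their convex subspaces
# disjoint, and does the known follow-up edit surface at the top of the
# pair-contribution ranking?

#' One recovery run on a synthetic cohort
#'
#' Simulates a cohort, embeds it, and measures (a) the mean silhouette
#' width of the diagnosis groups over the baseline states' embedded
#' coordinates, (b) whether all pairs of group subspaces (baseline states
#' only) are disjoint, and (c) for the first subject with a follow-up
#' visit, the rank of the ground-truth edited pair in the
#' pair-contribution table on that pair's dominant axis.
#'
#' @param config A [cohort_config()]; its `seed` drives the run.
#' @param dims Embedding dimensions (default 3).
#' @param tol Hull-separation tolerance.
#' @return One-row tibble: `seed`, `silhouette`, `hulls_disjoint`,
#'   `edited_pair_rank` (NA when no group declares a follow-up),
#'   `stress`.
#' @export
recovery_run <- function(config, dims = 3, tol = 1e-9) {
  sim <- simulate_cohort(config)
  cohort <- harmonize_states(sim$states, quiet = TRUE)
  embedding <- embed_states(state_distances(cohort), dims = dims)
  meta <- cohort$states
  x <- embedding_coords(embedding)

  base <- meta$timepoint == "baseline"
  grp <- as.integer(factor(meta$diagnosis[base]))
  sil <- mean(cluster::silhouette(grp, stats::dist(x[meta$state_id[base], ]))[, 3])

  labs <- unique(meta$diagnosis)
  base_meta <- meta[base, ]
  subs <- lapply(setNames(labs, labs),
                 function(l) build_subspace(embedding, base_meta, l))
  cmb <- utils::combn(labs, 2)
  disjoint <- all(vapply(seq_len(ncol(cmb)), function(i) {
    hulls_disjoint(subs[[cmb[1, i]]], subs[[cmb[2, i]]], tol = tol)$disjoint
  }, logical(1)))

  rank <- NA_integer_
  fu_groups <- names(Filter(function(e) !is.null(e$followup_delta), sim$truth))
  if (length(fu_groups) > 0) {
    edit <- sim$truth[[fu_groups[1]]]$followup_delta
    rois <- cohort$roi_labels
    edited <- c(roi_names(config$n_rois)[edit$idx_i[1]],
                roi_names(config$n_rois)[edit$idx_j[1]])
    if (all(edited %in% rois)) {
      pc <- pair_axis_correlation(pair_features(cohort), embedding)
      sel <- (pc$roi_i == edited[1] & pc$roi_j == edited[2]) |
        (pc$roi_i == edited[2] & pc$roi_j == edited[1])
      dim_cols <- grep("^dim_", names(pc), value = TRUE)
      axis <- which.max(abs(as.numeric(pc[sel, dim_cols])))
      subj <- meta$subject_id[meta$diagnosis == fu_groups[1] &
                                meta$timepoint != "baseline"][1]
      sid <- meta$state_id[meta$subject_id == subj & meta$timepoint == "baseline"]
      tid <- meta$state_id[meta$subject_id == subj & meta$timepoint != "baseline"]
      k <- compute_k(get_matrix(cohort, sid), get_matrix(cohort, tid))
      contrib <- pair_contributions(k, pc, axis = axis)
      rank <- which((contrib$roi_i == edited[1] & contrib$roi_j == edited[2]) |
                      (contrib$roi_i == edited[2] & contrib$roi_j == edited[1]))
    }
  }

  tibble(seed = config$seed, silhouette = sil, hulls_disjoint = disjoint,
         edited_pair_rank = as.integer(rank),
         stress = attr(embedding, "stress"))
}

#' Recovery experiment over several seeds
#'
#' Repeats [recovery_run()] with seeds `base_seed + 0 ... n_seeds - 1`.
#'
#' @param config Base [cohort_config()] (its seed is overridden).
#' @param n_seeds Number of repetitions (default 20).
#' @param base_seed First seed.
#' @param dims,tol Passed to [recovery_run()].
#' @return Tibble with one row per seed.
#' @export
recovery_experiment <- function(config, n_seeds = 20, base_seed = 1,
                                dims = 3, tol = 1e-9) {
  dplyr::bind_rows(lapply(seq_len(n_seeds) - 1L, function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    recovery_run(cfg, dims = dims, tol = tol)
  }))
}
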