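# The K-operator: the link-weight change carrying one brain state into
# another, in full connectome space and compressed into the embedding.

#' Compute the K-operator between two brain states
#'
#' In additive mode (default) `K = target - source`, so applying K to the
#' source reproduces the target exactly; positive entries are strengthened
#' links, negative entries weakened ones.  In multiplicative mode K is the
#' element-wise ratio `target / source`, defined only where the source
#' entry is nonzero; undefined cells are `NA` and counted in a warning.
#'
#' @param source,target [brain_state()] objects (or bare connectivity
#'   matrices) over identical harmonized ROI sets.
#' @param mode `"additive"` or `"multiplicative"`.
#' @return A `k_operator`: list with `values` (N x N symmetric matrix),
#'   `mode`, `source_state_id`, `target_state_id`, `roi_labels`,
#'   `n_masked`.
#' @export
compute_k <- function(source, target, mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  sid <- if (inherits(source, "brain_state")) source$state_id else "source"
  tid <- if (inherits(target, "brain_state")) target$state_id else "target"
  sm <- if (inherits(source, "brain_state")) source$matrix else as.matrix(source)
  tm <- if (inherits(target, "brain_state")) target$matrix else as.matrix(target)
  if (!identical(rownames(sm), rownames(tm))) {
    abort("source and target must share identical ROI labels; harmonize first")
  }
  if (anyNA(sm) || anyNA(tm)) abort("states contain missing ROIs; harmonize first")
  n_masked <- 0L
  if (mode == "additive") {
    v <- tm - sm
  } else {
    v <- tm / sm
    mask <- sm == 0
    n_masked <- sum(mask)
    v[mask] <- NA_real_
    if (n_masked > 0) {
      warn(sprintf("multiplicative K undefined on %d cells with zero source entries", n_masked))
    }
  }
  structure(
    list(source_state_id = sid, target_state_id = tid, mode = mode,
         values = v, roi_labels = rownames(sm), n_masked = n_masked),
    class = "k_operator"
  )
}

#' Apply a K-operator to a connectivity matrix
#' @param k A `k_operator`.
#' @param m Connectivity matrix (or `brain_state`) with matching ROIs.
#' @return The transformed matrix.
#' @export
apply_k <- function(k, m) {
  if (inherits(m, "brain_state")) m <- m$matrix
  if (!identical(rownames(m), k$roi_labels)) abort("ROI labels do not match the operator")
  if (k$mode == "additive") m + k$values else m * k$values
}

#' Invert a K-operator (the ideal healing)
#'
#' The inverse operator carries the target state back to the source:
#' negated values in additive mode, element-wise reciprocals in
#' multiplicative mode (only when every cell is defined and nonzero).
#'
#' @param k A `k_operator`.
#' @return The inverse `k_operator`, with source/target swapped.
#' @export
invert_k <- function(k) {
  if (k$mode == "multiplicative") {
    if (k$n_masked > 0 || anyNA(k$values) || any(k$values == 0)) {
      abort("multiplicative K not invertible: masked or zero cells")
    }
    v <- 1 / k$values
  } else {
    v <- -k$values
  }
  structure(
    list(source_state_id = k$target_state_id, target_state_id = k$source_state_id,
         mode = k$mode, values = v, roi_labels = k$roi_labels, n_masked = 0L),
    class = "k_operator"
  )
}

#' @export
print.k_operator <- function(x, ...) {
  cat(sprintf("<k_operator> %s -> %s (%s), %d ROIs, max |K| = %.3g%s\n",
              x$source_state_id, x$target_state_id, x$mode,
              length(x$roi_labels), max(abs(x$values), na.rm = TRUE),
              if (x$n_masked > 0) sprintf(", %d masked cells", x$n_masked) else ""))
  invisible(x)
}

#' Reduced-space path between two embedded states
#'
#' The compressed description of a K-operator: per embedding dimension,
#' the absolute coordinate change and the percentage variation
#' \eqn{100 |x_t - x_s| / |x_s|} relative to the source coordinate.  Where
#' the source coordinate is (numerically) zero the percentage is
#' undefined (`NA`) and only the absolute change is meaningful.
#'
#' @param embedding A `brain_embedding`.
#' @param source_id,target_id State ids present in the embedding.
#' @param zero_tol Source coordinates below this magnitude count as zero.
#' @return Tibble `dimension`, `source`, `target`, `abs_change`,
#'   `pct_variation`, with the ids as attributes.
#' @export
reduced_path <- function(embedding, source_id, target_id, zero_tol = 1e-12) {
  x <- embedding_coords(embedding)
  for (id in c(source_id, target_id)) {
    if (!id %in% rownames(x)) abort(paste0("unknown state id: ", id))
  }
  s <- unname(x[source_id, ]); t <- unname(x[target_id, ])
  out <- tibble(
    dimension = seq_along(s),
    source = unname(s), target = unname(t),
    abs_change = abs(unname(t - s)),
    pct_variation = ifelse(abs(s) < zero_tol, NA_real_,
                           100 * abs(unname(t - s)) / abs(unname(s)))
  )
  attr(out, "source_id") <- source_id
  attr(out, "target_id") <- target_id
  out
}

#' Per-pair contribution of a K-operator to one embedding axis
#'
#' For every ROI pair: the connectivity change (the K entry), the pair's
#' correlation with the chosen axis, and their product, the estimated
#' contribution of that pair to the movement along the axis.  Since
#' correlations are bounded by 1, a contribution never exceeds the raw
#' change in magnitude.  Ranked by absolute contribution, descending.
#'
#' Signs are meaningful only within the one fitted embedding the
#' correlations came from (MDS axes have arbitrary orientation).
#'
#' @param k An additive `k_operator`.
#' @param pair_corr Pair-axis correlations from [pair_axis_correlation()]
#'   computed on the same cohort/embedding.
#' @param axis Axis (dimension) index, 1-based.
#' @param top_k How many pairs to return (default all).
#' @return Tibble `roi_i`, `roi_j`, `connectivity_change`, `axis_corr`,
#'   `estimated_contribution`, ranked.
#' @export
pair_contributions <- function(k, pair_corr, axis, top_k = Inf) {
  if (k$mode != "additive") abort("pair_contributions() needs an additive K")
  dim_cols <- grep("^dim_[0-9]+$", names(pair_corr), value = TRUE)
  if (!(axis %in% seq_along(dim_cols))) {
    abort(sprintf("axis must be in 1..%d", length(dim_cols)))
  }
  ii <- match(pair_corr$roi_i, k$roi_labels)
  jj <- match(pair_corr$roi_j, k$roi_labels)
  if (anyNA(ii) || anyNA(jj)) abort("pair ROIs not found in the operator's ROI set")
  change <- k$values[cbind(ii, jj)]
  corr <- pair_corr[[dim_cols[axis]]]
  out <- tibble(
    roi_i = pair_corr$roi_i, roi_j = pair_corr$roi_j,
    connectivity_change = change, axis_corr = corr,
    estimated_contribution = change * corr
  )
  out <- out[order(-abs(out$estimated_contribution), seq_len(nrow(out))), ]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  out
}

#' Longitudinal state pairs within a cohort
#'
#' Pairs consecutive timepoints of the same subject, in the order the
#' timepoints appear in the cohort metadata.
#'
#' @param cohort A `brain_cohort`.
#' @return Tibble `subject_id`, `source_id`, `target_id` (possibly empty).
#' @export
longitudinal_pairs <- function(cohort) {
  meta <- cohort$states
  tp_levels <- unique(meta$timepoint)
  out <- dplyr::group_modify(
    dplyr::group_by(meta, .data$subject_id),
    function(df, key) {
      df <- df[order(match(df$timepoint, tp_levels)), ]
      if (nrow(df) < 2) return(tibble(source_id = character(), target_id = character()))
      tibble(source_id = df$state_id[-nrow(df)], target_id = df$state_id[-1])
    })
  dplyr::ungroup(out)
}
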