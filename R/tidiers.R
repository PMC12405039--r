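# broom-style tidiers for the package's result objects.

#' Tidy a brain embedding
#' @param x A `brain_embedding`.
#' @param ... Unused.
#' @return Plain tibble `state_id`, `dim_1` ... `dim_D`.
#' @export
tidy.brain_embedding <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' One-row summary of a brain embedding
#' @param x A `brain_embedding`.
#' @param ... Unused.
#' @return Tibble with `n_states`, `dims`, `method`, `stress`,
#'   `neg_eig_share`, `seed`.
#' @export
glance.brain_embedding <- function(x, ...) {
  tibble(n_states = nrow(x),
         dims = attr(x, "dims") %||% length(grep("^dim_", names(x))),
         method = attr(x, "method") %||% NA_character_,
         stress = attr(x, "stress") %||% NA_real_,
         neg_eig_share = attr(x, "neg_eig_share") %||% NA_real_,
         seed = attr(x, "seed") %||% NA_integer_)
}

#' Tidy a K-operator into one row per ROI pair
#' @param x A `k_operator`.
#' @param ... Unused.
#' @return Tibble `roi_i`, `roi_j`, `value` over the strict upper
#'   triangle.
#' @export
tidy.k_operator <- function(x, ...) {
  pairs <- roi_pairs(x$roi_labels)
  tibble(roi_i = pairs$roi_i, roi_j = pairs$roi_j,
         value = x$values[cbind(pairs$idx_i, pairs$idx_j)])
}

#' One-row summary of a K-operator
#' @param x A `k_operator`.
#' @param ... Unused.
#' @return Tibble with ids, mode, extremes and masked-cell count.
#' @export
glance.k_operator <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble(source = x$source_state_id, target = x$target_state_id,
         mode = x$mode, n_rois = length(x$roi_labels),
         max_abs = max(abs(off), na.rm = TRUE),
         frobenius = sqrt(2 * sum(off^2, na.rm = TRUE)),
         n_masked = x$n_masked)
}

#' One-row summary of a subspace model
#' @param x A `subspace_model`.
#' @param ... Unused.
#' @return Tibble with `label`, `n_members`, `n_vertices`, `dims`,
#'   `degenerate`.
#' @export
glance.subspace_model <- function(x, ...) {
  tibble(label = x$label, n_members = length(x$member_state_ids),
         n_vertices = nrow(x$vertices), dims = x$dims,
         degenerate = x$degenerate)
}
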