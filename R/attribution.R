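# Explaining the embedding axes: which ROI pairs and which individual
# ROIs carry each dimension of the brain space.

#' Enumerate ROI pairs in canonical order
#'
#' Lexicographic by index, i < j: (1,2), (1,3), ..., (1,N), (2,3), ...
#'
#' @param labels Character vector of ROI labels.
#' @return Tibble with `idx_i`, `idx_j`, `roi_i`, `roi_j`.
#' @export
roi_pairs <- function(labels) {
  n <- length(labels)
  if (n < 2) abort("need at least 2 ROIs")
  idx_i <- rep(seq_len(n - 1), times = (n - 1):1)
  idx_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  tibble(idx_i = idx_i, idx_j = idx_j,
         roi_i = labels[idx_i], roi_j = labels[idx_j])
}

#' Pair-feature matrix of a cohort
#'
#' Vectorizes the strict upper triangle of every state's matrix: one row
#' per state, one column per ROI pair in [roi_pairs()] order.
#'
#' @param cohort A harmonized `brain_cohort`.
#' @return An M x P numeric matrix; rownames = state ids, attribute
#'   `pairs` = the pair tibble.
#' @export
pair_features <- function(cohort) {
  if (!inherits(cohort, "brain_cohort")) abort("pair_features() needs a brain_cohort")
  pairs <- roi_pairs(cohort$roi_labels)
  idx <- cbind(pairs$idx_i, pairs$idx_j)
  f <- t(vapply(cohort$matrices, function(m) m[idx], numeric(nrow(pairs))))
  rownames(f) <- state_ids(cohort)
  attr(f, "pairs") <- pairs
  f
}

#' Correlation of each ROI pair with each embedding axis
#'
#' Pearson correlation, across states, between a pair's connectivity
#' values and the states' coordinates on each axis.  A pair (or axis) with
#' zero variance gets correlation 0, so downstream sums stay defined.
#'
#' @param features Pair-feature matrix from [pair_features()].
#' @param embedding A `brain_embedding` over the same states.
#' @return Tibble with `roi_i`, `roi_j` and one `dim_k` column per axis.
#' @export
pair_axis_correlation <- function(features, embedding) {
  if (nrow(features) < 3) abort("need at least 3 states for pair-axis correlations")
  x <- embedding_coords(embedding)
  if (!identical(rownames(features), rownames(x))) {
    x <- x[rownames(features), , drop = FALSE]
  }
  r <- suppressWarnings(stats::cor(features, x))
  r[!is.finite(r)] <- 0
  pairs <- attr(features, "pairs")
  out <- pairs[, c("roi_i", "roi_j")]
  for (k in seq_len(ncol(x))) out[[paste0("dim_", k)]] <- unname(r[, k])
  out
}

#' Rank ROI pairs by cross-state variance
#'
#' Sample variance (denominator M - 1) of each pair's connectivity value
#' across the cohort, sorted descending; ties keep canonical pair order.
#'
#' @param features Pair-feature matrix from [pair_features()].
#' @return Tibble `roi_i`, `roi_j`, `variance`, ranked.
#' @export
pair_variance_ranking <- function(features) {
  if (nrow(features) < 2) abort("need at least 2 states for a variance")
  v <- apply(features, 2, stats::var)
  pairs <- attr(features, "pairs")
  ord <- order(-v, seq_along(v))
  tibble(roi_i = pairs$roi_i[ord], roi_j = pairs$roi_j[ord],
         variance = unname(v[ord]))
}

#' Per-ROI impact on each axis (the half-sum rule)
#'
#' The impact of a ROI on an axis is half the sum of the pair-axis
#' correlations of all pairs involving that ROI; the 1/2 factor stops a
#' pair from being counted twice, so per axis the ROI impacts sum exactly
#' to the sum of the pair correlations.
#'
#' @param pair_corr Output of [pair_axis_correlation()].
#' @param normalize If `TRUE`, divide each ROI's impact by its number of
#'   incident pairs (N - 1), giving a correlation-scale average instead of
#'   a raw half-sum.
#' @return Tibble with `roi` and one `dim_k` column per axis, in cohort
#'   ROI order.
#' @export
roi_impact <- function(pair_corr, normalize = FALSE) {
  rois <- unique(c(pair_corr$roi_i, pair_corr$roi_j))
  dim_cols <- grep("^dim_[0-9]+$", names(pair_corr), value = TRUE)
  cmat <- as.matrix(pair_corr[, dim_cols, drop = FALSE])
  inc <- vapply(rois, function(r) pair_corr$roi_i == r | pair_corr$roi_j == r,
                logical(nrow(pair_corr)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = nrow(pair_corr))
  imp <- 0.5 * t(inc) %*% cmat
  if (normalize) imp <- imp / (length(rois) - 1)
  out <- tibble(roi = rois)
  for (k in seq_along(dim_cols)) out[[dim_cols[k]]] <- unname(imp[, k])
  out
}

#' Top-k ROIs per axis by absolute impact
#'
#' @param impact Output of [roi_impact()].
#' @param k How many ROIs per axis (default 5).
#' @return Tibble `axis`, `rank`, `roi`, `impact` with the signed impact
#'   retained; ties broken by ROI label.
#' @export
top_rois <- function(impact, k = 5) {
  if (k > nrow(impact)) abort("k must not exceed the number of ROIs")
  long <- tidyr::pivot_longer(impact, dplyr::starts_with("dim_"),
                              names_to = "axis", values_to = "impact")
  long <- dplyr::mutate(long, axis = as.integer(sub("^dim_", "", .data$axis)))
  long <- dplyr::arrange(long, .data$axis, dplyr::desc(abs(.data$impact)), .data$roi)
  long <- dplyr::mutate(dplyr::group_by(long, .data$axis), rank = dplyr::row_number())
  dplyr::select(dplyr::ungroup(dplyr::slice_head(long, n = k)),
                "axis", "rank", "roi", "impact")
}

#' One-call axis attribution for a cohort
#'
#' Convenience wrapper running [pair_features()],
#' [pair_axis_correlation()], [pair_variance_ranking()], [roi_impact()]
#' and [top_rois()].
#'
#' @param cohort A harmonized `brain_cohort`.
#' @param embedding Its `brain_embedding`.
#' @param k Top-k size for the ROI tables (default 5).
#' @param normalize Passed to [roi_impact()].
#' @return An `axis_attribution` list with elements `correlations`,
#'   `variances`, `impacts`, `top_rois` and the `features` matrix.
#' @export
attribute_axes <- function(cohort, embedding, k = 5, normalize = FALSE) {
  features <- pair_features(cohort)
  correlations <- pair_axis_correlation(features, embedding)
  structure(
    list(correlations = correlations,
         variances = pair_variance_ranking(features),
         impacts = roi_impact(correlations, normalize = normalize),
         top_rois = top_rois(roi_impact(correlations, normalize = normalize), k = k),
         features = features),
    class = "axis_attribution"
  )
}

#' @export
print.axis_attribution <- function(x, ...) {
  cat(sprintf("<axis_attribution> %d pairs x %d axes; top pair by variance: %s-%s (%.3g)\n",
              nrow(x$correlations),
              length(grep("^dim_", names(x$correlations))),
              x$variances$roi_i[1], x$variances$roi_j[1], x$variances$variance[1]))
  invisible(x)
}
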