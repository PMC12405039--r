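# Diagnosis subspaces: convex regions of the embedding, membership,
# separation between regions, and the stability verdict for a subject's
# trajectory.

#' Build the convex subspace of a diagnosis
#'
#' The subspace of a label is the convex hull of the embedded states
#' carrying that label: a point for one member, a segment for two, a
#' simplex/polytope beyond.  Cohorts smaller than D + 1 affinely
#' independent points give a degenerate (lower-dimensional) hull; it is
#' flagged and all geometry is computed in its affine span, not rejected —
#' small cohorts are the normal regime here.
#'
#' @param embedding A `brain_embedding`.
#' @param states State metadata: a `brain_cohort` or a tibble with
#'   `state_id` and `diagnosis` columns.
#' @param label The diagnosis whose subspace to build; must occur in the
#'   metadata.
#' @return A `subspace_model`: list with `label`, `member_state_ids`,
#'   `points` (members x D), `vertices` (V x D), `vertex_state_ids`,
#'   `dims`, `degenerate`.
#' @export
build_subspace <- function(embedding, states, label) {
  meta <- if (inherits(states, "brain_cohort")) states$states else as_tibble(states)
  if (!label %in% meta$diagnosis) {
    abort(paste0("unknown diagnosis label: '", label, "'"))
  }
  ids <- meta$state_id[meta$diagnosis == label]
  x <- embedding_coords(embedding)
  missing <- setdiff(ids, rownames(x))
  if (length(missing) > 0) abort(paste0("state not in embedding: ", missing[1]))
  pts <- x[ids, , drop = FALSE]
  d <- ncol(pts)
  vidx <- hull_vertices_idx(pts)
  centered <- sweep(pts, 2, colMeans(pts))
  affine_rank <- if (nrow(pts) == 1) 0L else qr(centered)$rank
  structure(
    list(label = label, member_state_ids = ids, points = pts,
         vertices = pts[vidx, , drop = FALSE], vertex_state_ids = ids[vidx],
         dims = d, degenerate = affine_rank < d),
    class = "subspace_model"
  )
}

#' @export
print.subspace_model <- function(x, ...) {
  cat(sprintf("<subspace_model> '%s': %d members, %d hull vertices in %d dims%s\n",
              x$label, length(x$member_state_ids), nrow(x$vertices), x$dims,
              if (x$degenerate) " (degenerate: lower-dimensional hull)" else ""))
  invisible(x)
}

#' Is a point inside a subspace?
#'
#' @param s A `subspace_model`.
#' @param point Numeric vector of length `dims`.
#' @param tol A point within `tol` of the hull (inside, on the boundary,
#'   or just outside) counts as contained; default 1e-9.  Degenerate hulls
#'   use the distance to the affine piece.
#' @return `TRUE` or `FALSE`.
#' @export
contains <- function(s, point, tol = 1e-9) {
  stopifnot(inherits(s, "subspace_model"))
  if (length(point) != s$dims) {
    abort(sprintf("point has length %d but the subspace has %d dims",
                  length(point), s$dims))
  }
  hull_project(s$points, as.numeric(point))$distance <= tol
}

#' Distance from a point to a subspace
#' @inheritParams contains
#' @return Nonnegative scalar (0 inside or on the hull).
#' @export
subspace_distance <- function(s, point) {
  stopifnot(inherits(s, "subspace_model"))
  if (length(point) != s$dims) abort("dimension mismatch")
  hull_project(s$points, as.numeric(point))$distance
}

#' Are two subspaces disjoint?
#'
#' Two convex regions are disjoint when the minimum distance between them
#' exceeds `tol`.  The witness is the closest point pair (coincident if
#' the hulls intersect).
#'
#' @param a,b `subspace_model`s of equal dimension.
#' @param tol Separation tolerance (default 1e-9).
#' @return List `disjoint` (logical), `distance`, `witness_a`,
#'   `witness_b`.
#' @export
hulls_disjoint <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "subspace_model"), inherits(b, "subspace_model"))
  if (a$dims != b$dims) abort("subspaces have different dimensions")
  r <- hulls_distance(a$points, b$points)
  list(disjoint = r$distance > tol, distance = r$distance,
       witness_a = r$witness_a, witness_b = r$witness_b)
}

verdict_from_inside <- function(inside) {
  # all inside -> healthy-stable; >= 2 inside/outside switches ->
  # oscillating; otherwise diseased (final run outside, or a single
  # excursion whose recovered stability is not yet demonstrated)
  if (all(inside)) return("healthy-stable")
  n_switch <- sum(diff(inside) != 0)
  if (n_switch >= 2) "oscillating" else "diseased"
}

#' Classify a subject's trajectory against the healthy subspace
#'
#' A brain is healthy-stable when every one of its states over time lies
#' inside the healthy subspace; repeated entering and leaving (two or
#' more switches) is oscillating; anything else is diseased.
#'
#' @param embedding A `brain_embedding`.
#' @param healthy The healthy `subspace_model`.
#' @param state_ids The subject's state ids in time order.
#' @param subject_id Optional subject label for the output.
#' @param tol Membership tolerance, as in [contains()].
#' @return A `trajectory_verdict`: tibble `step`, `state_id`, `inside`,
#'   `region`, with attribute `verdict` in
#'   `{"healthy-stable", "diseased", "oscillating"}`.
#' @export
classify_trajectory <- function(embedding, healthy, state_ids,
                                subject_id = NA_character_, tol = 1e-9) {
  if (length(state_ids) < 1) abort("need at least one timepoint")
  x <- embedding_coords(embedding)
  missing <- setdiff(state_ids, rownames(x))
  if (length(missing) > 0) abort(paste0("state not in embedding: ", missing[1]))
  inside <- vapply(state_ids, function(id) contains(healthy, x[id, ], tol = tol),
                   logical(1))
  out <- tibble(step = seq_along(state_ids), state_id = state_ids,
                inside = unname(inside),
                region = ifelse(inside, healthy$label, "outside"))
  attr(out, "verdict") <- verdict_from_inside(unname(inside))
  attr(out, "subject_id") <- subject_id
  class(out) <- c("trajectory_verdict", class(out))
  out
}

#' @export
print.trajectory_verdict <- function(x, ...) {
  cat(sprintf("<trajectory_verdict> %s: %s (%d timepoints, %d inside)\n",
              attr(x, "subject_id") %||% "?", attr(x, "verdict"),
              nrow(x), sum(x$inside)))
  NextMethod()
}

#' Classify every multi-timepoint subject in a cohort
#'
#' Builds the healthy subspace from the states carrying `healthy_label`
#' and classifies each subject's time-ordered trajectory against it.
#'
#' @param embedding A `brain_embedding`.
#' @param cohort The `brain_cohort` the embedding was fit on.
#' @param healthy_label Diagnosis label defining the healthy subspace.
#' @param tol Membership tolerance.
#' @return Tibble `subject_id`, `verdict`, `n_timepoints`, `n_inside`.
#' @export
classify_cohort_trajectories <- function(embedding, cohort, healthy_label,
                                         tol = 1e-9) {
  healthy <- build_subspace(embedding, cohort, healthy_label)
  meta <- cohort$states
  tp_levels <- unique(meta$timepoint)
  out <- dplyr::group_modify(
    dplyr::group_by(meta, .data$subject_id),
    function(df, key) {
      df <- df[order(match(df$timepoint, tp_levels)), ]
      v <- classify_trajectory(embedding, healthy, df$state_id,
                               subject_id = key$subject_id[1], tol = tol)
      tibble(verdict = attr(v, "verdict"),
             n_timepoints = nrow(v), n_inside = sum(v$inside))
    })
  dplyr::ungroup(out)
}
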