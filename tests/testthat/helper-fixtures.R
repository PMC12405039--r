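# Shared fixture builders and independent oracles.

# a realizable correlation matrix with ROI labels, via random time series
rand_conn <- function(n = 5, t_len = 60, seed = 1, labels = NULL) {
  labels <- labels %||% sprintf("ROI_%03d", seq_len(n))
  withr::with_seed(seed, {
    m <- stats::cor(matrix(stats::rnorm(t_len * n), t_len, n))
    dimnames(m) <- list(labels, labels)
    m
  })
}

# a small cohort of k states over shared labels
toy_states <- function(k = 4, n = 5, seed = 1, diagnoses = NULL,
                       subjects = NULL, timepoints = NULL) {
  diagnoses <- diagnoses %||% rep("unknown", k)
  subjects <- subjects %||% sprintf("sub%02d", seq_len(k))
  timepoints <- timepoints %||% rep("baseline", k)
  lapply(seq_len(k), function(i) {
    brain_state(rand_conn(n, seed = seed + i),
                state_id = sprintf("st%02d", i), subject_id = subjects[i],
                timepoint = timepoints[i], diagnosis = diagnoses[i])
  })
}

toy_cohort <- function(k = 4, n = 5, seed = 1, ...) {
  harmonize_states(toy_states(k, n, seed, ...), quiet = TRUE)
}

# longhand Pearson correlation, independent of stats::cor
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  cxy <- sum((x - mx) * (y - my)) / (length(x) - 1)
  sx <- sqrt(sum((x - mx)^2) / (length(x) - 1))
  sy <- sqrt(sum((y - my)^2) / (length(y) - 1))
  cxy / (sx * sy)
}

# embedding-shaped tibble from explicit coordinates (rows = states)
fake_embedding <- function(coords, ids = NULL) {
  ids <- ids %||% sprintf("st%02d", seq_len(nrow(coords)))
  out <- tibble::tibble(state_id = ids)
  for (k in seq_len(ncol(coords))) out[[paste0("dim_", k)]] <- coords[, k]
  structure(out, class = c("brain_embedding", class(tibble::tibble())))
}

# subspace built straight from a coordinate matrix
fake_subspace <- function(coords, label = "healthy") {
  ids <- sprintf("m%02d", seq_len(nrow(coords)))
  emb <- fake_embedding(coords, ids)
  meta <- tibble::tibble(state_id = ids, diagnosis = label)
  build_subspace(emb, meta, label)
}

# 2D point-in-convex-polygon oracle built on grDevices::chull:
# the point is inside iff it lies on the inner side of every hull edge.
in_hull_2d_oracle <- function(pts, p, tol = 1e-9) {
  h <- grDevices::chull(pts)
  if (length(h) == 1) return(sqrt(sum((pts[h, ] - p)^2)) <= tol)
  if (length(h) == 2) {
    a <- pts[h[1], ]; b <- pts[h[2], ]
    tt <- sum((p - a) * (b - a)) / max(sum((b - a)^2), 1e-300)
    tt <- min(max(tt, 0), 1)
    return(sqrt(sum((a + tt * (b - a) - p)^2)) <= tol)
  }
  poly <- pts[h, , drop = FALSE]
  ctr <- colMeans(poly)
  for (i in seq_len(nrow(poly))) {
    a <- poly[i, ]; b <- poly[if (i == nrow(poly)) 1 else i + 1, ]
    nrm <- c(b[2] - a[2], a[1] - b[1])           # edge normal
    if (sum(nrm * (ctr - a)) < 0) nrm <- -nrm    # orient inward
    if (sum(nrm * (p - a)) < -tol * sqrt(sum(nrm^2))) return(FALSE)
  }
  TRUE
}
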