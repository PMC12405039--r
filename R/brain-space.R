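# The brain space proper: Frobenius distances between connectivity
# matrices and their multidimensional-scaling embedding.

#' Frobenius distance between two connectivity matrices
#'
#' Square root of the sum of squared element-wise differences over all
#' off-diagonal entries, i.e. \eqn{\sqrt{2 \sum_{i<j} (a_{ij}-b_{ij})^2}}.
#' The diagonal is excluded: it is identically 1 and carries no
#' information.
#'
#' @param a,b Connectivity matrices over identical ROI labels in identical
#'   order, with no missing entries (harmonize first).
#' @return A nonnegative scalar.
#' @export
frobenius_distance <- function(a, b) {
  la <- rownames(a); lb <- rownames(b)
  if (!identical(la, lb)) {
    diff1 <- if (length(la) != length(lb)) {
      setdiff(union(la, lb), intersect(la, lb))[1]
    } else la[which(la != lb)[1]]
    abort(paste0("ROI labels differ between matrices; first mismatch: '", diff1, "'"))
  }
  if (anyNA(a) || anyNA(b)) abort("matrices contain missing entries; harmonize the cohort first")
  d <- (a - b)[upper.tri(a)]
  sqrt(2 * sum(d^2))
}

#' All pairwise Frobenius distances within a cohort
#'
#' @param cohort A harmonized [`brain_cohort`][harmonize_states()].
#' @return An M x M symmetric matrix with zero diagonal, state ids as
#'   dimnames, and attribute `metric = "frobenius"`.
#' @export
state_distances <- function(cohort) {
  if (!inherits(cohort, "brain_cohort")) {
    abort("state_distances() needs a harmonized brain_cohort (see harmonize_states())")
  }
  feats <- pair_features(cohort)
  d <- sqrt(2) * as.matrix(stats::dist(feats))
  dimnames(d) <- list(state_ids(cohort), state_ids(cohort))
  attr(d, "metric") <- "frobenius"
  d
}

kruskal_stress <- function(d, coords) {
  dhat <- as.matrix(stats::dist(coords))
  num <- sum((d[upper.tri(d)] - dhat[upper.tri(dhat)])^2)
  den <- sum(d[upper.tri(d)]^2)
  if (den == 0) return(if (num == 0) 0 else Inf)
  sqrt(num / den)
}

smacof_once <- function(d, dims, init, max_iter = 500, tol = 1e-12) {
  m <- nrow(d)
  x <- init
  s_old <- kruskal_stress(d, x)
  for (it in seq_len(max_iter)) {
    dh <- as.matrix(stats::dist(x))
    b <- ifelse(dh > 0, -d / dh, 0)
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / m                      # Guttman transform
    s_new <- kruskal_stress(d, x)
    if (abs(s_old - s_new) < tol) break
    s_old <- s_new
  }
  list(coords = x, stress = kruskal_stress(d, x))
}

#' Embed a cohort of brain states by multidimensional scaling
#'
#' Places each state as a point in `dims` dimensions so that pairwise
#' embedded distances approximate the input Frobenius distances.  The
#' default is classical (Torgerson) scaling — double-centering followed by
#' a truncated spectral factorization — which is fully deterministic.
#' `method = "smacof"` minimizes Kruskal stress by majorization from
#' seeded random starts.
#'
#' Coordinates are determined only up to rotation/reflection; compare
#' distances, never raw axes, across fits.
#'
#' @param d A distance matrix (from [state_distances()]) or a
#'   `brain_cohort` (distances are computed first).
#' @param dims Number of embedding dimensions (default 3); must be
#'   at most M - 1.
#' @param method `"classical"` (default) or `"smacof"`.
#' @param seed Integer seed for the SMACOF starts (ignored by classical).
#' @param n_starts Number of SMACOF restarts; the lowest-stress fit wins.
#' @param max_iter Majorization iteration cap per start.
#' @return A `brain_embedding`: a tibble with columns `state_id`,
#'   `dim_1` ... `dim_D`, carrying attributes `stress` (Kruskal stress-1),
#'   `method`, `dims`, `seed`, `eig` (classical spectrum) and
#'   `neg_eig_share`.  If more than 30% of the spectral mass is negative
#'   (badly non-Euclidean input) a warning is recorded on the object.
#' @export
embed_states <- function(d, dims = 3, method = c("classical", "smacof"),
                         seed = NULL, n_starts = 4, max_iter = 500) {
  method <- match.arg(method)
  if (inherits(d, "brain_cohort")) d <- state_distances(d)
  d <- as.matrix(d)
  m <- nrow(d)
  ids <- rownames(d) %||% paste0("state_", seq_len(m))
  if (dims > m - 1) abort(sprintf("dims (%d) must be <= M - 1 (%d)", dims, m - 1))
  if (dims < 1) abort("dims must be a positive integer")

  eig <- NULL
  neg_share <- 0
  if (method == "classical") {
    fit <- suppressWarnings(stats::cmdscale(d, k = dims, eig = TRUE))
    x <- fit$points
    if (is.null(dim(x)) || ncol(x) < dims) {    # fewer positive eigenvalues than dims
      x <- cbind(x, matrix(0, m, dims - (if (is.null(dim(x))) 0 else ncol(x))))
    }
    eig <- fit$eig
    tot <- sum(abs(eig))
    neg_share <- if (tot > 0) sum(abs(eig[eig < 0])) / tot else 0
    seed <- NULL
  } else {
    seed <- as.integer(seed %||% 1L)
    best <- NULL
    scale0 <- max(d)
    if (scale0 == 0) scale0 <- 1
    for (s in seed + seq_len(n_starts) - 1L) {
      old <- get0(".Random.seed", envir = globalenv())
      set.seed(s)
      init <- matrix(stats::rnorm(m * dims, sd = scale0 / 2), m, dims)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      fit <- smacof_once(d, dims, init, max_iter = max_iter)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    x <- best$coords
  }
  rownames(x) <- ids
  stress <- kruskal_stress(d, x)

  out <- tibble(state_id = ids)
  for (k in seq_len(dims)) out[[paste0("dim_", k)]] <- unname(x[, k])
  out <- structure(out, class = c("brain_embedding", class(tibble())))
  attr(out, "method") <- method
  attr(out, "dims") <- dims
  attr(out, "seed") <- seed
  attr(out, "stress") <- stress
  attr(out, "eig") <- eig
  attr(out, "neg_eig_share") <- neg_share
  if (neg_share > 0.3) {
    attr(out, "warning") <- sprintf(
      "badly non-Euclidean distances: %.0f%% of spectral mass is negative", 100 * neg_share)
    warn(attr(out, "warning"))
  }
  out
}

#' Coordinate matrix of an embedding
#' @param embedding A `brain_embedding` (or any tibble with `state_id` and
#'   `dim_*` columns).
#' @return Numeric matrix, rows named by state id.
#' @export
embedding_coords <- function(embedding) {
  dim_cols <- grep("^dim_[0-9]+$", names(embedding), value = TRUE)
  x <- as.matrix(embedding[, dim_cols, drop = FALSE])
  rownames(x) <- embedding$state_id
  x
}

#' @export
print.brain_embedding <- function(x, ...) {
  cat(sprintf("<brain_embedding> %d states in %d dims (%s MDS), stress = %.4g\n",
              nrow(x), attr(x, "dims") %||% (ncol(x) - 1),
              attr(x, "method") %||% "?", attr(x, "stress") %||% NA_real_))
  NextMethod()
}
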