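# Convex geometry primitives: minimum-norm point in a convex hull
# (Wolfe's active-set algorithm), point-to-hull distance and projection,
# hull vertices, and the distance between two hulls via the Minkowski
# difference.  Exact up to machine precision for the small point sets a
# cohort produces; no external qhull binding is required.

affine_min_norm <- function(P) {
  # minimize ||P' a||^2 subject to sum(a) = 1 (a unconstrained in sign)
  k <- nrow(P)
  G <- P %*% t(P)
  A <- rbind(cbind(2 * G, rep(1, k)), c(rep(1, k), 0))
  rhs <- c(rep(0, k), 1)
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) drop(MASS::ginv(A) %*% rhs))
  a <- sol[seq_len(k)]
  s <- sum(a)
  if (abs(s) < 1e-300) rep(1 / k, k) else a / s
}

min_norm_point <- function(Z, tol = 1e-12) {
  # Wolfe's algorithm: the point of conv(rows of Z) closest to the origin.
  # Returns list(point, norm, weights) with weights over the rows of Z.
  m <- nrow(Z)
  nrm2 <- rowSums(Z^2)
  scale <- max(nrm2, 1)
  S <- which.min(nrm2)
  w <- 1
  w_tol <- 1e-12
  for (major in seq_len(10L * m + 100L)) {
    x <- drop(crossprod(Z[S, , drop = FALSE], w))
    ip <- drop(Z %*% x)
    j <- which.min(ip)
    if (ip[j] >= sum(x * x) - tol * scale) break
    if (j %in% S) break                      # numerical stall: accept current point
    S <- c(S, j); w <- c(w, 0)
    for (minor in seq_len(10L * m + 100L)) {
      a <- affine_min_norm(Z[S, , drop = FALSE])
      if (all(a > w_tol)) { w <- a; break }
      bad <- which(a <= w_tol & w > a)
      if (length(bad) == 0) { w <- pmax(a, 0); w <- w / sum(w); break }
      th <- min(w[bad] / (w[bad] - a[bad]))
      w <- (1 - th) * w + th * a
      keep <- w > w_tol
      if (all(keep)) keep[which.min(w)] <- FALSE
      S <- S[keep]; w <- w[keep]
      w <- w / sum(w)
    }
  }
  x <- drop(crossprod(Z[S, , drop = FALSE], w))
  weights <- numeric(m); weights[S] <- w
  list(point = x, norm = sqrt(max(sum(x * x), 0)), weights = weights)
}

hull_project <- function(X, p) {
  # distance from point p to conv(rows of X), with projection and weights
  Z <- sweep(X, 2, p)
  r <- min_norm_point(Z)
  list(distance = r$norm, projection = p + r$point, weights = r$weights)
}

hull_vertices_idx <- function(X, tol = 1e-9) {
  # indices of the rows of X that are vertices of conv(X)
  keep <- !duplicated(round(X / max(1, max(abs(X))), 12))
  cand <- which(keep)
  U <- X[cand, , drop = FALSE]
  if (nrow(U) <= 2) return(cand)
  scale <- max(1, max(abs(U)))
  is_v <- vapply(seq_len(nrow(U)), function(i) {
    hull_project(U[-i, , drop = FALSE], U[i, ])$distance > tol * scale
  }, logical(1))
  cand[is_v]
}

hulls_distance <- function(X, Y) {
  # min distance between conv(X) and conv(Y); witness points achieving it.
  # conv(X) - conv(Y) = conv({x_i - y_j}), so this is one min-norm problem.
  ma <- nrow(X); mb <- nrow(Y)
  ii <- rep(seq_len(ma), times = mb)
  jj <- rep(seq_len(mb), each = ma)
  Z <- X[ii, , drop = FALSE] - Y[jj, , drop = FALSE]
  r <- min_norm_point(Z)
  wa <- tapply(r$weights, ii, sum)[as.character(seq_len(ma))]
  wb <- tapply(r$weights, jj, sum)[as.character(seq_len(mb))]
  wa[is.na(wa)] <- 0; wb[is.na(wb)] <- 0
  list(distance = r$norm,
       witness_a = as.numeric(crossprod(X, wa)),
       witness_b = as.numeric(crossprod(Y, wb)))
}
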