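test_that("frobenius distance matches hand computation and a loop oracle", {
  labs <- letters[1:3]
  a <- diag(3); dimnames(a) <- list(labs, labs)
  expect_identical(frobenius_distance(a, a), 0)

  b <- a; b[1, 2] <- b[2, 1] <- 0.5        # one symmetric pair changed
  expect_equal(frobenius_distance(a, b), sqrt(2 * 0.25), tolerance = 1e-15)

  x <- rand_conn(5, seed = 3); y <- rand_conn(5, seed = 4)
  acc <- 0
  for (i in 1:5) for (j in 1:5) if (i != j) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(frobenius_distance(x, y), sqrt(acc), tolerance = 1e-12)
})

test_that("label mismatches are reported with the offending ROI", {
  a <- rand_conn(3, seed = 1, labels = c("A", "B", "C"))
  b <- rand_conn(3, seed = 2, labels = c("A", "X", "C"))
  expect_error(frobenius_distance(a, b), "'B'|'X'")
})

test_that("the cohort distance matrix agrees with per-pair calls", {
  coh <- toy_cohort(3, n = 6, seed = 7)
  d <- state_distances(coh)
  expect_equal(diag(d), setNames(rep(0, 3), state_ids(coh)))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d[i, j],
                 frobenius_distance(coh$matrices[[i]], coh$matrices[[j]]),
                 tolerance = 1e-12)
    expect_identical(d[i, j], d[j, i])
  }
  expect_error(state_distances(list()), "brain_cohort")
})

test_that("a duplicated matrix sits at distance zero and permutations relabel consistently", {
  states <- toy_states(3, n = 5, seed = 21)
  dup <- brain_state(states[[1]]$matrix, "dup", subject_id = "dup")
  d <- state_distances(harmonize_states(c(states, list(dup)), quiet = TRUE))
  expect_equal(d["st01", "dup"], 0)

  d1 <- state_distances(harmonize_states(states, quiet = TRUE))
  d2 <- state_distances(harmonize_states(states[c(3, 1, 2)], quiet = TRUE))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("distances satisfy the triangle inequality on all triples", {
  coh <- toy_cohort(8, n = 6, seed = 31)
  d <- state_distances(coh)
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }
})

test_that("classical MDS recovers Euclidean configurations", {
  # forced geometries
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  e0 <- embed_states(z, dims = 2)
  expect_equal(unname(embedding_coords(e0)), matrix(0, 3, 2))
  expect_equal(attr(e0, "stress"), 0)

  two <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  e1 <- embed_states(two, dims = 1)
  expect_equal(abs(unname(diff(embedding_coords(e1)[, 1]))), 5, tolerance = 1e-12)

  # 4 known 3D points: distances reproduced up to rotation/reflection
  withr::with_seed(11, pts <- matrix(rnorm(12), 4, 3))
  D <- as.matrix(dist(pts)); dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  e3 <- embed_states(D, dims = 3)
  expect_lt(max(abs(as.matrix(dist(embedding_coords(e3))) - D)), 1e-8)
  expect_lt(attr(e3, "stress"), 1e-8)
})

test_that("embedded and input distances are monotone together", {
  withr::with_seed(12, pts <- matrix(rnorm(10 * 3), 10, 3))
  D <- as.matrix(dist(pts)); dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  e <- embed_states(D, dims = 3)
  dh <- as.matrix(dist(embedding_coords(e)))
  expect_gte(cor(D[upper.tri(D)], dh[upper.tri(dh)], method = "spearman"), 0.99)
})

test_that("embedding is equivariant to state reordering", {
  coh <- toy_cohort(6, n = 5, seed = 41)
  d <- state_distances(coh)
  perm <- c(4, 1, 6, 3, 2, 5)
  e1 <- embed_states(d, dims = 2)
  e2 <- embed_states(d[perm, perm], dims = 2)
  d1 <- as.matrix(dist(embedding_coords(e1)))
  d2 <- as.matrix(dist(embedding_coords(e2)))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
})

test_that("dimension bounds and non-Euclidean warnings are enforced", {
  coh <- toy_cohort(4, n = 5, seed = 51)
  d <- state_distances(coh)
  expect_error(embed_states(d, dims = 4), "dims")
  # strongly non-metric 'distances' carry a recorded warning
  bad <- matrix(1, 4, 4) - diag(4)
  bad[1, 2] <- bad[2, 1] <- 10
  dimnames(bad) <- dimnames(d)
  expect_warning(eb <- embed_states(bad, dims = 2), "non-Euclidean")
  expect_match(attr(eb, "warning"), "negative")
})

test_that("SMACOF is seeded, reproducible, and fits embeddable inputs tightly", {
  coh <- toy_cohort(7, n = 6, seed = 61)
  d <- state_distances(coh)
  e1 <- embed_states(d, dims = 2, method = "smacof", seed = 5)
  e2 <- embed_states(d, dims = 2, method = "smacof", seed = 5)
  expect_identical(embedding_coords(e1), embedding_coords(e2))
  expect_identical(attr(e1, "method"), "smacof")

  # an exactly 2D-embeddable configuration reaches near-zero stress
  withr::with_seed(62, pts <- matrix(rnorm(12), 6, 2))
  D <- as.matrix(dist(pts)); dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  es <- embed_states(D, dims = 2, method = "smacof", seed = 1)
  expect_lt(attr(es, "stress"), 1e-3)
})

test_that("glance and tidy expose the embedding summary", {
  coh <- toy_cohort(5, n = 5, seed = 71)
  e <- embed_states(state_distances(coh), dims = 2)
  g <- glance(e)
  expect_identical(g$n_states, 5L)
  expect_identical(g$method, "classical")
  expect_identical(names(tidy(e)), c("state_id", "dim_1", "dim_2"))
})
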