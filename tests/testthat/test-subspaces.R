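test_that("hulls have the forced geometry on simple configurations", {
  # 4 affinely independent points in 3D form a tetrahedron
  tet <- fake_subspace(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_identical(nrow(tet$vertices), 4L)
  expect_false(tet$degenerate)

  # one member: the hull is the point itself, flagged degenerate
  pt <- fake_subspace(matrix(c(2, 3), 1, 2))
  expect_identical(nrow(pt$vertices), 1L)
  expect_true(pt$degenerate)
  expect_true(contains(pt, c(2, 3)))
  expect_false(contains(pt, c(2, 3.1)))

  # interior points are not vertices
  sq <- fake_subspace(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5)))
  expect_identical(nrow(sq$vertices), 4L)
})

test_that("hull vertices match the 2D chull oracle on random point sets", {
  for (seed in 1:4) {
    withr::with_seed(seed, pts <- matrix(rnorm(20), 10, 2))
    s <- fake_subspace(pts)
    oracle <- sort(grDevices::chull(pts))
    expect_identical(sort(match(s$vertex_state_ids, s$member_state_ids)), oracle)
    # every non-vertex member still lies inside the hull
    for (i in setdiff(1:10, oracle)) expect_true(contains(s, pts[i, ]))
  }
})

test_that("membership agrees with an independent 2D polygon oracle", {
  withr::with_seed(5, {
    pts <- matrix(rnorm(16), 8, 2)
    s <- fake_subspace(pts)
    probes <- matrix(rnorm(120, sd = 1.5), 60, 2)
    for (r in seq_len(nrow(probes))) {
      p <- probes[r, ]
      d <- subspace_distance(s, p)
      if (d > 1e-6) {
        expect_false(in_hull_2d_oracle(pts, p, tol = 1e-9))
        expect_false(contains(s, p))
      } else if (d == 0) {
        expect_true(in_hull_2d_oracle(pts, p, tol = 1e-9))
        expect_true(contains(s, p))
      }
    }
  })
})

test_that("membership tolerance behaves at the boundary", {
  tri <- fake_subspace(rbind(c(0, 0), c(2, 0), c(0, 2)))
  expect_true(contains(tri, c(2 / 3, 2 / 3)))          # centroid
  tol <- 1e-6
  # 10*tol along the outward normal of the bottom face -> outside
  expect_false(contains(tri, c(1, -10 * tol), tol = tol))
  # within tol outside still counts as contained
  expect_true(contains(tri, c(1, -0.5 * tol), tol = tol))
  expect_error(contains(tri, c(1, 1, 1)), "dims")
})

test_that("hull separation is measured exactly and symmetrically", {
  segA <- fake_subspace(rbind(c(0, 0), c(1, 0)), "A")
  segB <- fake_subspace(rbind(c(2, 0), c(3, 0)), "B")
  r <- hulls_disjoint(segA, segB)
  expect_true(r$disjoint)
  expect_equal(r$distance, 1, tolerance = 1e-9)
  expect_equal(unname(r$witness_a), c(1, 0), tolerance = 1e-9)
  expect_equal(unname(r$witness_b), c(2, 0), tolerance = 1e-9)
  # symmetry in the arguments
  r2 <- hulls_disjoint(segB, segA)
  expect_equal(r2$distance, r$distance, tolerance = 1e-12)

  # sharing a vertex -> not disjoint
  t1 <- fake_subspace(rbind(c(0, 0), c(1, 0), c(0, 1)), "A")
  t2 <- fake_subspace(rbind(c(0, 0), c(-1, 0), c(0, -1)), "B")
  expect_false(hulls_disjoint(t1, t2)$disjoint)
})

test_that("separation verdicts agree with a dense-sampling oracle", {
  withr::with_seed(6, {
    for (gap in c(2, 0)) {
      A <- matrix(rnorm(14, sd = 0.4), 7, 2)
      B <- matrix(rnorm(14, sd = 0.4), 7, 2); B[, 1] <- B[, 1] + gap
      if (gap == 0) B[1, ] <- A[1, ]        # force an intersection point
      sA <- fake_subspace(A, "A"); sB <- fake_subspace(B, "B")
      r <- hulls_disjoint(sA, sB)
      lam <- matrix(rexp(7 * 4000), 4000, 7); lam <- lam / rowSums(lam)
      mu <- matrix(rexp(7 * 4000), 4000, 7); mu <- mu / rowSums(mu)
      oracle_min <- min(sqrt(rowSums((lam %*% A - mu %*% B)^2)))
      expect_lte(r$distance, oracle_min + 1e-9)   # sampling only over-estimates
      if (gap == 2) expect_true(r$disjoint && oracle_min > 0.5)
      if (gap == 0) expect_false(r$disjoint)
    }
  })
})

test_that("trajectory verdicts enumerate the three-rule truth table", {
  healthy <- fake_subspace(rbind(c(0, 0), c(1, 0), c(0, 1)))
  inside_pt <- c(0.2, 0.2); outside_pt <- c(5, 5)
  oracle <- function(inside) {
    if (all(inside)) return("healthy-stable")
    if (sum(abs(diff(inside))) >= 2) return("oscillating")
    "diseased"
  }
  for (len in 1:4) {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), len))
    for (r in seq_len(nrow(grid))) {
      inside <- as.logical(grid[r, ])
      coords <- t(vapply(inside, function(i) if (i) inside_pt else outside_pt,
                         numeric(2)))
      ids <- sprintf("t%d", seq_len(len))
      emb <- fake_embedding(coords, ids)
      v <- classify_trajectory(emb, healthy, ids, subject_id = "subj")
      expect_identical(attr(v, "verdict"), oracle(inside))
      expect_identical(v$inside, inside)
    }
  }
  # spot checks of the named patterns
  expect_identical(attr(classify_trajectory(
    fake_embedding(rbind(inside_pt, outside_pt, inside_pt, outside_pt),
                   paste0("s", 1:4)),
    healthy, paste0("s", 1:4)), "verdict"), "oscillating")
  expect_error(classify_trajectory(fake_embedding(rbind(inside_pt), "a"),
                                   healthy, character(0)), "one timepoint")
})

test_that("subspaces are built per diagnosis from cohort metadata", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  ids <- sprintf("s%d", 1:6)
  emb <- fake_embedding(coords, ids)
  meta <- tibble::tibble(state_id = ids,
                         diagnosis = rep(c("healthy", "PD"), each = 3))
  h <- build_subspace(emb, meta, "healthy")
  expect_setequal(h$member_state_ids, ids[1:3])
  expect_true(all(vapply(seq_len(3), function(i) contains(h, coords[i, ]),
                         logical(1))))       # members always inside their hull
  expect_error(build_subspace(emb, meta, "AD"), "unknown diagnosis")
  expect_true(hulls_disjoint(h, build_subspace(emb, meta, "PD"))$disjoint)
  g <- glance(h)
  expect_identical(g$n_members, 3L)
})
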