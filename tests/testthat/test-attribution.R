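test_that("pair features are extracted in canonical order and round-trip", {
  coh <- toy_cohort(4, n = 3, seed = 1)
  f <- pair_features(coh)
  pairs <- attr(f, "pairs")
  expect_identical(nrow(pairs), 3L)
  expect_identical(pairs$idx_i, c(1L, 1L, 2L))
  expect_identical(pairs$idx_j, c(2L, 3L, 3L))

  # reshaping a column back writes the correct two symmetric cells
  m <- matrix(0, 3, 3)
  m[cbind(pairs$idx_i, pairs$idx_j)] <- f[2, ]
  m <- m + t(m)
  expect_equal(m[1, 3], unname(f[2, 2]))
  expect_equal(m, t(m))

  # double-loop extraction oracle
  coh2 <- toy_cohort(3, n = 5, seed = 2)
  f2 <- pair_features(coh2)
  p2 <- attr(f2, "pairs")
  for (s in 1:3) for (p in seq_len(nrow(p2))) {
    expect_identical(unname(f2[s, p]),
                     coh2$matrices[[s]][p2$idx_i[p], p2$idx_j[p]])
  }
})

test_that("pair-axis correlations are Pearson correlations with a zero-variance convention", {
  coh <- toy_cohort(5, n = 4, seed = 3)
  f <- pair_features(coh)
  # axis set equal to one pair's values -> correlation 1 on that axis
  emb <- fake_embedding(cbind(f[, 2], rnorm(5)), ids = rownames(f))
  pc <- pair_axis_correlation(f, emb)
  expect_equal(pc$dim_1[2], 1, tolerance = 1e-12)

  # longhand oracle per (pair, axis)
  x <- embedding_coords(emb)
  for (p in seq_len(ncol(f))) for (k in 1:2) {
    expect_equal(pc[[paste0("dim_", k)]][p], pearson_oracle(f[, p], x[, k]),
                 tolerance = 1e-12)
  }

  # constant pair across states -> 0, not NaN
  f0 <- f; f0[, 1] <- 0.4
  attr(f0, "pairs") <- attr(f, "pairs")
  pc0 <- pair_axis_correlation(f0, emb)
  expect_identical(pc0$dim_1[1], 0)
  expect_identical(pc0$dim_2[1], 0)

  expect_error(pair_axis_correlation(f[1:2, ], emb), "3 states")
})

test_that("pair variance ranking uses sample variance with lexicographic ties", {
  coh <- toy_cohort(2, n = 3, seed = 4)
  f <- pair_features(coh)
  f[, 1] <- c(0, 1)   # variance 0.5 by hand: (0.25 + 0.25) / (2 - 1)
  f[, 2] <- 0.2       # constant -> 0, ranked last
  f[, 3] <- c(0, 1)   # tie with pair 1 -> canonical order preserved
  attr(f, "pairs") <- attr(pair_features(coh), "pairs")
  r <- pair_variance_ranking(f)
  expect_equal(r$variance[1:2], c(0.5, 0.5))
  expect_identical(r$roi_j[1], "ROI_002")   # pair (1,2) before (2,3)
  expect_identical(r$roi_i[2], "ROI_002")
  expect_equal(r$variance[3], 0)
})

test_that("ROI impacts obey the half-sum rule and its conservation identity", {
  # single pair with correlation r -> each ROI gets r/2
  pc1 <- tibble::tibble(roi_i = "A", roi_j = "B", dim_1 = 0.8)
  imp1 <- roi_impact(pc1)
  expect_equal(imp1$dim_1, c(0.4, 0.4))

  withr::with_seed(9, {
    n <- 7
    labs <- sprintf("R%02d", 1:n)
    pairs <- roi_pairs(labs)
    pc <- pairs[, c("roi_i", "roi_j")]
    pc$dim_1 <- runif(nrow(pc), -1, 1)
    pc$dim_2 <- runif(nrow(pc), -1, 1)
    imp <- roi_impact(pc)
    # incidence-loop brute force
    for (r in labs) for (k in 1:2) {
      inc <- pc$roi_i == r | pc$roi_j == r
      expect_equal(imp[[paste0("dim_", k)]][imp$roi == r],
                   0.5 * sum(pc[[paste0("dim_", k)]][inc]), tolerance = 1e-12)
    }
    # conservation: per axis, impacts sum to the pair-correlation sum
    for (k in 1:2) {
      expect_equal(sum(imp[[paste0("dim_", k)]]), sum(pc[[paste0("dim_", k)]]),
                   tolerance = 1e-12)
    }
    # all-zero correlations -> all-zero impacts
    pc0 <- pc; pc0$dim_1 <- 0; pc0$dim_2 <- 0
    expect_true(all(as.matrix(roi_impact(pc0)[, -1]) == 0))
    # normalized variant divides by the incident-pair count
    expect_equal(roi_impact(pc, normalize = TRUE)$dim_1,
                 roi_impact(pc)$dim_1 / (n - 1), tolerance = 1e-14)
  })
})

test_that("top_rois ranks by absolute impact with label tie-breaks", {
  imp <- tibble::tibble(roi = c("A", "B", "C"),
                        dim_1 = c(0.1, -0.9, 0.5),
                        dim_2 = c(0.3, 0.3, -0.3))
  t1 <- top_rois(imp, k = 1)
  expect_identical(t1$roi[t1$axis == 1], "B")
  expect_identical(t1$impact[t1$axis == 1], -0.9)   # signed value retained
  tN <- top_rois(imp, k = 3)
  expect_setequal(tN$roi[tN$axis == 2], c("A", "B", "C"))
  expect_identical(tN$roi[tN$axis == 2], c("A", "B", "C"))  # |0.3| ties -> label order
  expect_error(top_rois(imp, k = 4), "exceed")
})

test_that("attribution re-runs cleanly when a state is added and stays well-formed", {
  states <- toy_states(5, n = 6, seed = 12)
  run <- function(sts) {
    coh <- harmonize_states(sts, quiet = TRUE)
    emb <- embed_states(state_distances(coh), dims = 2)
    attribute_axes(coh, emb, k = 3)
  }
  a1 <- run(states[1:4])
  a2 <- run(states)
  for (a in list(a1, a2)) {
    expect_identical(nrow(a$correlations), 15L)
    expect_true(all(abs(as.matrix(a$correlations[, -(1:2)])) <= 1 + 1e-12))
    expect_true(all(diff(a$variances$variance) <= 1e-15))
    expect_identical(nrow(a$top_rois), 6L)
  }
})
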