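test_that("featurization has the right shape and alignment removes rigid motion", {
  cx <- toy_complex(seed = 1)
  tr <- make_clustered_trajectory(cx, n_frames = 6, n_clusters = 1, seed = 2)
  m <- featurize(tr$trajectory, selection = "all", align = FALSE)
  n_atoms <- nrow(dplyr::filter(tr$trajectory, frame == 1))
  expect_equal(dim(m), c(6, 3 * n_atoms))
  # constant trajectory: zero-variance columns
  f1 <- dplyr::filter(tr$trajectory, frame == 1)
  const <- dplyr::bind_rows(lapply(1:4, function(f) {
    dplyr::mutate(f1, frame = f)
  }))
  mc <- featurize(const, selection = "all", align = FALSE)
  expect_true(all(apply(mc, 2, stats::var) < 1e-20))
  # rigidly moved copies collapse after alignment
  moved <- dplyr::bind_rows(lapply(1:4, function(f) {
    dplyr::mutate(rigid_motion(f1, seed = f), frame = f)
  }))
  ma <- featurize(moved, selection = "all", align = TRUE)
  expect_lt(max(apply(ma, 2, stats::sd)), 1e-6)
  expect_error(featurize(tr$trajectory, selection = integer(0)), "empty")
})

test_that("frame filtering drops broken frames with reasons", {
  cx <- toy_complex(seed = 2)
  tr <- make_clustered_trajectory(cx, n_frames = 5, n_clusters = 1, seed = 3)$trajectory
  clean <- filter_frames(tr)
  expect_equal(sort(unique(clean$frame)), 1:5)
  expect_equal(nrow(attr(clean, "dropped")), 0)
  bad <- tr
  bad$x[bad$frame == 3][1] <- NaN
  out <- filter_frames(bad)
  expect_equal(sort(unique(out$frame)), c(1, 2, 4, 5))
  expect_equal(attr(out, "dropped")$reason, "non-finite coordinates")
  # topology mismatch
  bad2 <- dplyr::filter(tr, !(frame == 2 & elety == "CB" & resno == 1))
  out2 <- filter_frames(bad2)
  expect_equal(attr(out2, "dropped")$frame, 2)
  expect_equal(attr(out2, "dropped")$reason, "topology mismatch")
  all_bad <- dplyr::mutate(tr, x = NA_real_)
  expect_error(filter_frames(all_bad), "no valid frames")
})

test_that("dimensionality reduction is deterministic and preserves blob structure", {
  set.seed(10)
  blobs <- rbind(
    matrix(rnorm(50 * 12, 0, 0.5), ncol = 12),
    matrix(rnorm(50 * 12, 8, 0.5), ncol = 12),
    matrix(rnorm(50 * 12, -8, 0.5), ncol = 12)
  )
  labels <- rep(1:3, each = 50)
  for (method in c("linear_projection", "neighbor_graph_nonlinear")) {
    e1 <- reduce_dimensionality(blobs, method, n_dims = 2, seed = 1)
    e2 <- reduce_dimensionality(blobs, method, n_dims = 2, seed = 1)
    expect_identical(e1, e2)
    expect_equal(dim(e1), c(150, 2))
    # blob separation survives: silhouette-style check via cluster distances
    within <- mean(sapply(1:3, function(k) {
      mean(dist(e1[labels == k, ]))
    }))
    between <- mean(dist(rowsum(e1, labels) / 50))
    expect_gt(between / within, 3)
  }
  # duplicate frames map to near-identical points
  dup <- rbind(blobs[1, ], blobs[1, ], blobs[2:20, ])
  ed <- reduce_dimensionality(dup, "neighbor_graph_nonlinear",
    n_dims = 2,
    seed = 1, n_neighbors = 5
  )
  expect_lt(sqrt(sum((ed[1, ] - ed[2, ])^2)), 1e-6)
  expect_error(reduce_dimensionality(blobs[1:2, ], n_dims = 2), "fewer frames")
})

test_that("the Gaussian mixture recovers planted partitions and normalises", {
  cx <- toy_complex(seed = 3)
  tr <- make_clustered_trajectory(cx,
    n_frames = 150, n_clusters = 3,
    separation = 8, noise_sigma = 0.1, seed = 4
  )
  m <- featurize(tr$trajectory, selection = "all", align = FALSE)
  emb <- reduce_dimensionality(m, "linear_projection", n_dims = 2, seed = 1)
  fit <- fit_gmm(emb, k = 3, seed = 1)
  expect_gte(mclust::adjustedRandIndex(fit$labels, tr$labels), 0.95)
  expect_equal(fit$n_clusters, 3)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
  # k = 1 labels everything identically
  f1 <- fit_gmm(emb, k = 1, seed = 1)
  expect_equal(unique(f1$labels), 1L)
  expect_error(fit_gmm(emb, k = 1000, seed = 1), "exceeds")
  # auto-k selects 3 on well-separated blobs and records the trace
  fa <- fit_gmm(emb, k = "auto", seed = 1)
  expect_equal(fa$n_clusters, 3)
  expect_s3_class(fa$criterion_trace, "tbl_df")
  expect_true(3 %in% fa$criterion_trace$k)
})

test_that("tidy and glance summarise the ensemble fit", {
  cx <- toy_complex(seed = 4)
  tr <- make_clustered_trajectory(cx, n_frames = 40, n_clusters = 2, seed = 5)
  emb <- reduce_dimensionality(
    featurize(tr$trajectory, selection = "all", align = FALSE),
    "linear_projection",
    n_dims = 2, seed = 1
  )
  fit <- fit_gmm(emb, k = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 40)
  expect_true(all(c("frame", "cluster", "uncertainty", "dim1", "dim2") %in% names(td)))
  expect_true(all(td$uncertainty >= 0 & td$uncertainty <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_frames, 40)
  expect_equal(gl$n_clusters, 2)
})

test_that("representative conformations are exact coordinate means", {
  cx <- toy_complex(seed = 5)
  f1 <- dplyr::filter(cx$structure, frame == 1)
  # cluster of identical frames returns the frame itself
  const <- dplyr::bind_rows(lapply(1:3, function(f) dplyr::mutate(f1, frame = f)))
  rep1 <- representative_conformations(const, rep(1L, 3), align = FALSE)
  expect_equal(rep1$x, f1$x, tolerance = 1e-12)
  expect_equal(nrow(rep1), nrow(f1))
  # two frames differing by +2 on one atom, align off -> midpoint
  f2 <- f1
  f2$x[3] <- f2$x[3] + 2
  pair <- dplyr::bind_rows(
    dplyr::mutate(f1, frame = 1),
    dplyr::mutate(f2, frame = 2)
  )
  rep2 <- representative_conformations(pair, c(1L, 1L), align = FALSE)
  expect_equal(rep2$x[3], f1$x[3] + 1, tolerance = 1e-12)
  # averaged coordinates equal column means of member feature rows
  tr <- make_clustered_trajectory(cx, n_frames = 12, n_clusters = 2, seed = 6)
  reps <- representative_conformations(tr$trajectory, tr$labels, align = FALSE)
  m <- featurize(tr$trajectory, selection = "all", align = FALSE)
  for (cl in 1:2) {
    cm <- colMeans(m[tr$labels == cl, , drop = FALSE])
    got <- as.numeric(t(as.matrix(
      dplyr::filter(reps, cluster == cl)[, c("x", "y", "z")]
    )))
    expect_equal(got, cm, tolerance = 1e-12)
  }
  expect_equal(unique(reps$cluster), c(1L, 2L))
})

test_that("conformer ranking orders by energy and flags the extrema", {
  r <- rank_conformers(c(b = -48.4, a = -54.8, c = -50.0))
  expect_equal(r$conformer, c("a", "c", "b"))
  expect_equal(r$energy[r$is_min], -54.8)
  expect_equal(r$energy[r$is_max], -48.4)
  single <- rank_conformers(c(only = -10))
  expect_true(single$is_min && single$is_max)
  # ties broken lexicographically
  tied <- rank_conformers(c(z = -5, a = -5, m = -7))
  expect_equal(tied$conformer, c("m", "a", "z"))
  expect_error(rank_conformers(numeric(0)), "empty")
})
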