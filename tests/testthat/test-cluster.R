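test_that("silhouette matches the hand-evaluated example", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  labs <- c("A", "A", "B", "B")
  hand <- mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(silhouette_score(pts, labs), hand, tolerance = 1e-12)
  expect_equal(round(silhouette_score(pts, labs), 4), 0.8997)
})

test_that("silhouette limits: coincident clusters and separated blobs", {
  set.seed(101)
  pts <- matrix(rnorm(60), 30, 2)
  # two 'clusters' drawn from the same cloud: no separation
  expect_lte(silhouette_score(pts, rep(c(1, 2), 15)), 0)
  # widely separated tight blobs approach 1
  blobs <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                 matrix(rnorm(40, 50, 0.1), 20, 2))
  expect_gt(silhouette_score(blobs, rep(c(1, 2), each = 20)), 0.99)
  expect_error(silhouette_score(pts, rep(1, 30)), "at least 2")
})

test_that("node_pca keeps the smallest sufficient component count", {
  set.seed(102)
  params <- cluster_tree_params()
  # rank-1 data plus tiny noise: one component reaches 90% variance
  u <- rnorm(100)
  M <- outer(u, c(1, 2, -1)) + matrix(rnorm(300, 0, 0.01), 100, 3)
  p1 <- node_pca(M, params)
  expect_equal(ncol(p1$projections), 1)
  # isotropic 5-D data: the cap of 3 components binds
  M2 <- matrix(rnorm(500), 100, 5)
  p2 <- node_pca(M2, params)
  expect_equal(ncol(p2$projections), 3)
  # projections are uncorrelated
  cc <- cor(p2$projections)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-9)
  # zero-variance node degenerates to a leaf signal
  expect_null(node_pca(matrix(1, 30, 3), params))
})

test_that("split_node accepts planted blobs and rejects a single blob", {
  params <- cluster_tree_params(seed = 5)
  set.seed(103)
  blobs <- rbind(matrix(rnorm(200, 0, 0.5), 100, 2),
                 matrix(rnorm(200, 6, 0.5), 100, 2))
  truth <- rep(1:2, each = 100)
  sp <- split_node(blobs, params)
  expect_true(sp$accepted)
  expect_gte(sp$silhouette, 0.4)
  expect_gte(adjusted_rand(sp$labels, truth), 0.95)
  # determinism: same node, same seed, identical children
  sp2 <- split_node(blobs, params)
  expect_identical(sp$labels, sp2$labels)

  # isotropic single blob: silhouette below the gate almost always
  rejections <- sum(vapply(1:20, function(i) {
    pts <- matrix(rnorm(400), 200, 2)
    !split_node(pts, params, node_seed = i)$accepted
  }, logical(1)))
  expect_gte(rejections, 16)
})

test_that("tiny child clusters disqualify a candidate k", {
  # 2 far outliers + tight mass: k = 2 would isolate a 2-point cluster
  pts <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
               matrix(c(50, 50, 50.1, 50.1), 2, 2, byrow = TRUE))
  params <- cluster_tree_params(candidate_k = 2, seed = 2)
  sp <- split_node(pts, params)
  expect_false(sp$accepted)
})

test_that("build_cluster_tree keeps partition integrity at every depth", {
  set.seed(104)
  A <- rbind(matrix(rnorm(400, 0), 200, 2),
             matrix(rnorm(400, 5), 200, 2),
             matrix(c(rnorm(200, 10), rnorm(200, 0)), 200, 2))
  colnames(A) <- c("s1", "s2")
  y <- rbinom(600, 1, rep(c(0.02, 0.3, 0.1), each = 200))
  attr <- dentshap:::new_attribution_matrix(A, 0, rowSums(A), A, "external")
  tree <- build_cluster_tree(attr, y, cluster_tree_params(seed = 3))

  la <- leaf_assignments(tree)
  expect_equal(sort(la$instance), 1:600)          # no instance lost/duplicated
  expect_equal(anyDuplicated(la$instance), 0)

  # silhouette gate on every internal node
  internal <- dentshap:::collect_internal(tree$root)
  expect_gt(length(internal), 0)
  for (nd in internal) {
    expect_gte(nd$silhouette, tree$params$min_silhouette)
    members <- sort(unlist(lapply(nd$children, `[[`, "member_indices")))
    expect_equal(members, sort(nd$member_indices)) # children partition parent
    for (ch in nd$children)
      expect_lt(length(ch$member_indices), length(nd$member_indices))
  }

  # labels follow the prevalence factors
  overall <- mean(y)
  for (l in dentshap:::collect_leaves(tree$root)) {
    expected <- if (l$prevalence >= 2 * overall) "high"
      else if (l$prevalence <= 0.5 * overall) "low" else "average"
    expect_equal(l$label, expected)
  }
})

test_that("max_depth 0 yields a single average leaf at overall prevalence", {
  set.seed(105)
  A <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, 0.3)
  attr <- dentshap:::new_attribution_matrix(A, 0, rowSums(A), A, "external")
  tree <- build_cluster_tree(attr, y, cluster_tree_params(max_depth = 0))
  expect_length(tree$root$children, 0)
  expect_equal(tree$root$label, "average")
  expect_equal(tree$root$prevalence, mean(y))
  expect_error(build_cluster_tree(attr, rep(0, 100)), "strictly")
})

test_that("clustering SHAP separates a planted subgroup better than raw features", {
  # the subgroup differs on 2 low-variance coordinates while 8 irrelevant
  # coordinates carry twice the spread; variance-driven PCA + k-means on
  # raw features chases the noise, whereas a model's attributions amplify
  # exactly the outcome-relevant coordinates and mute the rest -- the
  # supervision advantage clustering in SHAP space is for
  set.seed(106)
  n <- 400
  sub <- rep(c(TRUE, FALSE), c(120, 280))
  raw <- cbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 8, 0, 2), n, 8))
  raw[sub, 1:2] <- raw[sub, 1:2] + 2.5
  colnames(raw) <- paste0("r", 1:10)
  shap_like <- cbind(3 * raw[, 1:2], 0.05 * raw[, 3:10])
  colnames(shap_like) <- paste0("s", 1:10)
  params <- cluster_tree_params(seed = 4, min_silhouette = 0.0,
                                candidate_k = 2, max_depth = 1)
  km_raw <- split_node(node_pca(raw, params)$projections, params)
  km_shap <- split_node(node_pca(shap_like, params)$projections, params)
  expect_gt(adjusted_rand(km_shap$labels, sub),
            adjusted_rand(km_raw$labels, sub) + 0.3)
})

test_that("summarize_high_prevalence ranks the driving feature first", {
  set.seed(107)
  n <- 300
  A <- matrix(rnorm(n * 3, 0, 0.05), n, 3,
              dimnames = list(NULL, c("driver", "f2", "f3")))
  grp <- 1:100
  A[grp, "driver"] <- A[grp, "driver"] + 2
  y <- integer(n); y[grp] <- rbinom(100, 1, 0.5)
  y[-grp] <- rbinom(200, 1, 0.02)
  attr <- dentshap:::new_attribution_matrix(A, 0, rowSums(A), A, "external")
  tree <- build_cluster_tree(attr, y, cluster_tree_params(seed = 6))
  drv <- summarize_high_prevalence(tree, attr, top_n = 3)
  expect_gt(nrow(drv), 0)
  top_per_leaf <- drv$feature[drv$rank == 1]
  expect_true(all(top_per_leaf == "driver"))

  # permutation invariance of the ranking
  perm <- c(3, 1, 2)
  attr_p <- dentshap:::new_attribution_matrix(
    A[, perm], 0, rowSums(A), A[, perm], "external")
  tree_p <- build_cluster_tree(attr_p, y, cluster_tree_params(seed = 6))
  drv_p <- summarize_high_prevalence(tree_p, attr_p, top_n = 3)
  expect_true(all(drv_p$feature[drv_p$rank == 1] == "driver"))

  # no high leaf -> empty result, not an error
  flat <- dentshap:::new_attribution_matrix(
    matrix(rnorm(200, 0, 0.01), 100, 2, dimnames = list(NULL, c("a", "b"))),
    0, rnorm(100), matrix(rnorm(200), 100, 2), "external")
  ytame <- rbinom(100, 1, 0.5)
  t2 <- build_cluster_tree(flat, ytame, cluster_tree_params(max_depth = 0))
  expect_equal(nrow(summarize_high_prevalence(t2, flat)), 0)
})

test_that("cluster trees serialize to JSON with members and labels", {
  set.seed(108)
  A <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 6), 100, 2))
  colnames(A) <- c("u", "v")
  y <- rbinom(200, 1, rep(c(0.05, 0.4), each = 100))
  attr <- dentshap:::new_attribution_matrix(A, 0, rowSums(A), A, "external")
  tree <- build_cluster_tree(attr, y, cluster_tree_params(seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_tree(tree, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n, 200)
  expect_equal(sort(back$root$member_indices), 1:200)
  expect_equal(back$params$min_silhouette, 0.4)
})
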