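test_that("exact linear relations give unit correlations", {
  x <- 1:10
  M <- cbind(x = x, up = 2 * x + 1, down = -x)
  res <- correlation_analysis(M)
  expect_equal(res$r["x", "up"], 1, tolerance = 1e-12)
  expect_equal(res$r["x", "down"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 3))
})

test_that("correlations and p-values match the covariance-ratio oracle", {
  set.seed(50)
  M <- matrix(rnorm(24 * 8), 24, 8)
  colnames(M) <- paste0("v", 1:8)
  res <- correlation_analysis(M)
  for (i in 1:7) for (j in (i + 1):8) {
    xi <- M[, i]; xj <- M[, j]
    r_manual <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(res$r[i, j], r_manual, tolerance = 1e-12)
    ct <- cor.test(xi, xj)
    expect_equal(res$p[i, j], unname(ct$p.value), tolerance = 1e-10)
  }
  # correlation matrices are positive semi-definite
  expect_gt(min(eigen(res$r, symmetric = TRUE)$values), -1e-10)
})

test_that("constant columns are flagged, not silently dropped", {
  M <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(res <- correlation_analysis(M), "b")
  expect_true(all(is.na(res$r["b", ])))
  expect_identical(res$constant, "b")
})

test_that("PCA explains variance as expected in degenerate geometries", {
  # rank-1 data: one component carries everything
  t <- seq(-1, 1, length.out = 20)
  M <- cbind(a = 3 * t, b = -2 * t, c = 0.5 * t)
  p <- suppressWarnings(pca_responses(M, standardize = FALSE))
  expect_equal(p$explained[1], 100, tolerance = 1e-8)
  expect_equal(sum(p$explained), 100, tolerance = 1e-10)

  # two independent equal-variance variables: ~50/50 at large n
  set.seed(77)
  M2 <- cbind(x = rnorm(500), y = rnorm(500))
  p2 <- pca_responses(M2)
  expect_equal(p2$explained[1], 50, tolerance = 5)
})

test_that("PCA is rotation-invariant and contributions are signed shares", {
  set.seed(12)
  M <- matrix(rnorm(30 * 5), 30, 5)
  p <- pca_responses(M, standardize = FALSE)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  p_rot <- pca_responses(M %*% Q, standardize = FALSE)
  expect_equal(p$explained, p_rot$explained, tolerance = 1e-8)

  expect_equal(unname(colSums(abs(p$contributions))),
               rep(100, ncol(p$contributions)), tolerance = 1e-10)
  expect_equal(sign(p$contributions), sign(p$loadings))
  # scores' variances equal the eigenvalues, components uncorrelated
  expect_equal(unname(apply(p$scores, 2, var)), unname(p$sdev^2),
               tolerance = 1e-10)
  cc <- cor(p$scores[, 1:3])
  expect_equal(cc[upper.tri(cc)], rep(0, 3), tolerance = 1e-8)
})

test_that("clustering separates well-separated clouds and is order-stable", {
  set.seed(5)
  A <- matrix(rnorm(10 * 3, mean = 0, sd = 0.1), 10, 3)
  B <- matrix(rnorm(10 * 3, mean = 8, sd = 0.1), 10, 3)
  M <- rbind(A, B)
  tree <- hierarchical_cluster(M, standardize = FALSE)
  k2 <- cut_clusters(tree, 2)
  expect_equal(length(unique(k2[1:10])), 1)
  expect_equal(length(unique(k2[11:20])), 1)
  expect_false(k2[1] == k2[11])
  # complete linkage heights are monotone along merges
  expect_true(all(diff(tree$hclust$height) >= -1e-12))

  perm <- sample(20)
  tree_p <- hierarchical_cluster(M[perm, ], standardize = FALSE)
  expect_equal(sort(tree_p$hclust$height), sort(tree$hclust$height),
               tolerance = 1e-10)
})

test_that("tiny and duplicated inputs merge as expected", {
  M <- rbind(c(0, 0), c(3, 4))
  tree <- hierarchical_cluster(M, standardize = FALSE)
  expect_equal(tree$hclust$height, 5)
  M3 <- rbind(c(0, 0), c(0, 0), c(9, 9))
  tree3 <- hierarchical_cluster(M3, standardize = FALSE)
  expect_equal(tree3$hclust$height[1], 0)
  expect_error(hierarchical_cluster(M, metric = "cosine"), "metric")
  expect_error(hierarchical_cluster(M, linkage = "banana"), "linkage")
})

test_that("trees serialize to merge-list JSON and Newick", {
  d <- small_synth(seed = 61, replicates = 1)
  tree <- hierarchical_cluster(d$responses)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_tree(tree, path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(length(o$height), 23)
  nwk <- cluster_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
})
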