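test_that("size factors have the closed form under exact proportionality", {
  mat <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("t1", "t2")))
  sf <- size_factors(mat)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  norm <- normalize_expression(mat, sf)
  expect_equal(norm[, 1], norm[, 2])
})

test_that("identical columns give unit factors and scaling is homogeneous", {
  set.seed(81)
  v <- rlnorm(20)
  mat <- cbind(t1 = v, t2 = v, t3 = v)
  rownames(mat) <- paste0("g", 1:20)
  expect_equal(unname(size_factors(mat)), rep(1, 3))
  mat2 <- matrix(rlnorm(60), 20, 3,
                 dimnames = list(paste0("g", 1:20), paste0("t", 1:3)))
  ## median-of-ratios factors are invariant under a global rescale (the
  ## gene-wise geometric means absorb it), so normalized values scale
  expect_equal(size_factors(mat2 * 7), size_factors(mat2))
  expect_equal(normalize_expression(mat2 * 7),
               7 * normalize_expression(mat2))
})

test_that("genes with zeros are excluded from the reference set", {
  mat <- matrix(c(0, 2, 4, 0, 4, 8), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("t1", "t2")))
  sf <- size_factors(mat)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  allzero <- matrix(c(0, 1, 1, 0), 2, 2,
                    dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(size_factors(allzero), "pseudocount")
  expect_length(size_factors(allzero, pseudocount = 0.5), 2L)
})

test_that("size factors agree with the reference estimator", {
  set.seed(86)
  ## odd reference-gene count so the linear and log-space medians coincide
  mat <- matrix(rlnorm(41 * 5, meanlog = 2), 41, 5,
                dimnames = list(paste0("g", 1:41), paste0("t", 1:5)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(size_factors(mat)), unname(ref), tolerance = 1e-8)
})

test_that("k-means recovers well-separated blobs up to label permutation", {
  gen <- gen_expression(n_genes = 60, seed = 82)
  fit <- kmeans_cluster(normalize_expression(gen$mat), k = 3, seed = 9)
  lab <- classify_expression_levels(fit)
  expect_identical(unname(lab$labels), unname(gen$truth))
  expect_true(all(diff(fit$wss) <= 1e-9))
})

test_that("k-means matches stats::kmeans at its converged fixed point", {
  ## cross-check: our Lloyd iteration and the stock implementation agree
  ## on the partition when started from our converged centers
  gen <- gen_expression(n_genes = 45, seed = 83)
  mat <- normalize_expression(gen$mat)
  fit <- kmeans_cluster(mat, k = 3, seed = 5)
  ref <- stats::kmeans(mat[order(rownames(mat)), ], centers = fit$centers,
                       algorithm = "Lloyd", iter.max = 2)
  expect_identical(unname(ref$cluster), unname(fit$cluster))
})

test_that("k = 1 gives the column means and k > n errors", {
  gen <- gen_expression(n_genes = 10, seed = 84)
  fit <- kmeans_cluster(gen$mat, k = 1, seed = 1)
  expect_equal(fit$centers[1, ], colMeans(gen$mat))
  expect_error(kmeans_cluster(gen$mat, k = 11), "exceeds")
})

test_that("clustering is invariant to input row order", {
  gen <- gen_expression(n_genes = 30, seed = 85)
  mat <- normalize_expression(gen$mat)
  f1 <- kmeans_cluster(mat, k = 3, seed = 2)
  f2 <- kmeans_cluster(mat[rev(seq_len(nrow(mat))), ], k = 3, seed = 2)
  expect_identical(f1$cluster, f2$cluster)
})

test_that("expression level labels rank by centroid magnitude", {
  fit <- list(cluster = stats::setNames(c(1L, 2L, 3L), c("a", "b", "c")),
              centers = rbind(rep(10, 4), rep(0.1, 4), rep(1, 4)))
  lab <- classify_expression_levels(fit)
  expect_identical(unname(lab$cluster_labels),
                   c("moderate-to-minimal", "basal-to-none",
                     "minimal-to-basal"))
  ## ties broken by cluster index
  fit$centers <- rbind(rep(1, 4), rep(1, 4), rep(5, 4))
  lab2 <- classify_expression_levels(fit)
  expect_identical(unname(lab2$cluster_labels),
                   c("minimal-to-basal", "basal-to-none",
                     "moderate-to-minimal"))
  expect_error(classify_expression_levels(
    list(cluster = 1L, centers = matrix(1, 2, 2))), "k = 3")
})
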