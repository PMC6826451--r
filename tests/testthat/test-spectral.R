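# Spectral clustering: Laplacian structure, eigengap, embedding, Lloyd
# k-means, silhouettes.

block_adjacency <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  W <- matrix(between, n, n)
  W[outer(lab, lab, "==")] <- within
  diag(W) <- 0
  dimnames(W) <- list(paste0("n", 1:n), paste0("n", 1:n))
  W
}

test_that("normalized Laplacian of disjoint cliques has null multiplicity q", {
  for (q in 2:4) {
    W <- block_adjacency(rep(3, q))
    spec <- eigenspectrum(normalized_laplacian(W))
    expect_equal(sum(spec$values < 1e-10), q)
    expect_true(all(spec$values > -1e-10 & spec$values < 2 + 1e-10))
  }
})

test_that("a single edge gives the K2 spectrum {0, 2}", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(eigenspectrum(normalized_laplacian(W))$values, c(0, 2))
})

test_that("Laplacian rejects invalid adjacencies", {
  W <- block_adjacency(c(2, 2))
  W[1, ] <- W[, 1] <- 0
  expect_error(normalized_laplacian(W), "zero-degree")
  expect_error(normalized_laplacian(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(eigenspectrum(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("eigenspectrum is ascending, orthonormal and sign-canonical", {
  set.seed(51)
  A <- matrix(rnorm(64), 8, 8); A <- (A + t(A)) / 2
  spec <- eigenspectrum(A)
  expect_false(is.unsorted(spec$values))
  expect_equal(crossprod(spec$vectors), diag(8), tolerance = 1e-10)
  for (j in 1:8) {
    i <- which.max(abs(spec$vectors[, j]))
    expect_gt(spec$vectors[i, j], 0)
  }
  D <- diag(c(3, 1, 2))
  expect_equal(eigenspectrum(D)$values, c(1, 2, 3))
})

test_that("eigengap rule finds the largest gap, ties to the largest k", {
  ev <- c(0, 0.01, 0.02, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75, 0.8,
          0.85, 0.9, 0.95, 1, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3, 1.35)
  expect_equal(as.integer(suggest_k(ev)), 3)
  gaps <- attr(suggest_k(ev), "gaps")
  expect_equal(gaps$gap[gaps$k == 3], 0.48)
  for (q in 2:4) {
    W <- block_adjacency(rep(4, q), within = 1, between = 0)
    spec <- eigenspectrum(normalized_laplacian(W))
    expect_equal(as.integer(suggest_k(spec, k_max = 6)), q)
  }
  expect_warning(k <- suggest_k(seq(0, 2, length.out = 30), k_max = 10),
                 "flat")
  expect_equal(as.integer(k), 10)   # tie-break to the largest index
})

test_that("embedding rows are unit-norm and degenerate rows are flagged", {
  W <- block_adjacency(c(4, 4), within = 1, between = 0.05)
  spec <- eigenspectrum(normalized_laplacian(W))
  emb <- spectral_embedding(spec, 2)
  expect_equal(unname(sqrt(rowSums(emb$T^2))), rep(1, 8), tolerance = 1e-12)
  expect_length(emb$degenerate_rows, 0)
  emb1 <- spectral_embedding(spec, 1)
  expect_true(all(abs(abs(emb1$T[, 1]) - 1) < 1e-12))
  expect_error(spectral_embedding(spec, 9), "exceeds")
  # synthetic degenerate row
  spec$vectors[3, ] <- 0
  emb2 <- spectral_embedding(spec, 2)
  expect_equal(emb2$degenerate_rows, 3L)
  expect_equal(unname(emb2$T[3, ]), c(1, 0))
})

test_that("Lloyd k-means recovers separated blobs and is deterministic", {
  set.seed(52)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  pts <- do.call(rbind, lapply(1:3, function(c) {
    sweep(matrix(rnorm(20, sd = 0.3), 10, 2), 2, centers[c, ], "+")
  }))
  truth <- rep(1:3, each = 10)
  km <- kmeans_lloyd(pts, 3)
  expect_equal(length(unique(km$labels)), 3)
  # blob recovery up to label permutation
  expect_equal(mclust::adjustedRandIndex(km$labels, truth), 1)
  # k = N: every point its own centroid, SSE 0
  kmN <- kmeans_lloyd(pts[1:5, ], 5, n_init = 2)
  expect_equal(kmN$sse, 0)
  # determinism under a fixed seed
  set.seed(9); a <- kmeans_lloyd(pts, 3)
  set.seed(9); b <- kmeans_lloyd(pts, 3)
  expect_identical(a$labels, b$labels)
  expect_error(kmeans_lloyd(pts, 31), "exceeds")
})

test_that("best-of-restarts SSE matches exhaustive partition search", {
  set.seed(53)
  for (r in 1:5) {
    pts <- matrix(rnorm(14), 7, 2)
    for (k in 2:3) {
      km <- kmeans_lloyd(pts, k, n_init = 100)
      expect_lte(km$sse, oracle_best_sse(pts, k) + 1e-8)
    }
  }
})

test_that("k-means SSE agrees with the stats::kmeans reference on blobs", {
  set.seed(54)
  pts <- rbind(matrix(rnorm(20, 0, .2), 10, 2),
               matrix(rnorm(20, 5, .2), 10, 2))
  km <- kmeans_lloyd(pts, 2)
  ref <- stats::kmeans(pts, 2, nstart = 5)
  expect_equal(km$sse, ref$tot.withinss, tolerance = 1e-8)
})

test_that("silhouette reproduces the hand-worked example in both norms", {
  pts <- matrix(c(0.0, 0.1, 1.0), ncol = 1)
  lab <- c(1, 1, 2)
  paper <- silhouette_values(pts, lab, "paper")
  # a(0.0) = 0.1/2 = 0.05, b = 1.0 -> s = 0.95; singleton gets 0
  expect_equal(paper$s, c(0.95, (0.9 - 0.05) / 0.9, 0))
  std <- silhouette_values(pts, lab, "standard")
  expect_equal(std$a[1], 0.1)     # divisor N_k - 1
  expect_equal(std$s[1], 0.9)
  expect_error(silhouette_values(pts, c(1, 1, 1)), "2 clusters")
})

test_that("standard silhouette matches the cluster-package reference", {
  set.seed(55)
  for (r in 1:10) {
    pts <- matrix(rnorm(40), 20, 2)
    lab <- sample(1:3, 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ours <- silhouette_values(pts, lab, "standard")
    expect_equal(ours$s, oracle_silhouette(pts, lab), tolerance = 1e-12)
    expect_true(all(ours$s >= -1 & ours$s <= 1))
  }
})

test_that("mirror-symmetric clusters give symmetric silhouettes", {
  pts <- matrix(c(-2, -1, 1, 2), ncol = 1)
  s <- silhouette_values(pts, c(1, 1, 2, 2), "paper")$s
  expect_equal(s[1:2], rev(s[3:4]))
})

test_that("planted blocks are recovered through the full spectral path", {
  set.seed(56)
  W <- block_adjacency(c(10, 8, 12), within = 0.9, between = 0.02)
  W <- W * matrix(runif(900, 0.8, 1.2), 30, 30)
  W <- (W + t(W)) / 2; diag(W) <- 0
  res <- spectral_cluster(W)
  expect_equal(res$suggested_k, 3)
  truth <- rep(1:3, c(10, 8, 12))
  expect_equal(mclust::adjustedRandIndex(res$labels$cluster, truth), 1)
  expect_true(all(res$silhouette$s >= -1 & res$silhouette$s <= 1))
  # cluster names are C0.. by decreasing size
  expect_equal(names(sort(table(res$labels$cluster), decreasing = TRUE)),
               c("C0", "C1", "C2"))
  g <- glance(res)
  expect_equal(g$k, 3)
  expect_equal(g$n, 30)
  td <- tidy(res)
  expect_equal(nrow(td), 30)
  expect_true(all(c("cluster", "silhouette", "dim1", "dim2") %in% names(td)))
})
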