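# spectral_clustering: normalized Laplacian, eigengap k-selection,
# eigenvector embedding, Lloyd k-means, silhouettes.

#' Normalized symmetric Laplacian of a weighted adjacency
#'
#' `L_sym = D^{-1/2} (D - W) D^{-1/2}` with the degree matrix
#' `D = diag(rowSums(W))`. Its spectrum lies in `[0, 2]`; the multiplicity
#' of the null eigenvalue equals the number of connected components.
#'
#' @param W symmetric non-negative matrix with zero diagonal and no
#'   zero-degree nodes (drop isolated nodes first, see
#'   [build_adjacency()]).
#' @return Symmetric numeric matrix.
#' @export
normalized_laplacian <- function(W) {
  if (inherits(W, "igs_adjacency")) W <- W$W
  if (!isTRUE(all.equal(W, t(W)))) stop("W must be symmetric")
  if (any(W < 0)) stop("W must be non-negative")
  d <- rowSums(W)
  if (any(d == 0)) stop("zero-degree node; drop isolated nodes before the Laplacian")
  inv_sqrt_d <- 1 / sqrt(d)
  L <- -W * tcrossprod(inv_sqrt_d)
  diag(L) <- 1
  dimnames(L) <- dimnames(W)
  (L + t(L)) / 2
}

#' Full eigendecomposition of a symmetric matrix, ascending
#'
#' Eigenvalues in ascending order with orthonormal eigenvectors as columns.
#' Eigenvector signs are canonicalized (largest-magnitude entry positive)
#' so embeddings are reproducible.
#'
#' @param L symmetric matrix.
#' @param tol asymmetry tolerance.
#' @return List of class `laplacian_spectrum`: `values` (ascending),
#'   `vectors` (columns matching `values`), `ids`.
#' @export
eigenspectrum <- function(L, tol = 1e-8) {
  if (max(abs(L - t(L))) > tol) stop("matrix is not symmetric")
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(e$values))     # eigen() returns descending
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  structure(list(values = values, vectors = vectors,
                 ids = rownames(L) %||% as.character(seq_len(nrow(L)))),
            class = "laplacian_spectrum")
}

#' Suggest a cluster number from the eigengap
#'
#' Chooses `k` in `2..k_max` maximizing the gap `lambda[k+1] - lambda[k]`
#' of the ascending Laplacian spectrum: the further the first k eigenvalues
#' sit from the rest, the cleaner the separation into k groups. Ties are
#' broken towards the largest k; a perfectly flat gap profile triggers a
#' warning. The suggestion is advisory — inspect the gap table and
#' override where cluster-level evidence (e.g. composition profiles)
#' favours another k.
#'
#' @param eigenvalues ascending eigenvalues (or a `laplacian_spectrum`).
#' @param k_max largest k considered (default 20, capped at N - 1).
#' @return Integer k, with the gap table in attribute `"gaps"`.
#' @export
suggest_k <- function(eigenvalues, k_max = 20L) {
  if (inherits(eigenvalues, "laplacian_spectrum")) {
    eigenvalues <- eigenvalues$values
  }
  k_max <- min(k_max, length(eigenvalues) - 1L)
  if (k_max < 2L) stop("need at least 3 eigenvalues")
  ks <- 2:k_max
  gaps <- eigenvalues[ks + 1L] - eigenvalues[ks]
  best <- max(ks[gaps >= max(gaps) - 1e-12])
  if (diff(range(gaps)) < 1e-12) {
    warning("flat eigengap profile; k defaulting to k_max = ", k_max)
  }
  structure(as.integer(best), gaps = tibble(k = ks, gap = gaps))
}

#' Row-normalized spectral embedding
#'
#' Takes the first k eigenvectors as columns of `U` and normalizes each row
#' to unit Euclidean norm. Degenerate all-zero rows are assigned the first
#' canonical unit vector and flagged.
#'
#' @param spectrum a `laplacian_spectrum` from [eigenspectrum()].
#' @param k embedding dimension.
#' @return List of class `spectral_embedding`: `U`, `T` (unit rows),
#'   `degenerate_rows`, `ids`.
#' @export
spectral_embedding <- function(spectrum, k) {
  N <- nrow(spectrum$vectors)
  if (k > N) stop("k exceeds the number of points")
  if (k < 1L) stop("k must be >= 1")
  U <- spectrum$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  degenerate <- which(norms == 0)
  Tm <- U / ifelse(norms == 0, 1, norms)
  if (length(degenerate)) {
    Tm[degenerate, ] <- 0
    Tm[degenerate, 1] <- 1
  }
  rownames(Tm) <- rownames(U) <- spectrum$ids
  structure(list(U = U, T = Tm, degenerate_rows = degenerate,
                 ids = spectrum$ids),
            class = "spectral_embedding")
}

#' Lloyd k-means with tolerance-based convergence
#'
#' Initial centroids are sampled from the points; each Lloyd iteration
#' assigns points to the nearest centroid (Euclidean) and recomputes
#' centroids, stopping when the largest centroid displacement falls below
#' `tol`. An emptied cluster is reseeded at the point farthest from its
#' assigned centroid. The best of `n_init` restarts by within-cluster sum
#' of squares is returned.
#'
#' @param points numeric matrix, one row per point.
#' @param k number of clusters (must not exceed the number of distinct
#'   points).
#' @param tol centroid-displacement convergence tolerance (default 1e-8).
#' @param n_init random restarts (default 10).
#' @param max_iter safety cap per restart.
#' @return List: `labels` (0-based cluster indices), `centroids`, `sse`.
#' @export
kmeans_lloyd <- function(points, k, tol = 1e-8, n_init = 10L,
                         max_iter = 1000L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k exceeds the number of points")
  if (k > nrow(unique(points))) stop("k exceeds the number of distinct points")

  sq_dist <- function(P, C) {
    # n x k matrix of squared Euclidean distances
    outer(rowSums(P^2), rep(1, nrow(C))) - 2 * P %*% t(C) +
      outer(rep(1, nrow(P)), rowSums(C^2))
  }
  one_run <- function() {
    cent <- points[sample(n, k), , drop = FALSE]
    for (iter in seq_len(max_iter)) {
      D2 <- sq_dist(points, cent)
      lab <- max.col(-D2, ties.method = "first")
      new_cent <- cent
      for (c in seq_len(k)) {
        members <- which(lab == c)
        if (!length(members)) {
          # reseed an emptied cluster at the farthest point from its centroid
          far <- which.max(D2[cbind(seq_len(n), lab)])
          new_cent[c, ] <- points[far, ]
          lab[far] <- c
        } else {
          new_cent[c, ] <- colMeans(points[members, , drop = FALSE])
        }
      }
      shift <- max(abs(new_cent - cent))
      cent <- new_cent
      if (shift < tol) break
    }
    lab <- max.col(-sq_dist(points, cent), ties.method = "first")
    sse <- sum((points - cent[lab, , drop = FALSE])^2)
    list(labels = lab, centroids = cent, sse = sse)
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    run <- one_run()
    if (is.null(best) || run$sse < best$sse) best <- run
  }
  best$labels <- best$labels - 1L
  best
}

#' Per-point silhouette values
#'
#' For point i in cluster `C_k`: `a(i)` is the mean distance to the other
#' members of its own cluster, `b(i)` the smallest mean distance to any
#' other cluster, and `s(i) = (b - a) / max(a, b)`. Two intra-cluster
#' normalizations are offered: `"paper"` divides the sum over the other
#' `N_k - 1` members by `N_k`; `"standard"` divides by `N_k - 1` (the
#' textbook definition). Singleton clusters get `s(i) = 0`.
#'
#' @param points numeric matrix (Euclidean metric).
#' @param labels integer cluster labels, one per row of `points`.
#' @param normalization `"paper"` (default) or `"standard"`.
#' @return Tibble: `id` (rownames or index), `cluster`, `a`, `b`, `s`.
#' @export
silhouette_values <- function(points, labels,
                              normalization = c("paper", "standard")) {
  normalization <- match.arg(normalization)
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(length(labels) == n)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stop("silhouettes need at least 2 clusters")
  D <- as.matrix(stats::dist(points))
  sizes <- table(factor(labels, levels = clusters))
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    nk <- sizes[[as.character(own)]]
    if (nk == 1L) { a[i] <- 0; b[i] <- 0; s[i] <- 0; next }
    intra <- sum(D[i, labels == own])          # d(i,i)=0 excludes i itself
    a[i] <- intra / if (normalization == "paper") nk else nk - 1L
    b[i] <- min(vapply(clusters[clusters != own], function(h) {
      mean(D[i, labels == h])
    }, numeric(1)))
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  tibble(id = rownames(points) %||% as.character(seq_len(n)),
         cluster = labels, a = a, b = b, s = s)
}

#' Spectral clustering of an IGS adjacency
#'
#' Runs the whole clustering stage: normalized Laplacian, eigenspectrum,
#' eigengap suggestion of k (unless `k` is fixed), row-normalized
#' k-eigenvector embedding, Lloyd k-means, silhouettes. Clusters are named
#' `C0, C1, ...` in decreasing size order.
#'
#' @param adjacency an `igs_adjacency` from [build_adjacency()] (or a bare
#'   weighted adjacency matrix).
#' @param k number of clusters, or `NULL` to use the eigengap suggestion.
#' @param k_max largest k considered by the eigengap rule.
#' @param tol k-means convergence tolerance.
#' @param n_init k-means restarts.
#' @param silhouette_normalization see [silhouette_values()].
#' @return Object of class `igs_clustering`: `labels` tibble (`id`,
#'   `cluster`), `k`, `suggested_k`, `eigenvalues`, `gap_table`,
#'   `embedding`, `centroids`, `silhouette` tibble, `unclustered_ids`.
#' @export
spectral_cluster <- function(adjacency, k = NULL, k_max = 20L, tol = 1e-8,
                             n_init = 10L,
                             silhouette_normalization = "paper") {
  unclustered <- character()
  if (inherits(adjacency, "igs_adjacency")) {
    unclustered <- adjacency$unclustered_ids
    W <- adjacency$W
  } else W <- adjacency
  L <- normalized_laplacian(W)
  spec <- eigenspectrum(L)
  suggested <- suggest_k(spec, k_max = k_max)
  k <- k %||% as.integer(suggested)
  emb <- spectral_embedding(spec, k)
  km <- kmeans_lloyd(emb$T, k, tol = tol, n_init = n_init)
  # stable naming: C0 is the largest cluster
  size_order <- order(tabulate(km$labels + 1L, nbins = k), decreasing = TRUE)
  remap <- integer(k); remap[size_order] <- seq_len(k) - 1L
  lab <- remap[km$labels + 1L]
  sil <- silhouette_values(emb$T, lab,
                           normalization = silhouette_normalization)
  structure(list(
    labels = tibble(id = emb$ids, cluster = paste0("C", lab)),
    k = k, suggested_k = as.integer(suggested),
    eigenvalues = spec$values, gap_table = attr(suggested, "gaps"),
    embedding = emb$T, centroids = km$centroids,
    silhouette = mutate(sil, cluster = paste0("C", .data$cluster)),
    unclustered_ids = unclustered
  ), class = "igs_clustering")
}

#' @export
print.igs_clustering <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  cat(sprintf("<igs_clustering> k=%d (eigengap suggested %d), N=%d\n",
              x$k, x$suggested_k, nrow(x$labels)))
  cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "),
      "\n")
  cat(sprintf("  mean silhouette: %.3f\n", mean(x$silhouette$s)))
  invisible(x)
}
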