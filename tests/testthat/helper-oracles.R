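# Independent oracles used by the tests. These deliberately re-derive
# results by a different route from the package implementation: a naive
# dynamic-programming aligner, exhaustive graph/partition enumeration, and
# textbook formulas.

# --- naive affine-gap alignment (Gotoh), plain R ---------------------------
# Gap of length k costs gap_open + (k - 1) * gap_extend. `mode = "global"`
# charges nothing for leading/trailing gaps and maximizes over the last row
# and column; `mode = "local"` is Smith-Waterman.
oracle_align <- function(a, b, mode = c("global", "local"),
                         gap_open = 10, gap_extend = 0.5,
                         sub = igsclust::ednafull_matrix()) {
  mode <- match.arg(mode)
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)  # X: gap in b, Y: gap in a
  S <- matrix(NEG, n + 1, m + 1)
  local <- mode == "local"
  S[1, ] <- 0; S[, 1] <- 0                  # free end gaps / local zero floor
  best_local <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- sub[A[i - 1], B[j - 1]] + S[i - 1, j - 1]
      X[i, j] <- max(S[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(S[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
      S[i, j] <- max(M[i, j], X[i, j], Y[i, j])
      if (local) S[i, j] <- max(S[i, j], 0)
      if (local) best_local <- max(best_local, S[i, j])
    }
  }
  if (local) best_local else max(S[n + 1, ], S[, m + 1])
}

# --- textbook silhouette ----------------------------------------------------
oracle_silhouette <- function(points, labels) {
  sil <- cluster::silhouette(labels, stats::dist(points))
  as.numeric(sil[, "sil_width"])
}

# --- exhaustive best k-means partition --------------------------------------
oracle_best_sse <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  assignments <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(assignments))) {
    lab <- as.integer(assignments[r, ])
    if (length(unique(lab)) < k) next
    sse <- sum(vapply(seq_len(k), function(c) {
      p <- points[lab == c, , drop = FALSE]
      sum(sweep(p, 2, colMeans(p))^2)
    }, numeric(1)))
    best <- min(best, sse)
  }
  best
}

# --- brute-force connected components (BFS over an edge list) ---------------
oracle_lcc <- function(nodes, edges) {
  # edges: 2-column character matrix; returns list(n_lcc, n_link)
  if (!length(nodes)) stop("no nodes")
  comp <- setNames(seq_along(nodes), nodes)
  if (nrow(edges)) {
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        c1 <- comp[edges[e, 1]]; c2 <- comp[edges[e, 2]]
        if (c1 != c2) { comp[comp == c2] <- c1; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  sizes <- table(comp)
  best_size <- max(sizes)
  cands <- names(sizes)[sizes == best_size]
  n_link <- vapply(cands, function(c) {
    members <- names(comp)[comp == as.integer(c)]
    sum(edges[, 1] %in% members & edges[, 2] %in% members)
  }, numeric(1))
  list(n_lcc = as.integer(best_size), n_link = as.integer(max(n_link)))
}

# --- shared fixtures --------------------------------------------------------
random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# A tiny two-gene linear annotation used across IO/extraction tests.
tiny_annotation <- function(topology = "linear", len = 1000L) {
  set.seed(99)
  genome_annotation(
    "tiny", random_dna(len),
    tibble::tibble(gene_id = c("gA", "gB"),
                   start = c(0L, 500L), end = c(300L, 800L),
                   strand = c("+", "+")),
    topology = topology
  )
}
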