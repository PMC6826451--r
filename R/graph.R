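# similarity_graph: shuffling-based threshold estimation and the thresholded,
# normalized weighted adjacency.

#' Randomly reorder the nucleotides of a sequence
#'
#' Uniform random permutation of the characters; length and base
#' composition are preserved exactly.
#'
#' @param seq nucleotide string.
#' @return Shuffled string.
#' @export
shuffle_sequence <- function(seq) {
  if (!nchar(seq)) stop("empty sequence")
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

#' Similarity threshold from whole-set shuffling
#'
#' Each iteration shuffles every sequence, scores all pairs (optionally a
#' random subsample of pairs) and takes the arithmetic mean; the threshold
#' is the mean of the iteration means. This estimates the typical score of
#' two unrelated sequences of the same composition.
#'
#' @param sequences character vector of sequences.
#' @param params an [alignment_params()].
#' @param n_iterations number of shuffle iterations (default 5).
#' @param pair_fraction fraction of the N(N-1)/2 pairs scored per iteration
#'   (default 1 = all pairs).
#' @return List of class `threshold_estimate`: `method`, `s_star`,
#'   `iteration_means`, `n_iterations`.
#' @export
estimate_threshold_global <- function(sequences, params = alignment_params(),
                                      n_iterations = 5L, pair_fraction = 1) {
  stopifnot(n_iterations >= 1L, pair_fraction > 0, pair_fraction <= 1)
  n <- length(sequences)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  means <- vapply(seq_len(n_iterations), function(it) {
    shuffled <- vapply(sequences, shuffle_sequence, "", USE.NAMES = FALSE)
    take <- if (pair_fraction < 1) {
      pairs[sample(nrow(pairs), max(1L, round(pair_fraction * nrow(pairs)))), ,
            drop = FALSE]
    } else pairs
    set <- Biostrings::DNAStringSet(shuffled)
    # group by subject so each call scores a batch
    scores <- unlist(lapply(unique(take[, 2L]), function(j) {
      is <- take[take[, 2L] == j, 1L]
      biostrings_align(set[is], set[[j]], params)
    }), use.names = FALSE)
    mean(scores)
  }, numeric(1))
  structure(list(method = "global_shuffle", s_star = mean(means),
                 iteration_means = means, n_iterations = n_iterations),
            class = "threshold_estimate")
}

#' Similarity threshold from per-sequence self-shuffling
#'
#' Aligns every sequence against `n_shuffles` random reorderings of itself;
#' the threshold is the mean of all these scores. For short sequences this
#' gives a higher, more discriminating threshold than whole-set shuffling
#' and is the default for the pipeline.
#'
#' @param sequences character vector of sequences.
#' @param params an [alignment_params()].
#' @param n_shuffles shuffled realizations per sequence (default 10).
#' @return List of class `threshold_estimate`: `method`, `s_star`,
#'   `per_sequence_means`, `n_shuffles`.
#' @export
estimate_threshold_self <- function(sequences, params = alignment_params(),
                                    n_shuffles = 10L) {
  stopifnot(n_shuffles >= 1L)
  per_seq <- vapply(sequences, function(s) {
    shuffled <- vapply(seq_len(n_shuffles), function(i) shuffle_sequence(s), "")
    mean(biostrings_align(Biostrings::DNAStringSet(shuffled),
                          Biostrings::DNAString(s), params))
  }, numeric(1), USE.NAMES = FALSE)
  structure(list(method = "self_shuffle", s_star = mean(per_seq),
                 per_sequence_means = per_seq, n_shuffles = n_shuffles),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> method=%s s*=%.3f\n", x$method, x$s_star))
  invisible(x)
}

#' Threshold and normalize a similarity matrix
#'
#' Entries below `s_star` are zeroed (kept when exactly equal); surviving
#' entries are divided by the global maximum surviving entry, so the
#' largest weight is 1. Nodes left with degree 0 are excluded from the
#' adjacency (the normalized Laplacian is undefined there) and reported.
#'
#' @param S symmetric similarity matrix ([similarity_matrix()]).
#' @param s_star threshold on the raw score scale (a number or a
#'   `threshold_estimate`).
#' @return List of class `igs_adjacency`: `W` (normalized weighted
#'   adjacency over the retained ids), `s_star`, `max_score`,
#'   `unclustered_ids` (isolated nodes).
#' @export
build_adjacency <- function(S, s_star) {
  if (inherits(s_star, "threshold_estimate")) s_star <- s_star$s_star
  if (!isTRUE(all.equal(unclass(S), t(unclass(S))))) {
    stop("similarity matrix must be symmetric")
  }
  W <- unclass(S)
  W[W < s_star] <- 0
  diag(W) <- 0
  mx <- max(W)
  if (mx <= 0) stop("threshold removes all edges")
  W <- W / mx
  deg <- rowSums(W)
  isolated <- rownames(W)[deg == 0]
  keep <- deg > 0
  structure(list(W = W[keep, keep, drop = FALSE], s_star = s_star,
                 max_score = mx, unclustered_ids = isolated),
            class = "igs_adjacency")
}

#' @export
print.igs_adjacency <- function(x, ...) {
  cat(sprintf("<igs_adjacency> %d nodes, %d edges, s*=%.3f, %d unclustered\n",
              nrow(x$W), sum(x$W > 0) / 2, x$s_star,
              length(x$unclustered_ids)))
  invisible(x)
}
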