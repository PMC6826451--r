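# pairwise_alignment: EDNAFULL-scored affine-gap alignment of all IGS pairs.

# The standard EDNAFULL nucleotide substitution table (match +5, mismatch -4
# among A/C/G/T, IUPAC ambiguity rows), embedded as a constant.
EDNAFULL_ORDER <- c("A", "T", "G", "C", "S", "W", "R", "Y", "K", "M",
                    "B", "V", "H", "D", "N")
EDNAFULL_VALUES <- c(
   5, -4, -4, -4, -4,  1,  1, -4, -4,  1, -4, -1, -1, -1, -2,
  -4,  5, -4, -4, -4,  1, -4,  1,  1, -4, -1, -4, -1, -1, -2,
  -4, -4,  5, -4,  1, -4,  1, -4,  1, -4, -1, -1, -4, -1, -2,
  -4, -4, -4,  5,  1, -4, -4,  1, -4,  1, -1, -1, -1, -4, -2,
  -4, -4,  1,  1, -1, -4, -2, -2, -2, -2, -1, -1, -3, -3, -1,
   1,  1, -4, -4, -4, -1, -2, -2, -2, -2, -3, -3, -1, -1, -1,
   1, -4,  1, -4, -2, -2, -1, -4, -2, -2, -3, -1, -3, -1, -1,
  -4,  1, -4,  1, -2, -2, -4, -1, -2, -2, -1, -3, -1, -3, -1,
  -4,  1,  1, -4, -2, -2, -2, -2, -1, -4, -1, -3, -3, -1, -1,
   1, -4, -4,  1, -2, -2, -2, -2, -4, -1, -3, -1, -1, -3, -1,
  -4, -1, -1, -1, -1, -3, -3, -1, -1, -3, -1, -2, -2, -2, -1,
  -1, -4, -1, -1, -1, -3, -1, -3, -3, -1, -2, -1, -2, -2, -1,
  -1, -1, -4, -1, -3, -1, -3, -1, -3, -1, -2, -2, -1, -2, -1,
  -1, -1, -1, -4, -3, -1, -1, -3, -1, -3, -2, -2, -2, -1, -1,
  -2, -2, -2, -2, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1
)

#' The EDNAFULL nucleotide substitution matrix
#'
#' The standard 15x15 IUPAC nucleotide score table (match +5, mismatch -4
#' among A/C/G/T).
#'
#' @return Symmetric numeric matrix with IUPAC dimnames.
#' @export
ednafull_matrix <- function() {
  matrix(EDNAFULL_VALUES, 15, 15, byrow = TRUE,
         dimnames = list(EDNAFULL_ORDER, EDNAFULL_ORDER))
}

#' Alignment parameters
#'
#' Scoring setup for IGS pairwise alignment. The affine gap cost of a
#' length-k gap is `gap_open + (k - 1) * gap_extend`; in global mode gaps
#' at the beginning or end of either sequence carry no penalty. The high
#' open / low extend defaults (10 / 0.5) keep long gaps cheap, which
#' favours high scores between compositionally similar sequences.
#'
#' @param mode `"global"` (free end gaps, the default) or `"local"`.
#' @param gap_open gap opening penalty (default 10).
#' @param gap_extend per-base gap extension penalty (default 0.5).
#' @param substitution substitution matrix, default [ednafull_matrix()].
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(mode = c("global", "local"), gap_open = 10,
                             gap_extend = 0.5,
                             substitution = ednafull_matrix()) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= 0, gap_extend >= 0,
            isTRUE(all.equal(substitution, t(substitution))))
  structure(list(mode = mode, gap_open = gap_open, gap_extend = gap_extend,
                 substitution = substitution),
            class = "alignment_params")
}

# Biostrings charges gapOpening + k * gapExtension for a k-gap; shifting the
# opening by one extension reproduces the gap_open + (k-1)*gap_extend
# convention exactly.
biostrings_align <- function(patterns, subject, params) {
  type <- if (params$mode == "global") "overlap" else "local"
  Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject,
    substitutionMatrix = params$substitution,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend,
    type = type, scoreOnly = TRUE
  )
}

#' Score one pair of sequences
#'
#' Best affine-gap alignment score of two nucleotide sequences under the
#' given parameters. Global mode spans both sequences but charges nothing
#' for leading/trailing gaps; local mode returns the best-scoring
#' subalignment (always >= 0).
#'
#' @param seq_a,seq_b nucleotide strings (IUPAC alphabet).
#' @param params an [alignment_params()].
#' @return Numeric score.
#' @export
align_pair <- function(seq_a, seq_b, params = alignment_params()) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  assert_iupac(seq_a); assert_iupac(seq_b)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  biostrings_align(Biostrings::DNAStringSet(seq_a),
                   Biostrings::DNAString(seq_b), params)
}

#' All-against-all similarity matrix
#'
#' Scores every unordered pair of sequences once and mirrors the result.
#' The diagonal is fixed at 0: self-similarity is not informative for the
#' downstream graph and would dominate the adjacency normalization.
#'
#' @param sequences character vector of equal-length sequences.
#' @param ids sequence identifiers (default names or `igs_<i>`).
#' @param params an [alignment_params()].
#' @return Symmetric numeric matrix with `ids` as dimnames, class
#'   `igs_simmat`.
#' @export
similarity_matrix <- function(sequences, ids = NULL,
                              params = alignment_params()) {
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- ids %||% names(sequences) %||% sprintf("igs_%04d", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  sequences <- toupper(sequences)
  set <- Biostrings::DNAStringSet(sequences)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    sc <- biostrings_align(set[(i + 1L):n], set[[i]], params)
    S[i, (i + 1L):n] <- sc
    S[(i + 1L):n, i] <- sc
  }
  class(S) <- c("igs_simmat", class(S))
  S
}

#' Write / read a similarity or adjacency matrix as TSV
#'
#' Square matrix with an id header row and id first column.
#'
#' @param S square matrix with dimnames.
#' @param path TSV path.
#' @return `write_matrix_tsv()`: `path` invisibly; `read_matrix_tsv()`:
#'   the matrix.
#' @export
write_matrix_tsv <- function(S, path) {
  df <- data.frame(id = rownames(S), unclass(S), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
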