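# Internal helpers shared across modules.
#
# Coordinate convention: all genomic positions are 0-based, half-open
# intervals [start, end) on the forward strand.  GenBank's 1-based inclusive
# coordinates are converted on input and restored on output.  All strand
# logic lives in the extraction module.

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse-complement a nucleotide string
#' @param x character scalar over the IUPAC alphabet.
#' @return character scalar.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  chars <- rev(strsplit(toupper(x), "")[[1]])
  comp <- DNA_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("non-IUPAC character in sequence: ",
         paste(unique(chars[is.na(comp)]), collapse = ", "))
  }
  paste(comp, collapse = "")
}

# Extract forward-strand bases at 0-based positions `pos` (already reduced
# mod L for circular replicons).
seq_at <- function(sequence, pos) {
  paste(strsplit(sequence, "")[[1]][pos + 1L], collapse = "")
}

# 0-based positions of the forward-strand window [from, to) with modular
# wrap-around when `circular`; errors out of range otherwise.
window_positions <- function(from, to, len, circular) {
  stopifnot(to > from)
  pos <- seq.int(from, to - 1L)
  if (circular) {
    pos %% len
  } else {
    if (from < 0L || to > len) {
      stop("window [", from, ",", to, ") outside a linear replicon of length ", len)
    }
    pos
  }
}

assert_iupac <- function(x, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(names(DNA_COMPLEMENT), collapse = "")), toupper(x))
  if (any(bad)) stop("non-IUPAC character in ", what)
  invisible(x)
}
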