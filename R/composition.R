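# composition_analysis: positional base composition (BCA), window smoothing,
# and homogeneous A/T/AT segment statistics.

#' Base composition analysis of an equal-length sequence set
#'
#' Per-position nucleotide densities: `rho_x(l)` is the fraction of
#' sequences carrying nucleotide x at position l, for x in A, T, G, C.
#' Positions are labelled `-M .. -1` upstream of the anchor (position 0 is
#' the transcription start site or start codon and is not included).
#' Ambiguity codes contribute to no nucleotide, so the four densities sum
#' to 1 only where all sequences are unambiguous.
#'
#' @param sequences character vector of equal-length sequences (an IGS
#'   tibble's `sequence` column, or the tibble itself).
#' @return Tidy tibble of class `igs_bca`: `position` (-M..-1),
#'   `nucleotide`, `density`.
#' @export
bca <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (!length(sequences)) stop("empty sequence set")
  if (length(unique(nchar(sequences))) != 1L) {
    stop("sequences must have equal length")
  }
  M <- nchar(sequences[1])
  chars <- matrix(unlist(strsplit(toupper(sequences), "")),
                  nrow = length(sequences), byrow = TRUE)
  out <- tidyr::expand_grid(position = seq(-M, -1L),
                            nucleotide = c("A", "T", "G", "C"))
  out$density <- vapply(seq_len(nrow(out)), function(i) {
    mean(chars[, out$position[i] + M + 1L] == out$nucleotide[i])
  }, numeric(1))
  class(out) <- c("igs_bca", class(out))
  out
}

#' Smooth a base-composition profile with a centered window
#'
#' Moving average of each nucleotide's density over positions
#' `[l - a, l + a]` (window of 2a + 1 positions). At the profile ends the
#' window truncates to the available positions and renormalizes by the
#' true covered width, avoiding edge artifacts. `a = 0` is the identity.
#'
#' @param profile an `igs_bca` tibble from [bca()].
#' @param a half-window in bp (default 15).
#' @return The profile with an added `smoothed` column.
#' @export
smooth_bca <- function(profile, a = 15L) {
  stopifnot(a >= 0L)
  smooth_one <- function(d) {
    M <- length(d)
    vapply(seq_len(M), function(i) {
      lo <- max(1L, i - a); hi <- min(M, i + a)
      mean(d[lo:hi])
    }, numeric(1))
  }
  out <- profile |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$nucleotide) |>
    arrange(.data$position, .by_group = TRUE) |>
    mutate(smoothed = smooth_one(.data$density)) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row")
  class(out) <- unique(c("igs_bca", class(out)))
  out
}

#' Count homogeneous A, T and alternating-AT segments
#'
#' Counts maximal runs of three types: pure A homopolymers, pure T
#' homopolymers, and strictly alternating period-2 AT runs containing both
#' letters (no two equal adjacent letters). Each type is counted
#' independently by its own maximality, and a run is reported only when at
#' least `min_len` long. Such weak-nucleotide motifs are the regular
#' patterns that drive the compositional clustering of intergenic
#' sequences.
#'
#' @param sequence nucleotide string.
#' @param min_len minimum reported run length (default 6).
#' @return Tibble: `type` (`"A"`, `"T"`, `"AT"`), `count`, and list-column
#'   `lengths` (run-length vector).
#' @export
homogeneous_segments <- function(sequence, min_len = 6L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  homo_runs <- function(base) {
    r <- rle(chars == base)
    r$lengths[r$values]
  }
  alt_runs <- function() {
    # maximal stretches over {A,T} with no two equal adjacent letters
    is_at <- chars %in% c("A", "T")
    runs <- integer(0)
    i <- 1L; n <- length(chars)
    while (i <= n) {
      if (!is_at[i]) { i <- i + 1L; next }
      j <- i
      while (j < n && is_at[j + 1L] && chars[j + 1L] != chars[j]) j <- j + 1L
      if (j > i) runs <- c(runs, j - i + 1L)  # both letters present iff len >= 2
      i <- j + 1L
    }
    runs
  }
  keep <- function(x) x[x >= min_len]
  lens <- list(A = keep(homo_runs("A")), T = keep(homo_runs("T")),
               AT = keep(alt_runs()))
  tibble(type = names(lens),
         count = unname(vapply(lens, length, integer(1))),
         lengths = unname(lens))
}

#' Per-cluster homogeneous-segment summary
#'
#' Aggregates [homogeneous_segments()] over the members of each cluster
#' and reports totals per segment type.
#'
#' @param igs_records IGS tibble (needs `tu_id`, `sequence`) or a bare
#'   sequence vector named by id.
#' @param labels tibble `id`, `cluster` (e.g. `igs_clustering$labels`)
#'   covering every record.
#' @param min_len minimum run length (default 6).
#' @return Tibble: `cluster`, `type`, `count` (one row per cluster x
#'   type, zero rows included).
#' @export
cluster_segment_summary <- function(igs_records, labels, min_len = 6L) {
  if (is.data.frame(igs_records)) {
    seqs <- setNames(igs_records$sequence, igs_records$tu_id)
  } else seqs <- igs_records
  miss <- setdiff(names(seqs), labels$id)
  if (length(miss)) stop("unlabeled record(s): ", paste(head(miss, 3), collapse = ", "))
  per_seq <- purrr::map_dfr(names(seqs), function(id) {
    mutate(homogeneous_segments(seqs[[id]], min_len), id = id)
  })
  per_seq |>
    left_join(labels, by = "id") |>
    group_by(.data$cluster, .data$type) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(cluster = unique(labels$cluster),
                    type = c("A", "T", "AT"),
                    fill = list(count = 0L)) |>
    arrange(.data$cluster, match(.data$type, c("A", "T", "AT")))
}
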