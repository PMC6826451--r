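# igs_extraction: intergenic regions, window-length rule, Shine-Dalgarno
# detection, and equal-length IGS emission.

#' Shine-Dalgarno motif set, longest first
#'
#' The six-base consensus AGGAGG and its 5-, 4- and 3-mer subsequences, in
#' the strictly decreasing length order used by the detector.
#' @export
SDS_MOTIFS <- c("AGGAGG", "AGGAG", "GGAGG", "GGAG", "GAGG", "AGGA",
                "GGA", "GAG", "AGG")

#' Intergenic regions upstream of transcription units
#'
#' For each transcription unit, the distance (bp) from the lead gene's
#' translation start codon back to the end of the previous coding region on
#' the *same* strand, scanning upstream of transcription (towards lower
#' coordinates on `+`, higher on `-`), with wrap-around on circular
#' replicons.
#'
#' @param annotation a [genome_annotation()].
#' @param tus transcription-unit tibble from [make_tus()].
#' @return Tibble `tu_id`, `strand`, `length` (class `"IGR"` region set).
#' @export
compute_igrs <- function(annotation, tus) {
  genes <- annotation$genes
  n <- nchar(annotation$sequence)
  circ <- annotation$topology == "circular"
  lengths <- vapply(seq_len(nrow(tus)), function(i) {
    lead <- genes[match(tus$lead_gene_id[i], genes$gene_id), ]
    same <- genes[genes$strand == lead$strand & genes$gene_id != lead$gene_id, ]
    if (lead$strand == "+") {
      t <- lead$start
      ends <- same$end
      if (circ) {
        if (!nrow(same)) return((t - lead$end) %% n)  # wraps to its own far side
        min((t - ends) %% n)
      } else {
        ends <- ends[ends <= t]
        if (!length(ends)) t else t - max(ends)
      }
    } else {
      t <- lead$end - 1L
      starts <- same$start
      if (circ) {
        if (!nrow(same)) return((lead$start - t - 1L) %% n)
        min((starts - t - 1L) %% n)
      } else {
        starts <- starts[starts > t]
        if (!length(starts)) n - t - 1L else min(starts) - t - 1L
      }
    }
  }, numeric(1))
  out <- tibble(tu_id = tus$tu_id, strand = tus$strand, length = as.numeric(lengths))
  attr(out, "kind") <- "IGR"
  out
}

#' Restricted intergenic regions (strand-agnostic gaps between genes)
#'
#' Gap lengths between consecutive coding spans regardless of strand;
#' overlapping spans contribute length 0. On a circular replicon the gap
#' across the origin is included, so n mutually non-overlapping genes yield
#' n gaps (n − 1 on a linear replicon).
#'
#' @param annotation a [genome_annotation()].
#' @return Tibble `left_gene`, `right_gene`, `length` (class `"RIGR"`).
#' @export
compute_rigrs <- function(annotation) {
  genes <- arrange(annotation$genes, .data$start, .data$end)
  if (nrow(genes) < 2L) stop("need at least 2 genes to compute RIGRs")
  n <- nchar(annotation$sequence)
  starts <- genes$start; ends <- genes$end
  run_end <- cummax(ends)
  gap <- pmax(0, starts[-1] - run_end[-length(run_end)])
  out <- tibble(left_gene = genes$gene_id[-nrow(genes)],
                right_gene = genes$gene_id[-1],
                length = as.numeric(gap))
  if (annotation$topology == "circular") {
    wrap <- pmax(0, starts[1] + n - max(ends))
    out <- bind_rows(out, tibble(left_gene = genes$gene_id[nrow(genes)],
                                 right_gene = genes$gene_id[1],
                                 length = as.numeric(wrap)))
  }
  attr(out, "kind") <- "RIGR"
  out
}

#' Common window length from a region-length distribution
#'
#' `round(mean - sd)` of the lengths, with the *population* standard
#' deviation (divisor n). Subtracting one spread from the mean trades a
#' little sequence for many more loci that fully cover the window; on the
#' reference genome the rule gives 250 - 50 = 200 bp. An explicit
#' `override` (e.g. 200) bypasses the computation.
#'
#' @param lengths numeric vector of region lengths (bp).
#' @param override optional fixed window length.
#' @return Integer window length in bp.
#' @export
choose_window_length <- function(lengths, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (!length(lengths)) stop("empty length list")
  if (all(lengths == 0)) stop("all region lengths are zero")
  m <- mean(lengths)
  s <- sqrt(mean((lengths - m)^2))
  as.integer(round(m - s))
}

#' Extract the upstream window of a transcription unit
#'
#' The `L` bases immediately 5' of the lead gene's translation start codon,
#' read 5'->3' on the coding strand (reverse-complemented for `-` strand
#' genes). The window crosses coding regions when necessary and wraps
#' around the origin of circular replicons.
#'
#' @param annotation a [genome_annotation()].
#' @param tsc 0-based position of the first base of the start codon.
#' @param strand `"+"` or `"-"`.
#' @param L window length (bp).
#' @return Character scalar, or `NA` (with a warning) when a linear
#'   replicon has fewer than `L` bp upstream.
#' @export
extract_upstream_window <- function(annotation, tsc, strand, L) {
  n <- nchar(annotation$sequence)
  circ <- annotation$topology == "circular"
  if (strand == "+") {
    if (!circ && tsc - L < 0L) {
      warning("fewer than ", L, " bp upstream on linear replicon; record skipped")
      return(NA_character_)
    }
    pos <- window_positions(tsc - L, tsc, n, circ)
    seq_at(annotation$sequence, pos)
  } else {
    if (!circ && tsc + 1L + L > n) {
      warning("fewer than ", L, " bp upstream on linear replicon; record skipped")
      return(NA_character_)
    }
    pos <- window_positions(tsc + 1L, tsc + 1L + L, n, circ)
    revcomp(seq_at(annotation$sequence, pos))
  }
}

#' Detect a Shine-Dalgarno sequence in an upstream window
#'
#' Scans the last `search_len` bases of the window (the region immediately
#' 5' of the translation start codon) for the motifs in [SDS_MOTIFS], in
#' strictly decreasing length order; the first nucleotide of a hit must lie
#' within the search region. The longest motif wins; among equal-length
#' hits the one closest to the start codon is taken.
#'
#' @param window coding-strand window string whose last base is immediately
#'   5' of the start codon.
#' @param search_len search region size in bp (default 25).
#' @return A list with `motif` and `offset` (bp from the start codon to the
#'   motif's first nucleotide, 1-based), or `NULL` when no motif is found.
#' @export
detect_sds <- function(window, search_len = 25L) {
  L <- nchar(window)
  if (L < search_len) stop("window shorter than the search region")
  window <- toupper(window)
  lens <- nchar(SDS_MOTIFS)
  for (len in sort(unique(lens), decreasing = TRUE)) {
    best <- -1L; best_motif <- NULL
    for (motif in SDS_MOTIFS[lens == len]) {
      i_min <- max(1L, L - search_len + 1L)
      i_max <- L - len + 1L
      if (i_max < i_min) next
      for (i in i_max:i_min) {           # nearest the start codon first
        if (substr(window, i, i + len - 1L) == motif) {
          if (i > best) { best <- i; best_motif <- motif }
          break
        }
      }
    }
    if (best > 0L) {
      return(list(motif = best_motif, offset = L - best + 1L))
    }
  }
  NULL
}

# IGS sequence inside a window: the (L - search_len) bases immediately 5'
# of the SDS first nucleotide, or of the start codon when no SDS was found.
igs_from_window <- function(window, sds, search_len = 25L) {
  L <- nchar(window)
  igs_len <- L - search_len
  i <- if (is.null(sds)) L + 1L else L - sds$offset + 1L  # anchor position
  substr(window, i - igs_len, i - 1L)
}

# Per-position logical coverage by any CDS span, either strand.
cds_coverage <- function(annotation) {
  n <- nchar(annotation$sequence)
  cov <- logical(n)
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    cov[(g$start:(g$end - 1L)) %% n + 1L] <- TRUE
  }
  cov
}

#' Coding fraction of a genomic span
#'
#' Fraction of the positions of the half-open forward-strand interval
#' `[start, end)` (modular on circular replicons) overlapped by any CDS
#' span on either strand.
#'
#' @param start,end 0-based half-open interval; `end` may exceed the
#'   replicon length to denote wrap-around.
#' @param annotation a [genome_annotation()].
#' @param coverage optional precomputed coverage vector (internal reuse).
#' @return Numeric in `[0, 1]`.
#' @export
coding_fraction <- function(start, end, annotation, coverage = NULL) {
  if (is.null(coverage)) coverage <- cds_coverage(annotation)
  n <- length(coverage)
  mean(coverage[(start:(end - 1L)) %% n + 1L])
}

#' Extract equal-length intergenic sequences for all transcription units
#'
#' The full extraction stage: for each transcription unit, take the
#' `window_length` bases upstream of the lead gene's start codon, detect a
#' Shine-Dalgarno sequence in the last `search_len` bases, anchor the
#' transcription start site at the motif's first nucleotide (or at the
#' start codon when none is found), and emit the
#' `window_length - search_len` bases immediately 5' of that anchor
#' (175 bp with the defaults). The coding fraction of each emitted
#' sequence is recorded.
#'
#' @param annotation a [genome_annotation()].
#' @param tus transcription units from [make_tus()] / [read_operon_table()].
#' @param window_length upstream window size (default 200 bp).
#' @param search_len Shine-Dalgarno search region (default 25 bp).
#' @return Tibble with one row per retained unit: `tu_id`, `sequence`
#'   (length `window_length - search_len`), `sds_motif`, `sds_offset`,
#'   `tss` (0-based genomic anchor), `coding_fraction`, `strand`, `start`,
#'   `end` (forward-strand half-open IGS span; `end` may exceed the
#'   replicon length to denote wrap).
#' @export
extract_igs <- function(annotation, tus, window_length = 200L,
                        search_len = 25L) {
  stopifnot(window_length > search_len)
  genes <- annotation$genes
  n <- nchar(annotation$sequence)
  coverage <- cds_coverage(annotation)
  igs_len <- window_length - search_len
  rows <- lapply(seq_len(nrow(tus)), function(i) {
    lead <- genes[match(tus$lead_gene_id[i], genes$gene_id), ]
    w <- extract_upstream_window(annotation, lead$tsc, lead$strand, window_length)
    if (is.na(w)) return(NULL)
    sds <- detect_sds(w, search_len)
    seq <- igs_from_window(w, sds, search_len)
    p <- if (is.null(sds)) 0L else sds$offset
    if (lead$strand == "+") {
      tss <- (lead$tsc - p) %% n
      s0 <- (lead$tsc - p - igs_len) %% n
    } else {
      tss <- (lead$tsc + p) %% n
      s0 <- (lead$tsc + p + 1L) %% n
    }
    tibble(
      tu_id = tus$tu_id[i], sequence = seq,
      sds_motif = if (is.null(sds)) NA_character_ else sds$motif,
      sds_offset = if (is.null(sds)) NA_integer_ else sds$offset,
      tss = as.integer(tss),
      coding_fraction = coding_fraction(s0, s0 + igs_len, annotation, coverage),
      strand = lead$strand, start = as.integer(s0), end = as.integer(s0 + igs_len)
    )
  })
  bind_rows(rows)
}
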