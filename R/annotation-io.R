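# annotation_io: read/write genome annotations, operon tables and IGS sets.

#' Construct a genome annotation
#'
#' Container for one replicon: its sequence, topology, and an ordered gene
#' table. Internal coordinates are 0-based half-open on the forward strand;
#' `tsc` is the 0-based position of the first base of the start codon
#' (= `start` on the `+` strand, `end - 1` on the `-` strand).
#'
#' @param replicon_id character scalar.
#' @param sequence nucleotide string (IUPAC alphabet).
#' @param genes tibble with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`). A `tsc` column is derived if absent.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(replicon_id, sequence, genes,
                              topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  assert_iupac(sequence, "replicon sequence")
  genes <- as_tibble(genes)
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
  if (any(genes$end <= genes$start)) stop("empty or inverted gene span")
  if (any(genes$start < 0L) || any(genes$end > nchar(sequence))) {
    stop("gene span outside replicon bounds")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!"tsc" %in% names(genes)) {
    genes$tsc <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  }
  genes <- arrange(genes, .data$start, .data$end)
  structure(
    list(replicon_id = replicon_id, sequence = sequence,
         topology = topology, genes = genes),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %s bp (%s), %d genes\n",
              x$replicon_id, format(nchar(x$sequence), big.mark = ","),
              x$topology, nrow(x$genes)))
  invisible(x)
}

# --- GenBank flat file ------------------------------------------------------

#' Read a GenBank flat file
#'
#' Minimal reader for single-replicon GenBank flat files: the LOCUS line
#' (topology), CDS features (plain and `complement(...)` locations) and the
#' ORIGIN sequence block. Coordinates are converted from 1-based inclusive to
#' the internal 0-based half-open convention; `complement` features get
#' strand `-`.
#'
#' @param path file path.
#' @param atg_only if `TRUE`, drop CDS records whose annotated start codon is
#'   not ATG; the default keeps any annotated start (GTG/TTG starts are
#'   common in bacteria).
#' @return A [genome_annotation()].
#' @export
read_genbank <- function(path, atg_only = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS"))) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  if (sum(startsWith(lines, "LOCUS")) > 1L) {
    stop("multiple replicons in file; run once per replicon")
  }
  locus <- strsplit(trimws(lines[startsWith(lines, "LOCUS")][1]), "\\s+")[[1]]
  replicon_id <- locus[2]
  topology <- if (any(tolower(locus) == "linear")) "linear" else "circular"

  origin_at <- which(startsWith(lines, "ORIGIN"))
  if (!length(origin_at)) stop("truncated GenBank file: no ORIGIN block")
  seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("truncated GenBank file: empty sequence")

  # CDS feature lines look like:  "     CDS             101..400"
  feat <- grep("^\\s{5}CDS\\s+", lines, value = TRUE)
  if (!length(feat)) stop("no CDS features in ", path)
  loc <- trimws(sub("^\\s{5}CDS\\s+", "", feat))
  if (any(grepl("join|order", loc))) {
    stop("compound (join/order) CDS locations are not supported")
  }
  strand <- ifelse(grepl("^complement\\(", loc), "-", "+")
  loc <- gsub("complement\\(|\\)|<|>", "", loc)
  parts <- strsplit(loc, "\\.\\.")
  start1 <- as.integer(vapply(parts, `[`, "", 1L))
  end1 <- as.integer(vapply(parts, `[`, "", 2L))
  if (anyNA(start1) || anyNA(end1)) stop("unparseable CDS location")
  ids <- sub("^.*locus_tag=\"([^\"]+)\".*$", "\\1",
             vapply(seq_along(feat), function(i) {
               j <- which(lines == feat[i])[1]
               block <- lines[j:min(j + 10L, length(lines))]
               tag <- grep("/locus_tag=", block, value = TRUE)
               if (length(tag)) tag[1] else ""
             }, ""))
  ids[ids == ""] <- sprintf("cds_%04d", which(ids == ""))
  genes <- tibble(
    gene_id = make.unique(ids),
    start = start1 - 1L,   # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = strand
  )
  ann <- genome_annotation(replicon_id, sequence, genes, topology)
  if (atg_only) {
    keep <- vapply(seq_len(nrow(ann$genes)), function(i) {
      start_codon(ann, ann$genes[i, ]) == "ATG"
    }, logical(1))
    ann$genes <- ann$genes[keep, ]
  }
  ann
}

# The annotated start codon of one gene row, read 5'->3' on its coding strand.
start_codon <- function(annotation, gene) {
  len <- nchar(annotation$sequence)
  circ <- annotation$topology == "circular"
  if (gene$strand == "+") {
    pos <- window_positions(gene$tsc, gene$tsc + 3L, len, circ)
    seq_at(annotation$sequence, pos)
  } else {
    pos <- window_positions(gene$tsc - 2L, gene$tsc + 1L, len, circ)
    revcomp(seq_at(annotation$sequence, pos))
  }
}

#' Write a genome annotation as a GenBank flat file
#'
#' Emits LOCUS (with topology), one CDS feature per gene (with
#' `/locus_tag`), and the ORIGIN sequence block. Inverse of
#' [read_genbank()].
#'
#' @param annotation a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(annotation, path) {
  n <- nchar(annotation$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                     annotation$replicon_id, n, annotation$topology), con)
  writeLines(sprintf("DEFINITION  %s.", annotation$replicon_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    loc <- sprintf("%d..%d", g$start + 1L, g$end)  # back to 1-based inclusive
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id), con)
  }
  writeLines("ORIGIN", con)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(annotation$sequence, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a FASTA + GFF3 annotation pair
#'
#' Alternate reader for the common FASTA/GFF3 distribution format. CDS
#' features are taken from the GFF3; coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param fasta_path replicon FASTA (single record).
#' @param gff_path GFF3 with CDS features.
#' @param topology replicon topology, default circular.
#' @return A [genome_annotation()].
#' @export
read_fasta_gff <- function(fasta_path, gff_path,
                           topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stop("expected a single-replicon FASTA; run per replicon")
  gff <- utils::read.delim(gff_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  names(gff)[1:9] <- c("seqid", "source", "type", "start", "end",
                       "score", "strand", "phase", "attributes")
  gff <- gff[gff$type == "CDS", ]
  if (!nrow(gff)) stop("no CDS features in ", gff_path)
  ids <- sub("^.*ID=([^;]+).*$", "\\1", gff$attributes)
  ids[!grepl("ID=", gff$attributes)] <- NA
  ids[is.na(ids)] <- sprintf("cds_%04d", which(is.na(ids)))
  genes <- tibble(
    gene_id = make.unique(ids),
    start = as.integer(gff$start) - 1L,
    end = as.integer(gff$end),
    strand = gff$strand
  )
  genome_annotation(sub("\\s.*$", "", names(seqs)[1]),
                    as.character(seqs[[1]]), genes, topology)
}

# --- operon table -> transcription units -----------------------------------

#' Group genes into transcription units from an operon table
#'
#' Reads a two-column TSV (`gene_id`, `operon_id`; header optional) in the
#' style of prokaryotic operon databases, groups annotated genes that share
#' an operon id, and adds singleton transcription units for annotated genes
#' absent from the table. The lead gene of each unit is the strand-wise
#' 5'-most member (smallest start on `+`, largest coordinate on `-`).
#'
#' @param path TSV path, or `NULL` to treat every gene as a singleton unit.
#' @param annotation a [genome_annotation()].
#' @return Tibble with one row per transcription unit: `tu_id`,
#'   `lead_gene_id`, `strand`, `n_genes`, and list-column `gene_ids` in
#'   transcription order.
#' @export
read_operon_table <- function(path, annotation) {
  genes <- annotation$genes
  op <- NULL
  if (!is.null(path)) {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2L) stop("operon table needs columns gene_id, operon_id")
    names(raw)[1:2] <- c("gene_id", "operon_id")
    if (identical(tolower(raw$gene_id[1]), "gene_id")) raw <- raw[-1, ]
    unknown <- !(raw$gene_id %in% genes$gene_id)
    if (any(unknown)) {
      warning(sum(unknown), " operon-table gene id(s) not in annotation; rows skipped")
      raw <- raw[!unknown, ]
    }
    op <- raw
  }
  make_tus(annotation, op)
}

#' Build transcription units from an in-memory operon map
#'
#' @param annotation a [genome_annotation()].
#' @param operons data frame with columns `gene_id`, `operon_id`, or `NULL`
#'   for all-singleton units.
#' @return As [read_operon_table()].
#' @export
make_tus <- function(annotation, operons = NULL) {
  genes <- annotation$genes
  tu_of <- setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  if (!is.null(operons) && nrow(operons)) {
    tu_of[operons$gene_id] <- as.character(operons$operon_id)
  }
  singleton <- is.na(tu_of)
  tu_of[singleton] <- paste0("su_", genes$gene_id[singleton])

  split_ids <- split(genes$gene_id, tu_of)
  rows <- lapply(names(split_ids), function(tu) {
    members <- genes[match(split_ids[[tu]], genes$gene_id), ]
    if (length(unique(members$strand)) != 1L) {
      stop("operon ", tu, " spans both strands")
    }
    strand <- members$strand[1]
    ord <- if (strand == "+") order(members$start) else order(-members$end)
    members <- members[ord, ]
    tibble(tu_id = tu, lead_gene_id = members$gene_id[1], strand = strand,
           n_genes = nrow(members), gene_ids = list(members$gene_id))
  })
  arrange(bind_rows(rows), .data$tu_id)
}

# --- IGS FASTA --------------------------------------------------------------

#' Write / read an IGS set as FASTA with metadata headers
#'
#' Headers encode the record metadata as
#' `>tu_id|sds_motif|sds_offset|coding_fraction|strand|start|end` with `.`
#' for a missing Shine-Dalgarno hit; the round trip is lossless.
#'
#' @param records IGS tibble as produced by [extract_igs()] (columns
#'   `tu_id`, `sequence`, `sds_motif`, `sds_offset`, `coding_fraction`,
#'   `strand`, `start`, `end`).
#' @param path FASTA path.
#' @return `write_igs_fasta()`: `path` invisibly; `read_igs_fasta()`: the
#'   IGS tibble.
#' @export
write_igs_fasta <- function(records, path) {
  if (nrow(records) && length(unique(nchar(records$sequence))) > 1L) {
    stop("IGS records must all have equal length")
  }
  enc <- function(x) ifelse(is.na(x), ".", as.character(x))
  headers <- sprintf("%s|%s|%s|%s|%s|%s|%s",
                     records$tu_id, enc(records$sds_motif),
                     enc(records$sds_offset), enc(records$coding_fraction),
                     records$strand, records$start, records$end)
  x <- Biostrings::DNAStringSet(records$sequence %||% character())
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_igs_fasta
#' @export
read_igs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) {
    return(tibble(tu_id = character(), sequence = character(),
                  sds_motif = character(), sds_offset = integer(),
                  coding_fraction = double(), strand = character(),
                  start = integer(), end = integer()))
  }
  parts <- strsplit(names(x), "|", fixed = TRUE)
  dec <- function(i) vapply(parts, `[`, "", i)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  tibble(
    tu_id = dec(1),
    sequence = unname(as.character(x)),
    sds_motif = ifelse(dec(2) == ".", NA_character_, dec(2)),
    sds_offset = as.integer(num(dec(3))),
    coding_fraction = num(dec(4)),
    strand = dec(5),
    start = as.integer(num(dec(6))),
    end = as.integer(num(dec(7)))
  )
}
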