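# synthetic_fixtures: fully synthetic genomes, score tables and category
# tables with planted ground truth, so every pipeline stage is testable
# offline.

#' Specification for a synthetic fixture genome
#'
#' Defaults emulate the study conditions of the reference pipeline:
#' intergenic gaps with mean ~250 bp and spread ~50 bp (truncated at
#' 200 bp so the planted upstream window is wholly intergenic), a
#' Shine-Dalgarno consensus planted in 88% of transcription units at an
#' offset peaked near 10 bp, and three compositional IGS classes — T-rich
#' (rho_T ~ 0.45), A-rich (rho_A ~ 0.45) and a weaker balanced class
#' (rho_A ~ rho_T ~ 0.3) — each carrying class-specific >= 6 bp
#' homopolymer / alternating patches, the regular weak-nucleotide motifs
#' that give the alignment its signal.
#'
#' @param n_genes number of genes (default 60).
#' @param operon_fraction fraction of genes grouped into multi-gene
#'   operons (default 0.4).
#' @param operon_size_range operon sizes sampled uniformly in this range.
#' @param gene_length_range CDS length range (bp, multiple-of-3 enforced).
#' @param gap_mean,gap_sd,gap_min intergenic gap distribution (truncated
#'   normal, bp).
#' @param sds_probability probability a transcription unit carries the
#'   planted consensus (default 0.88).
#' @param sds_offset_range offsets (bp from start codon to motif first
#'   base) sampled with a peak near 10 within this support.
#' @param class_proportions proportions of the T-rich, A-rich and balanced
#'   IGS classes (sum to 1).
#' @param patch_rate named vector: mean number of planted >= 6 bp patches
#'   per IGS for each class. Each class plants its signature patch type —
#'   T homopolymers, A homopolymers, alternating AT — so the classes are
#'   separable by alignment beyond their overall composition; the balanced
#'   class, whose composition is closest to uniform, carries the highest
#'   rate (its reference cluster is the one richest in regular segments).
#' @param n_modules planted interaction-network modules (genes of a
#'   transcription unit share a module).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 60L, operon_fraction = 0.4,
                         operon_size_range = c(2L, 4L),
                         gene_length_range = c(300L, 900L),
                         gap_mean = 250, gap_sd = 50, gap_min = 200,
                         sds_probability = 0.88,
                         sds_offset_range = c(6L, 25L),
                         class_proportions = c(t_rich = 1 / 3,
                                               a_rich = 1 / 3,
                                               balanced = 1 / 3),
                         patch_rate = c(t_rich = 3, a_rich = 3,
                                        balanced = 6),
                         n_modules = 3L) {
  stopifnot(n_genes >= 2L, sds_probability >= 0, sds_probability <= 1,
            abs(sum(class_proportions) - 1) < 1e-8,
            all(class_proportions >= 0))
  structure(as.list(environment()), class = "fixture_spec")
}

CLASS_COMPOSITIONS <- list(
  t_rich   = c(A = 0.25, T = 0.45, G = 0.15, C = 0.15),
  a_rich   = c(A = 0.45, T = 0.25, G = 0.15, C = 0.15),
  balanced = c(A = 0.30, T = 0.30, G = 0.20, C = 0.20)
)

random_bases <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# One 175-bp class-composed IGS with its class's signature weak-nucleotide
# patches planted (T runs / A runs / alternating AT; length 6 + Geom(0.4),
# so the most frequent planted length is six).
class_igs <- function(class, len, patch_rate) {
  seq <- strsplit(random_bases(len, CLASS_COMPOSITIONS[[class]]), "")[[1]]
  rate <- if (length(patch_rate) > 1L) patch_rate[[class]] else patch_rate
  patch_type <- switch(class, t_rich = "T", a_rich = "A", balanced = "AT")
  for (p in seq_len(rpois(1, rate))) {
    plen <- 6L + stats::rgeom(1, 0.4)
    at <- sample(len - plen, 1)
    patch <- if (patch_type == "AT") {
      rep(c("A", "T"), length.out = plen)
    } else rep(patch_type, plen)
    seq[at:(at + plen - 1L)] <- patch
  }
  paste(seq, collapse = "")
}

random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), len - 6, replace = TRUE),
                         nrow = 3), 2, paste, collapse = "")
  codons <- gsub("TAA|TAG|TGA", "TAC", codons)  # no internal stops
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Simulate a genome with planted ground truth
#'
#' Builds a circular replicon of non-overlapping CDSs on both strands,
#' grouped into operons, with the Shine-Dalgarno consensus AGGAGG planted
#' at a drawn offset with probability `sds_probability` and the 175 bp
#' upstream of the motif sampled from the transcription unit's planted
#' compositional class. Everything is reproducible from the RNG state
#' (`set.seed()` before calling).
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; when given, writes
#'   `genome.gbk` (GenBank), `operons.tsv` and `truth.tsv` there.
#' @return List: `annotation` ([genome_annotation()]), `operons` tibble
#'   (`gene_id`, `operon_id`), `truth` (per-TU tibble: `tu_id`, `class`,
#'   `sds_motif`, `sds_offset`, `strand`, `lead_gene_id`, `module`,
#'   `gene_ids` list-column), `paths` (when `dir` given).
#' @export
simulate_genome <- function(spec = fixture_spec(), dir = NULL) {
  window <- 200L; search_len <- 25L; igs_len <- window - search_len

  # partition genes into transcription units
  n_op_genes <- round(spec$n_genes * spec$operon_fraction)
  sizes <- integer(0)
  while (sum(sizes) < n_op_genes) {
    sizes <- c(sizes, sample(spec$operon_size_range[1]:spec$operon_size_range[2], 1))
  }
  sizes <- c(sizes, rep(1L, spec$n_genes - sum(sizes)))
  if (sum(sizes) > spec$n_genes) sizes[1] <- sizes[1] - (sum(sizes) - spec$n_genes)
  sizes <- sizes[sizes > 0]
  n_tu <- length(sizes)

  classes <- sample(names(spec$class_proportions), n_tu, replace = TRUE,
                    prob = spec$class_proportions)
  strands <- sample(c("+", "-"), n_tu, replace = TRUE)
  modules <- sample(seq_len(spec$n_modules), n_tu, replace = TRUE)
  has_sds <- runif(n_tu) < spec$sds_probability
  # offset peaked near 10: shifted binomial on the allowed support
  supp <- spec$sds_offset_range[1]:spec$sds_offset_range[2]
  offset_probs <- stats::dbinom(supp - supp[1],
                                size = length(supp) - 1L,
                                prob = (10 - supp[1]) / (length(supp) - 1L))
  offsets <- ifelse(has_sds, sample(supp, n_tu, replace = TRUE, prob = offset_probs),
                    NA_integer_)

  blocks <- character(n_tu)
  gene_tbl <- list(); truth <- list(); gene_counter <- 0L
  for (i in seq_len(n_tu)) {
    gap <- max(spec$gap_min,
               round(rnorm(1, spec$gap_mean, spec$gap_sd)))
    pre_len <- gap - window
    igs <- class_igs(classes[i], igs_len, spec$patch_rate)
    sds_region <- strsplit(random_bases(search_len,
                                        c(A = .3, C = .25, G = .15, T = .3)), "")[[1]]
    if (has_sds[i]) {
      p <- offsets[i]  # first motif base p bp upstream of the start codon
      sds_region[(search_len - p + 1L):(search_len - p + 6L)] <-
        strsplit("AGGAGG", "")[[1]]
    }
    upstream <- paste0(if (pre_len > 0) random_bases(pre_len) else "",
                       igs, paste(sds_region, collapse = ""))
    glens <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2], 3),
                    sizes[i], replace = TRUE)
    genes <- vapply(glens, random_cds, "")
    intra <- vapply(seq_len(sizes[i]), function(j)
      if (j == 1) "" else random_bases(20L), "")
    block <- paste0(upstream,
                    paste(paste0(intra, genes), collapse = ""))
    # gene coordinates within the block, coding-strand orientation
    at <- nchar(upstream)
    coords <- matrix(0L, sizes[i], 2L)
    for (j in seq_len(sizes[i])) {
      if (j > 1) at <- at + 20L
      coords[j, ] <- c(at, at + glens[j])
      at <- at + glens[j]
    }
    ids <- sprintf("g%04d", gene_counter + seq_len(sizes[i]))
    gene_counter <- gene_counter + sizes[i]
    B <- nchar(block)
    if (strands[i] == "-") {
      block <- revcomp(block)
      coords <- cbind(B - coords[, 2L], B - coords[, 1L])
    }
    blocks[i] <- block
    gene_tbl[[i]] <- tibble(gene_id = ids, block = i,
                            start = coords[, 1L], end = coords[, 2L],
                            strand = strands[i])
    truth[[i]] <- tibble(tu_id = sprintf("tu%03d", i), class = classes[i],
                         sds_motif = ifelse(has_sds[i], "AGGAGG", NA_character_),
                         sds_offset = offsets[i], strand = strands[i],
                         lead_gene_id = ids[1], module = modules[i],
                         gene_ids = list(ids))
  }
  offsets_bp <- cumsum(c(0L, head(nchar(blocks), -1L)))
  genes <- bind_rows(gene_tbl) |>
    mutate(start = .data$start + offsets_bp[.data$block],
           end = .data$end + offsets_bp[.data$block]) |>
    select(-"block")
  annotation <- genome_annotation("synth_chr", paste(blocks, collapse = ""),
                                  genes, topology = "circular")
  truth <- bind_rows(truth)
  operons <- truth |>
    select("tu_id", "gene_ids") |>
    tidyr::unnest("gene_ids") |>
    dplyr::rename(gene_id = "gene_ids", operon_id = "tu_id") |>
    select("gene_id", "operon_id")

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genbank = file.path(dir, "genome.gbk"),
                  operons = file.path(dir, "operons.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_genbank(annotation, paths$genbank)
    utils::write.table(operons, paths$operons, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    utils::write.table(select(truth, -"gene_ids"), paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  list(annotation = annotation, operons = operons, truth = truth,
       paths = paths)
}

#' Simulate a module-structured interaction score table
#'
#' Every unordered gene pair receives an integer score in 0..1000:
#' within-module pairs score above 700 with probability `within_p`,
#' between-module pairs with probability `between_p`; otherwise the score
#' is drawn uniformly in 0..700.
#'
#' @param truth truth tibble from [simulate_genome()] (uses `module` and
#'   `gene_ids`).
#' @param within_p,between_p probabilities of a high (> 700) score.
#' @param path optional TSV output path.
#' @return Tibble `gene1`, `gene2`, `score`.
#' @export
simulate_score_table <- function(truth, within_p = 0.6, between_p = 0.02,
                                 path = NULL) {
  stopifnot(within_p >= 0, within_p <= 1, between_p >= 0, between_p <= 1)
  genes <- tidyr::unnest(select(truth, "module", "gene_ids"), "gene_ids")
  ids <- genes$gene_ids
  mod <- setNames(genes$module, ids)
  pairs <- utils::combn(ids, 2L)
  same <- mod[pairs[1, ]] == mod[pairs[2, ]]
  hi <- runif(ncol(pairs)) < ifelse(same, within_p, between_p)
  score <- ifelse(hi, sample(701:1000, ncol(pairs), replace = TRUE),
                  sample(0:700, ncol(pairs), replace = TRUE))
  out <- tibble(gene1 = pairs[1, ], gene2 = pairs[2, ],
                score = as.integer(score))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  out
}

#' Simulate a gene -> functional-category table
#'
#' Every gene receives exactly one of `n_categories` categories. The first
#' category's sampling weight is multiplied by `enrichment_factor` for
#' genes whose transcription unit carries `target_class`; the background
#' is uniform.
#'
#' @param truth truth tibble from [simulate_genome()].
#' @param enrichment_factor weight multiplier (>= 1; 1 = no signal).
#' @param target_class planted class receiving the enrichment.
#' @param n_categories number of categories.
#' @param path optional TSV output path.
#' @return Tibble `gene_id`, `category`.
#' @export
simulate_category_table <- function(truth, enrichment_factor = 1,
                                    target_class = "t_rich",
                                    n_categories = 8L, path = NULL) {
  stopifnot(enrichment_factor >= 1)
  cats <- LETTERS[seq_len(n_categories)]
  genes <- tidyr::unnest(select(truth, "class", "gene_ids"), "gene_ids")
  category <- vapply(seq_len(nrow(genes)), function(i) {
    w <- rep(1, n_categories)
    if (genes$class[i] == target_class) w[1] <- enrichment_factor
    sample(cats, 1, prob = w)
  }, "")
  out <- tibble(gene_id = genes$gene_ids, category = category)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  out
}
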