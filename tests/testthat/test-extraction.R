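# IGS extraction: intergenic regions, window-length rule, upstream windows,
# Shine-Dalgarno detection, coding fraction.

test_that("IGRs measure to the previous same-strand coding end", {
  ann <- tiny_annotation("linear")          # + genes [0,300) and [500,800)
  tus <- make_tus(ann)
  igr <- compute_igrs(ann, tus)
  expect_equal(igr$length[igr$tu_id == "su_gB"], 200)   # 500 - 300
  expect_equal(igr$length[igr$tu_id == "su_gA"], 0)     # replicon edge

  # - strand: previous coding end sought at higher coordinates
  set.seed(1)
  ann2 <- genome_annotation(
    "m", random_dna(1000),
    tibble::tibble(gene_id = c("gA", "gB"), start = c(100L, 500L),
                   end = c(300L, 800L), strand = c("-", "-")),
    topology = "linear")
  igr2 <- compute_igrs(ann2, make_tus(ann2))
  expect_equal(igr2$length[igr2$tu_id == "su_gA"], 200) # 500 - 299 - 1

  # circular wrap: previous coding end 900, TSC 100 -> 200 bp
  set.seed(2)
  ann3 <- genome_annotation(
    "c", random_dna(1000),
    tibble::tibble(gene_id = c("g1", "g2"), start = c(600L, 100L),
                   end = c(900L, 400L), strand = c("+", "+")),
    topology = "circular")
  igr3 <- compute_igrs(ann3, make_tus(ann3))
  expect_equal(igr3$length[igr3$tu_id == "su_g2"], 200)
})

test_that("RIGRs are strand-agnostic gaps, zero under overlap", {
  ann <- tiny_annotation("linear")
  rigr <- compute_rigrs(ann)
  expect_equal(nrow(rigr), 1)
  expect_equal(rigr$length, 200)

  set.seed(3)
  ov <- genome_annotation(
    "ov", random_dna(1000),
    tibble::tibble(gene_id = c("a", "b"), start = c(0L, 250L),
                   end = c(300L, 600L), strand = c("+", "-")),
    topology = "linear")
  expect_equal(compute_rigrs(ov)$length, 0)

  # circular: n non-overlapping genes -> n gaps, totalling the noncoding bp
  set.seed(4)
  tri <- genome_annotation(
    "tri", random_dna(900),
    tibble::tibble(gene_id = c("a", "b", "c"),
                   start = c(0L, 350L, 600L), end = c(300L, 500L, 850L),
                   strand = c("+", "-", "+")))
  rigr3 <- compute_rigrs(tri)
  expect_equal(nrow(rigr3), 3)
  expect_equal(sum(rigr3$length), 900 - (300 + 150 + 250))
})

test_that("IGR >= RIGR at the same locus on the same strand side", {
  # downstream gene gB: the IGR may cross opposite-strand genes the RIGR stops at
  set.seed(8)
  ann <- genome_annotation(
    "mix", random_dna(2000),
    tibble::tibble(gene_id = c("gA", "gX", "gB"),
                   start = c(0L, 400L, 900L), end = c(300L, 600L, 1200L),
                   strand = c("+", "-", "+")),
    topology = "linear")
  igr <- compute_igrs(ann, make_tus(ann))
  rigr <- compute_rigrs(ann)
  expect_equal(igr$length[igr$tu_id == "su_gB"], 600)   # back to gA's end
  expect_equal(rigr$length[rigr$right_gene == "gB"], 300)
  expect_gte(igr$length[igr$tu_id == "su_gB"],
             rigr$length[rigr$right_gene == "gB"])
})

test_that("window length rule is round(mean - population sd)", {
  expect_equal(choose_window_length(c(200, 300)), 200)      # mean 250, sd 50
  expect_equal(choose_window_length(rep(300, 7)), 300)      # sd 0
  expect_equal(choose_window_length(c(90, 100, 110)), 92)   # 100 - 8.165
  expect_equal(choose_window_length(c(5, 10), override = 200), 200)
  expect_error(choose_window_length(numeric()), "empty")
  expect_error(choose_window_length(c(0, 0)), "zero")
})

test_that("upstream windows honor strand and circular wrap", {
  set.seed(9)
  seq <- random_dna(1000)
  ann <- genome_annotation(
    "w", seq,
    tibble::tibble(gene_id = c("p", "m"), start = c(500L, 100L),
                   end = c(800L, 400L), strand = c("+", "-")))
  # + strand, TSC 500, L=200 -> forward bases [300,500)
  expect_equal(extract_upstream_window(ann, 500L, "+", 200L),
               substr(seq, 301, 500))
  # - strand, TSC 399 -> reverse complement of [400,600)
  w <- extract_upstream_window(ann, 399L, "-", 200L)
  expect_equal(w, igsclust:::revcomp(substr(seq, 401, 600)))
  # circular wrap through the origin: TSC 50, L=200 -> [850,1000)+[0,50)
  w2 <- extract_upstream_window(ann, 50L, "+", 200L)
  expect_equal(w2, paste0(substr(seq, 851, 1000), substr(seq, 1, 50)))
  # linear replicon with too little upstream: NA with a warning
  annl <- genome_annotation("wl", seq, ann$genes, topology = "linear")
  expect_warning(w3 <- extract_upstream_window(annl, 50L, "+", 200L), "skipped")
  expect_true(is.na(w3))
})

test_that("Shine-Dalgarno detection prefers longer then closer motifs", {
  base <- strrep("CT", 100)                       # motif-free background
  plant <- function(motif, offset, L = 200L) {
    w <- strsplit(base, "")[[1]][1:L]
    at <- L - offset + 1L
    w[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    paste(w, collapse = "")
  }
  hit <- detect_sds(plant("AGGAGG", 12L))
  expect_equal(hit[c("motif", "offset")], list(motif = "AGGAGG", offset = 12L))
  # consensus outside the 25-bp search region: only the closer GGA counts
  w <- plant("AGGAGG", 30L)
  w <- `substr<-`(w, 193, 195, "GGA")             # GGA at offset 8
  expect_equal(detect_sds(w)$motif, "GGA")
  expect_equal(detect_sds(w)$offset, 8L)
  # equal-length candidates: the one closest to the start codon wins
  w2 <- plant("GGA", 20L)
  w2 <- `substr<-`(w2, 193, 195, "GAG")
  expect_equal(detect_sds(w2), list(motif = "GAG", offset = 8L))
  expect_null(detect_sds(base))                   # no purine motif at all
})

test_that("no shorter motif is reported when a longer one is in range", {
  # exhaustive: plant every motif at every feasible offset over a C/T
  # background; the detected motif is never shorter than the planted one
  base <- strsplit(strrep("CT", 15), "")[[1]]     # 30-bp windows
  for (motif in SDS_MOTIFS) {
    for (offset in nchar(motif):25) {
      w <- base
      at <- 30 - offset + 1L
      w[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
      hit <- detect_sds(paste(w, collapse = ""), search_len = 25L)
      expect_gte(nchar(hit$motif), nchar(motif))
    }
  }
})

test_that("IGS anchoring at the detected motif follows the interval rule", {
  set.seed(10)
  w <- random_dna(200)
  # no SDS: the last 175 bases
  expect_equal(igsclust:::igs_from_window(w, NULL), substr(w, 26, 200))
  # offset 12: positions -187..-13 relative to the start codon
  expect_equal(igsclust:::igs_from_window(w, list(motif = "AGGAGG", offset = 12L)),
               substr(w, 14, 188))
  # maximal offset 25: positions -200..-26
  expect_equal(igsclust:::igs_from_window(w, list(motif = "AGGAGG", offset = 25L)),
               substr(w, 1, 175))
})

test_that("emitted IGSs always have length window - search region", {
  set.seed(13)
  sim <- simulate_genome(fixture_spec(n_genes = 30))
  tus <- make_tus(sim$annotation, sim$operons)
  igs <- extract_igs(sim$annotation, tus, window_length = 200L)
  expect_equal(nrow(igs), nrow(tus))
  expect_true(all(nchar(igs$sequence) == 175L))
  igs2 <- extract_igs(sim$annotation, tus, window_length = 150L,
                      search_len = 25L)
  expect_true(all(nchar(igs2$sequence) == 125L))
})

test_that("planted consensus motifs are recovered with their offsets", {
  set.seed(14)
  sim <- simulate_genome(fixture_spec(n_genes = 40, sds_probability = 1))
  tus <- make_tus(sim$annotation, sim$operons)
  igs <- extract_igs(sim$annotation, tus)
  expect_true(all(!is.na(igs$sds_motif)))         # sub-motifs can only add hits
  truth <- sim$truth[match(igs$tu_id, sim$truth$tu_id), ]
  # wherever the full consensus was detected, the planted offset is exact
  hit6 <- igs$sds_motif == "AGGAGG"
  expect_gt(mean(hit6), 0.8)
  expect_equal(igs$sds_offset[hit6], truth$sds_offset[hit6])
})

test_that("detected fraction is at least the planted probability", {
  set.seed(15)
  sim <- simulate_genome(fixture_spec(n_genes = 120, sds_probability = 0.7))
  igs <- extract_igs(sim$annotation, make_tus(sim$annotation, sim$operons))
  expect_gte(mean(!is.na(igs$sds_motif)) + 0.05, 0.7)
})

test_that("coding fraction counts CDS overlap on either strand", {
  set.seed(16)
  ann <- genome_annotation(
    "cf", random_dna(1000),
    tibble::tibble(gene_id = c("a", "b"), start = c(100L, 600L),
                   end = c(400L, 900L), strand = c("+", "-")))
  expect_equal(coding_fraction(150L, 250L, ann), 1.0)   # inside a CDS
  expect_equal(coding_fraction(650L, 750L, ann), 1.0)   # inside a - CDS
  expect_equal(coding_fraction(450L, 550L, ann), 0.0)   # pure intergenic
  expect_equal(coding_fraction(350L, 450L, ann), 0.5)   # exactly half
  expect_equal(coding_fraction(950L, 1150L, ann), 0.25) # wraps into [100,150)
})
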