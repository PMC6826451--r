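# pipeline_cli: orchestrate extract -> align -> threshold -> cluster ->
# characterize (-> associate) from a single config, with a checksum
# manifest and a plain-text run log.

#' Default pipeline configuration
#'
#' Every tunable of the workflow surfaced as a key; values mirror the
#' defaults documented on the stage functions.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    genbank = NULL, fasta = NULL, gff = NULL,
    operon_table = NULL,
    window_length = 200L,          # NULL = derive via choose_window_length()
    sds_search_len = 25L,
    alignment = list(mode = "global", gap_open = 10, gap_extend = 0.5),
    threshold = list(method = "self_shuffle", n_shuffles = 10L,
                     n_iterations = 5L, pair_fraction = 1),
    k = "auto", k_max = 20L, kmeans_tol = 1e-8, kmeans_n_init = 10L,
    silhouette_normalization = "paper",
    score_tables = NULL,           # named list channel -> TSV path
    score_threshold = 700,
    category_table = NULL,
    n_resamples = 1000L,
    segment_min_len = 6L,
    smoothing_halfwindow = 15L,
    seed = 1L,
    out_dir = NULL
  )
}

#' Read a pipeline config from YAML
#'
#' Missing keys fall back to [default_config()].
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full IGS clustering pipeline
#'
#' Executes extract -> align -> threshold -> cluster -> characterize, plus
#' the network/enrichment association stages when score or category tables
#' are configured. With `out_dir` set, every stage artifact is written as
#' TSV/FASTA together with a JSON manifest of parameters, seeds and md5
#' checksums, and a plain-text log of the headline counts. Given the same
#' config and seed the manifest checksums are identical across reruns.
#'
#' @param config list as from [default_config()]/[read_run_config()], or a
#'   YAML path. Alternatively pass `annotation` (and `operons`) directly.
#' @param annotation optional in-memory [genome_annotation()] (overrides
#'   `config$genbank`).
#' @param operons optional in-memory operon tibble (`gene_id`, `operon_id`).
#' @return List of class `igs_run`: `igs` (record tibble), `tus`, `igr`,
#'   `rigr`, `window_length`, `threshold`, `similarity`, `adjacency`,
#'   `clustering` ([spectral_cluster()] result), `bca` (per cluster, with
#'   smoothing), `segments`, `network` (per channel, when configured),
#'   `enrichment` (when configured), `manifest`.
#' @export
run_igs_pipeline <- function(config = default_config(), annotation = NULL,
                             operons = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  set.seed(config$seed)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- inputs ---------------------------------------------------------------
  if (is.null(annotation)) {
    annotation <- if (!is.null(config$genbank)) {
      read_genbank(config$genbank)
    } else if (!is.null(config$fasta)) {
      read_fasta_gff(config$fasta, config$gff)
    } else stop("config must name a genbank or fasta/gff input")
  }
  if (is.null(operons)) {
    if (is.null(config$operon_table)) {
      warning("no operon table; treating every gene as a singleton unit")
      tus <- make_tus(annotation, NULL)
    } else {
      tus <- read_operon_table(config$operon_table, annotation)
    }
  } else {
    tus <- make_tus(annotation, operons)
  }
  say("input: %d genes, %d transcription units", nrow(annotation$genes),
      nrow(tus))

  # --- extraction -----------------------------------------------------------
  igr <- compute_igrs(annotation, tus)
  rigr <- compute_rigrs(annotation)
  L <- choose_window_length(rigr$length, override = config$window_length)
  say("window length: %d bp (search region %d bp)", L, config$sds_search_len)
  igs <- extract_igs(annotation, tus, window_length = L,
                     search_len = config$sds_search_len)
  say("extracted %d IGSs of %d bp; SDS found in %.1f%%", nrow(igs),
      L - config$sds_search_len, 100 * mean(!is.na(igs$sds_motif)))

  # --- alignment + threshold ------------------------------------------------
  params <- alignment_params(mode = config$alignment$mode,
                             gap_open = config$alignment$gap_open,
                             gap_extend = config$alignment$gap_extend)
  S <- similarity_matrix(igs$sequence, ids = igs$tu_id, params = params)
  thr <- if (config$threshold$method == "self_shuffle") {
    estimate_threshold_self(igs$sequence, params,
                            n_shuffles = config$threshold$n_shuffles)
  } else {
    estimate_threshold_global(igs$sequence, params,
                              n_iterations = config$threshold$n_iterations,
                              pair_fraction = config$threshold$pair_fraction)
  }
  say("threshold (%s): s* = %.2f", thr$method, thr$s_star)
  adj <- build_adjacency(S, thr)
  if (length(adj$unclustered_ids)) {
    say("%d isolated IGS(s) left unclustered", length(adj$unclustered_ids))
  }

  # --- clustering -----------------------------------------------------------
  k <- if (identical(config$k, "auto")) NULL else as.integer(config$k)
  clustering <- spectral_cluster(
    adj, k = k, k_max = config$k_max, tol = config$kmeans_tol,
    n_init = config$kmeans_n_init,
    silhouette_normalization = config$silhouette_normalization
  )
  say("clustered into k=%d (eigengap suggested %d); mean silhouette %.3f",
      clustering$k, clustering$suggested_k, mean(clustering$silhouette$s))

  # --- characterization -----------------------------------------------------
  labelled <- left_join(igs, clustering$labels, by = c(tu_id = "id"))
  profiles <- purrr::map_dfr(
    sort(unique(clustering$labels$cluster)), function(cl) {
      prof <- bca(labelled$sequence[labelled$cluster == cl & !is.na(labelled$cluster)])
      mutate(smooth_bca(prof, config$smoothing_halfwindow), cluster = cl,
             .before = 1)
    })
  segments <- cluster_segment_summary(
    filter(labelled, !is.na(.data$cluster)), clustering$labels,
    min_len = config$segment_min_len)

  # --- association (optional) ----------------------------------------------
  igs_genes <- setNames(tus$gene_ids, tus$tu_id)[clustering$labels$id]
  network <- NULL
  if (!is.null(config$score_tables)) {
    network <- purrr::imap_dfr(config$score_tables, function(path, channel) {
      tab <- if (is.character(path)) read_score_table(path) else path
      g <- build_network(tab, threshold = config$score_threshold)
      mutate(network_association(g, igs_genes, clustering$labels,
                                 n_resamples = config$n_resamples),
             channel = channel, .before = 1)
    })
  }
  enrichment <- NULL
  if (!is.null(config$category_table)) {
    cats <- if (is.character(config$category_table)) {
      stats::setNames(utils::read.delim(config$category_table,
                                        stringsAsFactors = FALSE)[, 1:2],
                      c("gene_id", "category"))
    } else config$category_table
    enrichment <- cluster_enrichment(cats, igs_genes, clustering$labels)
  }

  # --- artifacts ------------------------------------------------------------
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(name) file.path(config$out_dir, name)
    files <- c(
      write_igs_fasta(igs, out("igs.fasta")),
      write_tsv(igr, out("igr_lengths.tsv")),
      write_tsv(rigr, out("rigr_lengths.tsv")),
      write_matrix_tsv(S, out("similarity.tsv")),
      write_tsv(tibble(method = thr$method, s_star = thr$s_star,
                       seed = config$seed), out("threshold.tsv")),
      write_tsv(tibble(index = seq_along(clustering$eigenvalues),
                       eigenvalue = clustering$eigenvalues),
                out("spectrum.tsv")),
      write_tsv(clustering$labels, out("labels.tsv")),
      write_tsv(clustering$silhouette, out("silhouette.tsv")),
      write_tsv(as.data.frame(clustering$embedding), out("embedding.tsv")),
      write_tsv(profiles, out("bca.tsv")),
      write_tsv(segments, out("segments.tsv"))
    )
    if (!is.null(network)) files <- c(files, write_tsv(network, out("network.tsv")))
    if (!is.null(enrichment)) {
      files <- c(files, write_tsv(enrichment, out("enrichment.tsv")))
    }
    manifest <- list(
      seed = config$seed, window_length = L,
      sds_search_len = config$sds_search_len,
      alignment = config$alignment, threshold = config$threshold,
      k = clustering$k, suggested_k = clustering$suggested_k,
      n_igs = nrow(igs),
      sds_fraction = mean(!is.na(igs$sds_motif)),
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
    )
    writeLines(yaml::as.yaml(manifest), out("manifest.yaml"))
    writeLines(log_lines, out("run.log"))
  }

  structure(list(igs = labelled, tus = tus, igr = igr, rigr = rigr,
                 window_length = L, threshold = thr, similarity = S,
                 adjacency = adj, clustering = clustering, bca = profiles,
                 segments = segments, network = network,
                 enrichment = enrichment, manifest = manifest),
            class = "igs_run")
}

#' @export
print.igs_run <- function(x, ...) {
  cat(sprintf("<igs_run> %d IGSs of %d bp; k=%d\n", nrow(x$igs),
              x$window_length - 25L, x$clustering$k))
  print(x$clustering)
  invisible(x)
}
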