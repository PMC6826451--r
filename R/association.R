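# association_analysis: interaction-network statistics with resampling
# nulls, and exact binomial functional-category enrichment.

#' Read a gene-gene interaction score table
#'
#' Three-column TSV `gene1<TAB>gene2<TAB>score` (header optional) with
#' integer scores in 0..1000, one row per undirected pair, in the style of
#' interaction-database channel exports.
#'
#' @param path TSV path.
#' @return Tibble `gene1`, `gene2`, `score`.
#' @export
read_score_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("score table needs columns gene1, gene2, score")
  names(raw)[1:3] <- c("gene1", "gene2", "score")
  if (identical(tolower(raw$gene1[1]), "gene1")) raw <- raw[-1, ]
  raw$score <- as.numeric(raw$score)
  if (any(is.na(raw$score)) || any(raw$score < 0 | raw$score > 1000)) {
    stop("scores must be numbers in 0..1000")
  }
  as_tibble(raw[, 1:3])
}

#' Threshold a score table into an unweighted interaction network
#'
#' Keeps edges whose score strictly overtakes `threshold` (default 700,
#' giving a sparse, high-confidence graph); weights and self-edges are
#' discarded.
#'
#' @param score_table tibble `gene1`, `gene2`, `score` (see
#'   [read_score_table()]).
#' @param threshold score cutoff; strict by default.
#' @param strict if `FALSE`, keep edges with score `>= threshold`.
#' @return An undirected [igraph::graph_from_data_frame()] graph.
#' @export
build_network <- function(score_table, threshold = 700, strict = TRUE) {
  keep <- if (strict) score_table$score > threshold else
    score_table$score >= threshold
  edges <- score_table[keep & score_table$gene1 != score_table$gene2,
                       c("gene1", "gene2")]
  nodes <- unique(c(score_table$gene1, score_table$gene2))
  igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE,
                                                 vertices = nodes))
}

#' Largest-connected-component statistics of an induced subgraph
#'
#' Induces the subgraph on `gene_subset` (ids absent from the graph count
#' as isolated nodes), finds the largest connected component — ties broken
#' by more internal edges, then by the lexicographically smallest member —
#' and returns its node and edge counts. An edgeless induced graph gives
#' `N_LCC = 1`, `N_link = 0`.
#'
#' @param graph an igraph graph (see [build_network()]).
#' @param gene_subset character vector of gene ids.
#' @return Named list `n_lcc`, `n_link`.
#' @export
lcc_stats <- function(graph, gene_subset) {
  gene_subset <- unique(gene_subset)
  if (!length(gene_subset)) stop("empty gene subset")
  present <- intersect(gene_subset, igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, present)
  if (!igraph::gorder(sub) || !igraph::ecount(sub)) {
    return(list(n_lcc = 1L, n_link = 0L))
  }
  comp <- igraph::components(sub)
  best_size <- max(comp$csize)
  cands <- which(comp$csize == best_size)
  if (length(cands) > 1L) {
    edges <- vapply(cands, function(c) {
      igraph::ecount(igraph::induced_subgraph(sub, which(comp$membership == c)))
    }, numeric(1))
    cands <- cands[edges == max(edges)]
    if (length(cands) > 1L) {
      first_member <- vapply(cands, function(c) {
        min(igraph::V(sub)$name[comp$membership == c])
      }, character(1))
      cands <- cands[order(first_member)[1]]
    }
  }
  lcc_nodes <- which(comp$membership == cands[1])
  list(n_lcc = as.integer(best_size),
       n_link = as.integer(igraph::ecount(igraph::induced_subgraph(sub, lcc_nodes))))
}

#' Resampling null for cluster network statistics
#'
#' Draws `cluster_size` IGSs uniformly without replacement from the full
#' IGS set, expands each to its member genes, and records the LCC node and
#' edge counts of the induced network; repeated `n_resamples` times. Null
#' means, sample standard deviations (divisor n-1) and z-scores for the
#' observed statistics are returned. Resampling whole IGSs preserves the
#' operon structure of each draw.
#'
#' @param graph interaction network ([build_network()]).
#' @param igs_genes named list mapping each IGS/transcription-unit id to
#'   its member gene ids.
#' @param cluster_size number of IGSs per resample (the observed cluster's
#'   size).
#' @param observed named list/vector with observed `n_lcc`, `n_link`.
#' @param n_resamples number of resamples (default 1000).
#' @return Tibble row: `n_lcc`, `n_link`, `null_mean_lcc`, `null_sd_lcc`,
#'   `z_lcc`, `null_mean_link`, `null_sd_link`, `z_link`,
#'   `degenerate_null` (TRUE when an sd is zero; the z is `NA` then).
#' @export
resampling_null <- function(graph, igs_genes, cluster_size, observed,
                            n_resamples = 1000L) {
  stopifnot(cluster_size >= 1L, cluster_size <= length(igs_genes))
  ids <- names(igs_genes)
  draws <- matrix(0L, n_resamples, 2L)
  for (r in seq_len(n_resamples)) {
    take <- sample(ids, cluster_size)
    st <- lcc_stats(graph, unlist(igs_genes[take], use.names = FALSE))
    draws[r, ] <- c(st$n_lcc, st$n_link)
  }
  mu <- colMeans(draws)
  sdv <- apply(draws, 2, sd)
  z <- ifelse(sdv > 0, (c(observed$n_lcc, observed$n_link) - mu) / sdv, NA_real_)
  tibble(n_lcc = observed$n_lcc, n_link = observed$n_link,
         null_mean_lcc = mu[1], null_sd_lcc = sdv[1], z_lcc = z[1],
         null_mean_link = mu[2], null_sd_link = sdv[2], z_link = z[2],
         degenerate_null = any(sdv == 0))
}

#' Per-cluster network association statistics
#'
#' For each cluster of IGSs: the induced interaction network's LCC node
#' and edge counts, against a resampling null of equally sized random IGS
#' draws.
#'
#' @param graph interaction network ([build_network()]).
#' @param igs_genes named list: IGS id -> member gene ids.
#' @param labels tibble `id`, `cluster`.
#' @param n_resamples resamples per cluster (default 1000).
#' @return Tibble, one row per cluster: `cluster`, `n_igs`, `n_genes`,
#'   and the [resampling_null()] columns.
#' @export
network_association <- function(graph, igs_genes, labels,
                                n_resamples = 1000L) {
  purrr::map_dfr(sort(unique(labels$cluster)), function(cl) {
    ids <- labels$id[labels$cluster == cl]
    genes <- unlist(igs_genes[ids], use.names = FALSE)
    obs <- lcc_stats(graph, genes)
    null <- resampling_null(graph, igs_genes, length(ids), obs, n_resamples)
    bind_cols(tibble(cluster = cl, n_igs = length(ids),
                     n_genes = length(unique(genes))), null)
  })
}

#' Exact binomial functional-category enrichment
#'
#' For each category, tests whether its count among a cluster's annotated
#' genes departs from the genomic background proportion, with an exact
#' two-sided binomial test (`p = min(1, 2 * min(lower tail, upper tail))`).
#' Direction is `"over"` when the cluster fraction exceeds the background
#' proportion. Benjamini-Hochberg adjusted p-values are reported alongside
#' the raw ones.
#'
#' @param cluster_counts named integer vector (or table): category counts
#'   among the cluster's genes.
#' @param background_counts named integer vector (or table): category
#'   counts over the genomic background.
#' @return Tibble: `category`, `k`, `n`, `p_background`, `direction`,
#'   `p_value`, `p_adjusted`; categories unseen in the background or with
#'   an empty cluster are skipped.
#' @export
binomial_enrichment <- function(cluster_counts, background_counts) {
  bg <- as.integer(background_counts)
  names(bg) <- names(background_counts)
  total_bg <- sum(bg)
  n <- sum(as.integer(cluster_counts))
  if (n == 0L) {
    return(tibble(category = character(), k = integer(), n = integer(),
                  p_background = double(), direction = character(),
                  p_value = double(), p_adjusted = double()))
  }
  cats <- names(bg)[bg > 0 & bg < total_bg]
  rows <- purrr::map_dfr(cats, function(cat) {
    k <- as.integer(cluster_counts[cat])
    if (is.na(k)) k <- 0L
    p <- bg[[cat]] / total_bg
    lower <- pbinom(k, n, p)
    upper <- pbinom(k - 1L, n, p, lower.tail = FALSE)
    tibble(category = cat, k = k, n = n, p_background = p,
           direction = if (k / n >= p) "over" else "under",
           p_value = min(1, 2 * min(lower, upper)))
  })
  mutate(rows, p_adjusted = stats::p.adjust(.data$p_value, method = "BH"))
}

#' Category enrichment for every cluster
#'
#' Joins a gene -> category table with cluster labels (through the IGS ->
#' genes map) and runs [binomial_enrichment()] per cluster against the
#' whole-table background.
#'
#' @param categories tibble `gene_id`, `category` (one category per gene).
#' @param igs_genes named list: IGS id -> member gene ids.
#' @param labels tibble `id`, `cluster`.
#' @return Tibble with a `cluster` column ahead of the
#'   [binomial_enrichment()] columns.
#' @export
cluster_enrichment <- function(categories, igs_genes, labels) {
  background <- table(categories$category)
  purrr::map_dfr(sort(unique(labels$cluster)), function(cl) {
    genes <- unique(unlist(igs_genes[labels$id[labels$cluster == cl]],
                           use.names = FALSE))
    counts <- table(categories$category[categories$gene_id %in% genes])
    res <- binomial_enrichment(counts, background)
    if (nrow(res)) mutate(res, cluster = cl, .before = 1) else res
  })
}
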