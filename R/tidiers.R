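# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a clustering result
#'
#' One row per clustered IGS: cluster label, silhouette value and the
#' first two embedding coordinates.
#'
#' @param x an `igs_clustering` from [spectral_cluster()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.igs_clustering <- function(x, ...) {
  emb <- as_tibble(x$embedding[, seq_len(min(2L, ncol(x$embedding))),
                               drop = FALSE],
                   .name_repair = ~ paste0("dim", seq_along(.x)))
  bind_cols(x$labels, select(x$silhouette, silhouette = "s"), emb)
}

#' One-row summary of a clustering result
#'
#' @param x an `igs_clustering`.
#' @param ... unused.
#' @return Tibble: `n`, `k`, `suggested_k`, `mean_silhouette`,
#'   `min_cluster_size`, `n_unclustered`.
#' @export
glance.igs_clustering <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  tibble(n = nrow(x$labels), k = x$k, suggested_k = x$suggested_k,
         mean_silhouette = mean(x$silhouette$s),
         min_cluster_size = as.integer(min(sizes)),
         n_unclustered = length(x$unclustered_ids))
}

#' Plot the clustering space
#'
#' Scatter of the first two embedding coordinates, colored by cluster.
#'
#' @param object an `igs_clustering`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.igs_clustering <- function(object, ...) {
  d <- tidy(object)
  if (!"dim2" %in% names(d)) d$dim2 <- 0
  ggplot2::ggplot(d, ggplot2::aes(.data$dim1, .data$dim2,
                                  color = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "embedding dim 1", y = "embedding dim 2",
                  color = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a base-composition profile
#'
#' Positional nucleotide densities (smoothed when available), one line per
#' nucleotide, optionally faceted by cluster.
#'
#' @param object an `igs_bca` tibble from [bca()] / [smooth_bca()], or the
#'   per-cluster profile table of an `igs_run`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.igs_bca <- function(object, ...) {
  y <- if ("smoothed" %in% names(object)) "smoothed" else "density"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$position, .data[[y]],
                                    color = .data$nucleotide)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position upstream of TSS (bp)",
                  y = "nucleotide density") +
    ggplot2::theme_minimal()
  if ("cluster" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~cluster)
  }
  p
}

#' Plot the Laplacian spectrum and eigengap
#'
#' Ascending eigenvalues with the suggested k marked; the visual analogue
#' of reading the eigengap off the spectrum.
#'
#' @param x an `igs_clustering` (or an `igs_run`).
#' @param n_show how many leading eigenvalues to show (default 20).
#' @return A ggplot.
#' @export
plot_spectrum <- function(x, n_show = 20L) {
  if (inherits(x, "igs_run")) x <- x$clustering
  d <- tibble(index = seq_along(x$eigenvalues),
              eigenvalue = x$eigenvalues)[seq_len(min(n_show, length(x$eigenvalues))), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$suggested_k + 0.5, linetype = 2) +
    ggplot2::labs(x = "eigenvalue index (ascending)",
                  y = expression(lambda[i])) +
    ggplot2::theme_minimal()
}
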