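# Survey plots.

#' Histogram of k-mer relative abundances
#'
#' Shows the distribution of (non-zero) relative abundances, by default on a
#' log10 axis — for WGA single-cell data the compositional values typically
#' look log-Laplacian. A qualitative diagnostic, not a test.
#'
#' @param a A `kmer_abundance`.
#' @param log10 Plot `log10(abundance)` instead of the raw values.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_abundance_histogram <- function(a, log10 = TRUE, bins = 80) {
  stopifnot(inherits(a, "kmer_abundance"))
  x <- a$values@x
  x <- x[x > 0]
  df <- data.frame(abundance = if (log10) base::log10(x) else x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abundance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::labs(x = if (log10) "log10 relative abundance"
                  else "relative abundance",
                  y = "k-mer count") +
    ggplot2::theme_minimal()
}

#' Consensus phylogeny with class-colored tips
#'
#' @param tree An `ape::phylo`, e.g. from [majority_consensus()].
#' @param labels Optional tibble `sample_id`/`class` (or `cell_id`/
#'   `clone_id`) used to color tips.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, the tree.
#' @export
plot_phylogeny <- function(tree, labels = NULL, ...) {
  tip_col <- "black"
  if (!is.null(labels)) {
    lab <- check_labels(labels, tree$tip.label)
    cls <- factor(lab$class)
    pal <- grDevices::hcl.colors(nlevels(cls), "Dark 3")
    tip_col <- pal[as.integer(cls)]
  }
  ape::plot.phylo(tree, type = "unrooted", tip.color = tip_col,
                  cex = 0.7, ...)
  if (!is.null(tree$node.label))
    ape::nodelabels(tree$node.label, frame = "none", cex = 0.6,
                    adj = c(1.1, -0.3))
  invisible(tree)
}
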