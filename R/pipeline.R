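# End-to-end convenience wrapper.

#' Bootstrap consensus phylogeny from an abundance matrix
#'
#' Runs the phylogeny branch of the workflow in one call: sample distances
#' under the chosen metric, a point-estimate neighbor-joining tree,
#' `n_replicates` feature-bootstrap trees, and their majority-rule consensus.
#'
#' @param a A `kmer_abundance` (TSS-normalized, presence-filtered).
#' @param metric `"euclidean"` (default, used for trees) or `"bray-curtis"`.
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param extended Extended majority rule for the consensus.
#' @return List with `distances` (`kmer_dist`), `tree` (point-estimate NJ),
#'   `consensus` (`phylo` with supports), and `splits` (support tibble).
#' @export
build_phylogeny <- function(a, metric = c("euclidean", "bray-curtis"),
                            n_replicates = 1000, seed = 1L,
                            extended = TRUE) {
  metric <- match.arg(metric)
  d <- sample_distances(a, metric)
  tree <- suppressMessages(neighbor_joining(d))
  reps <- bootstrap_trees(a, n_replicates, seed = seed, metric = metric)
  cons <- majority_consensus(reps, extended = extended)
  list(distances = d, tree = tree, consensus = cons$tree,
       splits = cons$splits)
}
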