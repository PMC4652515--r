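# Fixtures are built in code: small matrices, random additive trees, and a
# cached small two-clone simulation shared across test files.

# dense matrix -> kmer_matrix (row/col names required)
as_kmer_matrix <- function(m, k = 3, normalized = FALSE) {
  kmerphylo:::new_kmer_matrix(
    Matrix::Matrix(m, sparse = TRUE, dimnames = dimnames(m)),
    k = k, normalized = normalized)
}

random_count_matrix <- function(n_kmers, n_samples, max_count = 20,
                                seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_kmers * n_samples, max_count / 4), n_kmers,
              dimnames = list(
                replicate(n_kmers,
                          paste(sample(c("A", "C", "G", "T"), 8,
                                       replace = TRUE), collapse = "")),
                paste0("s", seq_len(n_samples))))
  rownames(m) <- make.unique(rownames(m), sep = "")
  m
}

# random unrooted binary tree with positive branch lengths and its additive
# (path-length) matrix
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) runif(n, 0.5, 3))
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  list(tree = tree, d = d)
}

# unrooted topology equality via Robinson-Foulds distance
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}

# one small shared two-clone simulation (cheap: 8 kb, 6 cells/clone, k = 9)
small_sim_cache <- new.env()
small_two_clone <- function() {
  if (!is.null(small_sim_cache$sim)) return(small_sim_cache$sim)
  cfg <- sim_config(n_cells_per_clone = 6, coverage = 10,
                    error_rate = 0.002, wga_sigma = 0.2, seed = 99)
  sim <- simulate_two_clone_dataset(ref_length = 8000, n_segments = 8,
                                    n_diverged = 3, fold = 3, cfg = cfg)
  spectra <- Map(function(r, id) count_kmers(r, k = 9, sample_id = id),
                 sim$reads, names(sim$reads))
  sim$matrix <- merge_spectra(unname(spectra))
  sim$prep <- prepare_matrix(sim$matrix)
  small_sim_cache$sim <- sim
  sim
}

# exact two-sided rank-sum p-value by enumerating all C(n1+n2, n1) group
# assignments (independent oracle; no ties assumed)
enumerate_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (w_obs >= mu) {
    p <- 2 * mean(w_all >= w_obs)
  } else {
    p <- 2 * mean(w_all <= w_obs)
  }
  min(1, p)
}
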