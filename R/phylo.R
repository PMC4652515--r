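# Neighbor-joining trees, feature-bootstrap replication, and majority-rule
# consensus.
#
# The tree over cells is built by the Saitou-Nei neighbor-joining
# agglomeration from the sample distance matrix. Split support is estimated
# by resampling k-mer features with replacement, recomputing distances, and
# rebuilding the tree; the consensus keeps splits present in more than half
# of the replicates (optionally extended greedily with compatible minority
# splits, as PHYLIP's consense does by default).

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R` the row sums
#' over the `r` active nodes), attach both to a new node with the standard
#' branch lengths, and reduce the matrix. On an additive matrix the result is
#' the unique generating tree. Ties in Q are broken deterministically by the
#' lexicographically smallest pair of node labels (an internal node carries
#' the smallest leaf label in its cluster).
#'
#' Negative branch lengths can arise on non-additive input; they are kept and
#' signalled with a message unless `clamp_negative = TRUE`, which zeroes the
#' negative branch and transfers its length to the sister branch.
#'
#' @param d A `dist`/`kmer_dist` (or symmetric matrix) over at least 3
#'   samples; must be symmetric with non-negative entries.
#' @param clamp_negative Zero negative branch lengths, transferring length to
#'   the sister edge.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @examples
#' m <- matrix(c(0, 3, 7, 3, 0, 6, 7, 6, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' neighbor_joining(as.dist(m))
#' @export
neighbor_joining <- function(d, clamp_negative = FALSE) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3) stop("neighbor joining needs at least 3 samples")
  if (any(m < 0)) stop("distance matrix has negative entries")
  if (any(abs(m - t(m)) > 1e-9)) stop("distance matrix is not symmetric")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # subtree Newick fragments; tie-break labels carry the smallest leaf label
  sub <- labels
  tie_lab <- labels
  saw_negative <- FALSE
  join_lengths <- function(li, lj) {
    if (li < 0 || lj < 0) saw_negative <<- TRUE
    if (clamp_negative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
    }
    c(li, lj)
  }
  while (nrow(m) > 3) {
    r <- nrow(m)
    R <- rowSums(m)
    Q <- (r - 2) * m - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      key <- apply(cand, 1, function(ij) {
        paste(sort(c(tie_lab[ij[1]], tie_lab[ij[2]])), collapse = "\r")
      })
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- m[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- m[i, j] - li
    l <- join_lengths(li, lj)
    new_sub <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], l[1], sub[j], l[2])
    new_lab <- min(tie_lab[i], tie_lab[j])
    dk <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    m <- rbind(cbind(m[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    tie_lab <- c(tie_lab[keep], new_lab)
  }
  l1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  l2 <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  l3 <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  if (any(c(l1, l2, l3) < 0)) saw_negative <- TRUE
  if (clamp_negative) {
    # at the trinode, redistribute pairwise to preserve path lengths as far
    # as possible while keeping edges non-negative
    l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  }
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 sub[1], l1, sub[2], l2, sub[3], l3)
  tree <- ape::read.tree(text = nwk)
  if (saw_negative && !clamp_negative)
    message("neighbor_joining: negative branch length(s) present ",
            "(non-additive input)")
  attr(tree, "negative_branches") <- saw_negative
  tree
}

#' Feature-bootstrap neighbor-joining replicates
#'
#' Each replicate resamples the k-mer features (matrix rows) with replacement
#' to the original row count, recomputes the sample distance matrix under the
#' chosen metric, and rebuilds the neighbor-joining tree. For the Euclidean
#' metric the resample is applied as multinomial feature weights, which is
#' distributionally identical and avoids materializing the resampled matrix.
#'
#' @param a A `kmer_abundance` (or features x samples matrix).
#' @param n_replicates Number of bootstrap replicates (0 gives an empty
#'   list).
#' @param seed Integer seed; fixed seed gives an identical replicate list.
#' @param metric `"euclidean"` or `"bray-curtis"`.
#' @param clamp_negative Passed to [neighbor_joining()].
#' @return A `multiPhylo` list of trees.
#' @export
bootstrap_trees <- function(a, n_replicates = 1000, seed = 1L,
                            metric = c("euclidean", "bray-curtis"),
                            clamp_negative = FALSE) {
  metric <- match.arg(metric)
  v <- abundance_matrix_input(a)
  stopifnot(ncol(v) >= 3, nrow(v) >= 2, n_replicates >= 0)
  set.seed(seed)
  trees <- vector("list", n_replicates)
  nf <- nrow(v)
  for (b in seq_len(n_replicates)) {
    d <- if (metric == "euclidean") {
      w <- as.vector(rmultinom(1, nf, rep(1 / nf, nf)))
      weighted_euclidean(v, w)
    } else {
      idx <- sample.int(nf, nf, replace = TRUE)
      vegan::vegdist(t(v[idx, , drop = FALSE]), method = "bray")
    }
    trees[[b]] <- suppressMessages(neighbor_joining(d, clamp_negative))
  }
  class(trees) <- "multiPhylo"
  trees
}

# feature-weighted Euclidean distances between columns via one crossproduct:
# d(i,j)^2 = sum_f w_f (v[f,i] - v[f,j])^2
weighted_euclidean <- function(v, w) {
  C <- crossprod(v, w * v)
  s <- diag(C)
  d2 <- pmax(outer(s, s, "+") - 2 * C, 0)
  stats::as.dist(sqrt((d2 + t(d2)) / 2))
}

# canonical split key: tip indices (in ref_labels order) on the side not
# containing tip 1, sorted
tree_splits <- function(tree, ref_labels) {
  n <- length(ref_labels)
  parts <- ape::prop.part(tree)
  idx_map <- match(tree$tip.label, ref_labels)
  out <- list()
  for (p in parts) {
    side <- sort(idx_map[p])
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    if (length(side) < 2 || length(side) > n - 2) next
    out[[paste(side, collapse = ",")]] <- side
  }
  out
}

splits_compatible <- function(a, b) {
  # both exclude tip 1: compatible iff nested or disjoint
  int <- length(intersect(a, b))
  int == 0 || int == length(a) || int == length(b)
}

#' Majority-rule consensus of bootstrap trees
#'
#' Keeps the non-trivial leaf bipartitions present in more than half of the
#' input trees and assembles them into a tree, attaching each split's support
#' (fraction of replicates) as its internal node label. With
#' `extended = TRUE` (default), remaining splits are added greedily in order
#' of decreasing support when compatible with the tree so far, matching
#' PHYLIP `consense`'s extended majority rule.
#'
#' @param trees A `multiPhylo`/list of trees over an identical leaf set.
#' @param extended Resolve further with compatible minority splits.
#' @return List with `tree` (an `ape::phylo`, support fractions as
#'   `node.label`) and `splits`, a tibble with columns `split` (semicolon-free
#'   comma-joined tip labels of the smaller side), `count`, `support`, and
#'   `in_consensus`.
#' @export
majority_consensus <- function(trees, extended = TRUE) {
  stopifnot(length(trees) >= 1)
  ref_labels <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, ref_labels) ||
        length(t$tip.label) != length(ref_labels))
      stop("all trees must share an identical leaf set")
  n <- length(ref_labels)
  counts <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  for (t in trees) {
    for (key in names(tree_splits(t, ref_labels))) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], numeric(1))
  sets <- lapply(strsplit(keys, ","), as.integer)
  nrep <- length(trees)
  ord <- order(-cnt, keys)
  accepted <- list()
  accepted_keys <- character()
  for (o in ord) {
    majority <- cnt[o] * 2 > nrep
    if (!majority && !extended) break # ord is sorted by decreasing support
    compatible <- all(vapply(accepted, splits_compatible, logical(1),
                             b = sets[[o]]))
    if (compatible) {
      accepted[[length(accepted) + 1]] <- sets[[o]]
      accepted_keys <- c(accepted_keys, keys[o])
    }
  }
  tree <- splits_to_tree(accepted,
                         support = cnt[match(accepted_keys, keys)] / nrep,
                         ref_labels)
  split_label <- vapply(sets, function(s) {
    side <- if (length(s) <= n - length(s)) s else setdiff(seq_len(n), s)
    paste(ref_labels[side], collapse = ",")
  }, character(1))
  splits <- tibble::tibble(split = unname(split_label),
                           count = as.integer(unname(cnt)),
                           support = unname(cnt) / nrep,
                           in_consensus = keys %in% accepted_keys)
  splits <- dplyr::arrange(splits, dplyr::desc(.data$support), .data$split)
  list(tree = tree, splits = splits)
}

# Build a phylo from compatible clades (subsets of 2..n excluding tip 1),
# rooted on tip 1's side, supports as node labels.
splits_to_tree <- function(clades, support, ref_labels) {
  n <- length(ref_labels)
  sizes <- vapply(clades, length, integer(1))
  ord <- order(-sizes)
  clades <- clades[ord]
  support <- support[ord]
  build <- function(members, available) {
    # available: indices into clades still unplaced, all subsets of members
    tops <- c()
    for (ci in available) {
      inside <- any(vapply(tops, function(tj)
        all(clades[[ci]] %in% clades[[tj]]), logical(1)))
      if (!inside) tops <- c(tops, ci)
    }
    parts <- character()
    covered <- integer()
    for (ci in tops) {
      sub_avail <- setdiff(available[vapply(available, function(x)
        all(clades[[x]] %in% clades[[ci]]), logical(1))], ci)
      parts <- c(parts, paste0(build(clades[[ci]], sub_avail),
                               format(support[ci], digits = 4)))
      covered <- c(covered, clades[[ci]])
    }
    loose <- setdiff(members, covered)
    parts <- c(parts, ref_labels[loose])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(build(seq_len(n)[-1], seq_along(clades)), ";")
  # tip 1 attaches at the root trifurcation
  nwk <- sub("^\\(", paste0("(", ref_labels[1], ","), nwk)
  tree <- ape::read.tree(text = nwk)
  ape::unroot(tree)
}

#' Newick serialization helpers
#'
#' Thin wrappers over [ape::write.tree()]/[ape::read.tree()]; consensus
#' supports travel as internal node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path File path (`write_newick`) or file/`text=` source
#'   (`read_newick`).
#' @return `write_newick` returns `path` invisibly; `read_newick` a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
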