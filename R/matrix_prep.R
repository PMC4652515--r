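# Noise correction and normalization of the k-mer count matrix.
#
# Whole-genome-amplified single-cell reads carry three matrix-level noise
# signatures handled here: sequencing errors show up as k-mers with sparse
# occurrences (dropped below a count threshold); WGA unevenness means a region
# may amplify in one cell and not another (only k-mers present in all -- or a
# configurable fraction of -- samples are kept); and amplified duplicate
# libraries yield cells with identical spectra (detected and dropped). Depth
# differences are removed by Total Sum Scaling, performed after the filters so
# each sample's denominator is the sum over the retained k-mer set.

new_filter_report <- function(n_input, n_removed_sparse = 0L,
                              n_removed_not_ubiquitous = 0L,
                              removed_duplicate_samples = character()) {
  n_retained <- n_input - n_removed_sparse - n_removed_not_ubiquitous
  structure(list(n_input_kmers = n_input,
                 n_removed_sparse = n_removed_sparse,
                 n_removed_not_ubiquitous = n_removed_not_ubiquitous,
                 n_retained = n_retained,
                 removed_duplicate_samples = removed_duplicate_samples),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n",
      "  input k-mers:          ", x$n_input_kmers, "\n",
      "  removed (sparse):      ", x$n_removed_sparse, "\n",
      "  removed (not in all):  ", x$n_removed_not_ubiquitous, "\n",
      "  retained:              ", x$n_retained, "\n", sep = "")
  if (length(x$removed_duplicate_samples))
    cat("  dropped duplicate samples: ",
        paste(x$removed_duplicate_samples, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    stage = c("input", "removed_sparse", "removed_not_ubiquitous",
              "retained"),
    n_kmers = c(x$n_input_kmers, x$n_removed_sparse,
                x$n_removed_not_ubiquitous, x$n_retained))
}

#' Drop sparsely occurring k-mer counts
#'
#' Sequencing errors generate k-mers seen only a handful of times; entries
#' with count below `min_count` are zeroed per sample, and k-mers left with no
#' support in any sample are removed.
#'
#' @param m A `kmer_matrix` of raw counts.
#' @param min_count Minimum per-sample count to keep an entry (default 2;
#'   1 is the identity).
#' @return List with `matrix` (filtered `kmer_matrix`) and `report`
#'   (`filter_report`).
#' @export
filter_sparse <- function(m, min_count = 2) {
  stopifnot(inherits(m, "kmer_matrix"), !m$normalized, min_count >= 1)
  v <- m$values
  v@x[v@x < min_count] <- 0
  v <- Matrix::drop0(v)
  keep <- Matrix::rowSums(v) > 0
  report <- new_filter_report(nrow(m$values),
                              n_removed_sparse = sum(!keep))
  list(matrix = new_kmer_matrix(v[keep, , drop = FALSE], m$k),
       report = report)
}

#' Keep k-mers present in (a fraction of) all samples
#'
#' The strict WGA correction retains only k-mers with a positive count in
#' every sample (`presence_fraction = 1`). For data without amplification
#' dropout a laxer `presence_fraction` keeps k-mers present in at least that
#' fraction of samples.
#'
#' @param m A `kmer_matrix` of raw counts.
#' @param presence_fraction Required fraction of samples with a positive
#'   count, in (0, 1]; 1 means present in all.
#' @return List with `matrix` and `report`, as [filter_sparse()].
#' @export
filter_ubiquitous <- function(m, presence_fraction = 1) {
  stopifnot(inherits(m, "kmer_matrix"), ncol(m$values) >= 1,
            presence_fraction > 0, presence_fraction <= 1)
  present <- Matrix::rowSums(m$values > 0)
  keep <- present >= ceiling(presence_fraction * ncol(m$values))
  if (!any(keep))
    warning("no k-mer passes the presence filter; downstream stages need ",
            "at least 2 features")
  report <- new_filter_report(nrow(m$values),
                              n_removed_not_ubiquitous = sum(!keep))
  list(matrix = new_kmer_matrix(m$values[keep, , drop = FALSE], m$k),
       report = report)
}

#' Detect samples with identical k-mer counts
#'
#' Amplified duplicate libraries give byte-identical count vectors; all
#' unordered pairs of identical columns are reported (raw counts, exact
#' equality).
#'
#' @param m A `kmer_matrix`.
#' @return Tibble with columns `sample1`, `sample2`, one row per identical
#'   pair.
#' @export
detect_duplicates <- function(m) {
  stopifnot(inherits(m, "kmer_matrix"), ncol(m$values) >= 2)
  cols <- apply(as.matrix(m$values), 2, paste, collapse = "\r")
  groups <- unname(split(colnames(m$values), match(cols, unique(cols))))
  pairs <- lapply(groups, function(g) {
    if (length(g) < 2) return(NULL)
    g <- sort(g)
    t(combn(g, 2))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    return(tibble::tibble(sample1 = character(), sample2 = character()))
  tibble::tibble(sample1 = pairs[, 1], sample2 = pairs[, 2])
}

#' @describeIn detect_duplicates Drop the lexicographically later member of
#'   each duplicated group, keeping one representative.
#' @export
drop_duplicates <- function(m) {
  dup <- detect_duplicates(m)
  drop <- unique(dup$sample2)
  keep <- setdiff(colnames(m$values), drop)
  list(matrix = new_kmer_matrix(m$values[, keep, drop = FALSE], m$k,
                                normalized = m$normalized),
       removed = drop)
}

#' Total Sum Scaling normalization
#'
#' Each count is divided by its sample's total over the k-mers currently in
#' the matrix, yielding compositional relative abundances: every column sums
#' to 1.
#'
#' @param m A `kmer_matrix` of counts with strictly positive column sums.
#' @return A `kmer_abundance` (inherits from `kmer_matrix`).
#' @export
tss_normalize <- function(m) {
  stopifnot(inherits(m, "kmer_matrix"))
  totals <- Matrix::colSums(m$values)
  if (any(totals <= 0))
    stop("zero-sum sample(s): ",
         paste(colnames(m$values)[totals <= 0], collapse = ", "))
  v <- m$values %*% Matrix::Diagonal(x = 1 / totals)
  dimnames(v) <- dimnames(m$values)
  new_kmer_matrix(v, m$k, normalized = TRUE)
}

#' Standard noise-correction pipeline
#'
#' Applies, in order: sparse-occurrence filtering, the presence-in-all filter,
#' duplicate-sample removal, and TSS normalization. The combined report's
#' counts reconcile exactly: input = removed_sparse + removed_not_ubiquitous +
#' retained.
#'
#' @param m A `kmer_matrix` of raw counts.
#' @param min_count Passed to [filter_sparse()].
#' @param presence_fraction Passed to [filter_ubiquitous()].
#' @param drop_duplicates Whether to remove duplicated samples.
#' @return List with `abundance` (a `kmer_abundance`), `counts` (the filtered
#'   count matrix), and `report`.
#' @export
prepare_matrix <- function(m, min_count = 2, presence_fraction = 1,
                           drop_duplicates = TRUE) {
  s1 <- filter_sparse(m, min_count)
  s2 <- filter_ubiquitous(s1$matrix, presence_fraction)
  removed_dup <- character()
  counts <- s2$matrix
  if (drop_duplicates && ncol(counts$values) >= 2) {
    dd <- drop_duplicates(counts)
    counts <- dd$matrix
    removed_dup <- dd$removed
  }
  report <- new_filter_report(
    s1$report$n_input_kmers,
    n_removed_sparse = s1$report$n_removed_sparse,
    n_removed_not_ubiquitous = s2$report$n_removed_not_ubiquitous,
    removed_duplicate_samples = removed_dup)
  list(abundance = tss_normalize(counts), counts = counts, report = report)
}
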