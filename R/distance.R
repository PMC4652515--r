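# Sample-by-sample dissimilarities from relative-abundance matrices.
#
# Euclidean distance between abundance columns is the metric used for tree
# building; Bray-Curtis is provided for ordination-style surveys of
# compositional structure. Both are computed on the TSS-normalized,
# presence-filtered matrix by default — feature selection sits on the
# classification branch of the workflow, not the phylogeny branch.

new_dist_matrix <- function(d, metric) {
  attr(d, "metric") <- metric
  class(d) <- c("kmer_dist", "dist")
  d
}

#' @export
print.kmer_dist <- function(x, ...) {
  cat("<kmer_dist> ", attr(x, "Size"), " samples, metric: ",
      attr(x, "metric"), "\n", sep = "")
  print(stats::as.dist(unclass(x)))
  invisible(x)
}

validate_dist <- function(d) {
  m <- as.matrix(d)
  stopifnot(all(m >= 0), all(abs(m - t(m)) < 1e-12),
            all(abs(diag(m)) < 1e-12))
  invisible(d)
}

abundance_matrix_input <- function(a) {
  if (inherits(a, "kmer_matrix")) return(as.matrix(a$values))
  as.matrix(a)
}

#' Euclidean distances between samples
#'
#' `d(i, j) = sqrt(sum_f (a[f, i] - a[f, j])^2)` over the matrix's retained
#' k-mer features.
#'
#' @param a A `kmer_abundance` (or any features x samples matrix).
#' @return A `kmer_dist`, a [stats::dist] with a `metric` attribute.
#' @export
euclidean_distances <- function(a) {
  v <- abundance_matrix_input(a)
  if (ncol(v) < 2) stop("need at least 2 samples")
  d <- dist(t(v), method = "euclidean")
  validate_dist(new_dist_matrix(d, "euclidean"))
}

#' Bray-Curtis dissimilarities between samples
#'
#' `d(i, j) = sum_f |a[f,i] - a[f,j]| / sum_f (a[f,i] + a[f,j])`, bounded in
#' `[0, 1]`. For TSS-normalized columns (each summing to 1) this reduces to
#' half the L1 distance.
#'
#' @param a A `kmer_abundance` (or any non-negative features x samples
#'   matrix).
#' @return A `kmer_dist` with metric `"bray-curtis"`.
#' @export
bray_curtis <- function(a) {
  v <- abundance_matrix_input(a)
  if (ncol(v) < 2) stop("need at least 2 samples")
  if (any(v < 0)) stop("Bray-Curtis requires non-negative abundances")
  zero <- colSums(v) == 0
  if (sum(zero) >= 2)
    stop("all-zero samples make Bray-Curtis undefined: ",
         paste(colnames(v)[zero], collapse = ", "))
  d <- vegan::vegdist(t(v), method = "bray")
  validate_dist(new_dist_matrix(d, "bray-curtis"))
}

#' @describeIn euclidean_distances Dispatch on a metric name.
#' @param metric `"euclidean"` or `"bray-curtis"`.
#' @export
sample_distances <- function(a, metric = c("euclidean", "bray-curtis")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") euclidean_distances(a) else bray_curtis(a)
}

#' Write / read a square PHYLIP distance matrix
#'
#' The square PHYLIP dialect: first line the number of taxa, then one row per
#' taxon with the name padded to 10 characters followed by the distances.
#' Names longer than 10 characters are replaced by `t<i>` aliases recorded in
#' a sidecar `<path>.names` file (tab-separated `alias`, `name`), which
#' [read_phylip_dist()] restores automatically.
#'
#' @param d A `dist` (or `kmer_dist`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  m <- as.matrix(d)
  nm <- rownames(m)
  if (is.null(nm)) nm <- paste0("t", seq_len(nrow(m)))
  if (any(nchar(nm) > 10)) {
    alias <- paste0("t", seq_along(nm))
    utils::write.table(data.frame(alias = alias, name = nm),
                       paste0(path, ".names"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nm <- alias
  }
  lines <- c(format(nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(formatC(nm[i], width = -10),
                      paste(sprintf("%.9f", m[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1)
    stop("not a square PHYLIP distance file: ", path)
  nm <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    nm[i] <- fields[1]
    m[i, ] <- as.numeric(fields[-1])
  }
  sidecar <- paste0(path, ".names")
  if (file.exists(sidecar)) {
    map <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                             colClasses = "character")
    nm <- map$name[match(nm, map$alias)]
  }
  dimnames(m) <- list(nm, nm)
  new_dist_matrix(stats::as.dist(m), "unknown")
}
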