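# k-mer spectra and the k-mers x samples count matrix.
#
# A cell's genome content is summarized by the multiset of length-k substrings
# of its reads. Counting is strand-specific by default (a k-mer and its
# reverse complement are distinct keys); `canonical = TRUE` folds them
# together. Windows containing any non-ACGT symbol are skipped.

new_kmer_spectrum <- function(counts, k, sample_id) {
  structure(list(k = as.integer(k), sample_id = as.character(sample_id),
                 counts = counts, total = sum(as.numeric(counts))),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("<kmer_spectrum> sample ", x$sample_id, ": ", length(x$counts),
      " distinct ", x$k, "-mers, total ", format(x$total), "\n", sep = "")
  invisible(x)
}

read_sequences <- function(reads) {
  if (is.character(reads) && length(reads) >= 1 &&
      all(file.exists(reads))) {
    seqs <- unlist(lapply(reads, function(f) {
      x <- tryCatch(Biostrings::readDNAStringSet(f, format = "fastq"),
                    error = function(e) {
                      stop("failed to parse FASTQ '", f, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
      as.character(x)
    }))
    return(unname(seqs))
  }
  if (is.data.frame(reads)) {
    stopifnot("sequence" %in% names(reads))
    return(reads$sequence)
  }
  if (is.character(reads)) return(reads)
  stop("`reads` must be FASTQ path(s), a character vector of sequences, ",
       "or a tibble with a `sequence` column")
}

#' Count k-mers in a set of reads
#'
#' Every length-`k` window over the alphabet ACGT of every read is counted
#' once; windows containing any other symbol (e.g. N) are skipped, so a read
#' of length L contributes at most `L - k + 1` windows.
#'
#' @param reads FASTQ file path(s) (plain or gzipped), a character vector of
#'   read sequences, or a tibble with a `sequence` column (as produced by
#'   [simulate_reads()]).
#' @param k k-mer length, between 1 and 31.
#' @param sample_id Label for the resulting spectrum.
#' @param canonical If `TRUE`, a k-mer and its reverse complement are merged
#'   under the lexicographically smaller key. Off by default: spectra are
#'   strand-specific.
#' @return A `kmer_spectrum`: list with `k`, `sample_id`, `counts` (named
#'   integer vector, k-mers sorted), and `total`.
#' @examples
#' count_kmers("ACGT", k = 3)$counts
#' @export
count_kmers <- function(reads, k, sample_id = "sample", canonical = FALSE) {
  if (k < 1) stop("k must be >= 1")
  seqs <- read_sequences(reads)
  if (length(seqs) == 0) stop("`reads` is empty")
  counts <- cpp_count_kmers(seqs, as.integer(k), isTRUE(canonical))
  if (length(counts) == 0)
    warning("no length-", k, " window found (k exceeds every read length?); ",
            "spectrum is empty")
  new_kmer_spectrum(counts, k, sample_id)
}

new_kmer_matrix <- function(values, k, normalized = FALSE) {
  structure(list(values = values, k = as.integer(k),
                 normalized = isTRUE(normalized)),
            class = if (normalized) c("kmer_abundance", "kmer_matrix")
                    else "kmer_matrix")
}

#' @export
dim.kmer_matrix <- function(x) dim(x$values)

#' @export
dimnames.kmer_matrix <- function(x) dimnames(x$values)

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("<", if (x$normalized) "kmer_abundance" else "kmer_matrix", "> ",
      nrow(x$values), " ", x$k, "-mers x ", ncol(x$values), " samples",
      if (x$normalized) " (TSS relative abundances)", "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.kmer_matrix <- function(x, ...) as.matrix(x$values)

#' Long-format view of a k-mer matrix
#'
#' @param x A `kmer_matrix` or `kmer_abundance`.
#' @param ... Unused.
#' @return Tibble with columns `kmer`, `sample`, and `count` (or `abundance`
#'   for normalized matrices); zero entries are omitted.
#' @export
tidy.kmer_matrix <- function(x, ...) {
  tm <- methods::as(x$values, "TsparseMatrix")
  # a 0-row matrix normalizes its rownames to NULL; keep columns typed
  out <- tibble::tibble(
    kmer = as.character(rownames(x$values)[tm@i + 1L]),
    sample = as.character(colnames(x$values)[tm@j + 1L]),
    value = as.numeric(tm@x))
  names(out)[3] <- if (x$normalized) "abundance" else "count"
  dplyr::arrange(out, .data$kmer, .data$sample)
}

#' Merge per-sample spectra into a count matrix
#'
#' Rows are the union of observed k-mers (sorted); absent entries are zero and
#' stored sparsely. Column sums equal each spectrum's total.
#'
#' @param spectra List of [count_kmers()] results sharing the same `k` and
#'   with unique sample ids.
#' @return A `kmer_matrix` wrapping a sparse k-mers x samples count matrix.
#' @export
merge_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, logical(1), "kmer_spectrum")))
  ks <- vapply(spectra, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1)
    stop("all spectra must share the same k (got ",
         paste(unique(ks), collapse = ", "), ")")
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  kmers <- sort(unique(unlist(lapply(spectra, function(s) names(s$counts)))))
  i <- unlist(lapply(spectra, function(s) match(names(s$counts), kmers)))
  j <- rep(seq_along(spectra),
           vapply(spectra, function(s) length(s$counts), integer(1)))
  x <- unlist(lapply(spectra, function(s) unname(s$counts)))
  values <- Matrix::sparseMatrix(i = i, j = j, x = as.double(x),
                                 dims = c(length(kmers), length(spectra)),
                                 dimnames = list(kmers, ids))
  new_kmer_matrix(values, ks[1])
}

#' Count matrix straight from FASTQ files
#'
#' @param files FASTQ paths, one per cell; sample ids default to file names
#'   without extension.
#' @param k k-mer length.
#' @param sample_ids Optional sample labels, parallel to `files`.
#' @param canonical Passed to [count_kmers()].
#' @return A `kmer_matrix`.
#' @export
count_matrix_from_fastq <- function(files, k, sample_ids = NULL,
                                    canonical = FALSE) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(files))
  stopifnot(length(sample_ids) == length(files))
  merge_spectra(Map(function(f, id) count_kmers(f, k, id, canonical),
                    files, sample_ids))
}

#' Expected number of unique k-mers in a non-repetitive genome
#'
#' A genome of size `N` with no repeated k-length substring contains exactly
#' `N - k + 1` distinct k-mers.
#'
#' @param N Genome size in base pairs.
#' @param k k-mer length, `k <= N`.
#' @return `N - k + 1` as a double (exact for genome-scale N).
#' @examples
#' expected_unique_kmers(3e9, 25)
#' @export
expected_unique_kmers <- function(N, k) {
  if (k < 1) stop("k must be >= 1")
  if (N < k) stop("N must be >= k")
  N - k + 1
}

#' Size of the k-mer sequence space
#'
#' There are `4^k` DNA strings of length k. The value is returned as a double,
#' which represents it exactly for `k <= 26` (`4^26 < 2^53`); larger k errors
#' rather than silently losing precision.
#'
#' @param k k-mer length.
#' @return `4^k`, exact.
#' @examples
#' kmer_space_size(10) # 1048576
#' @export
kmer_space_size <- function(k) {
  if (k < 1) stop("k must be >= 1")
  if (k > 26) stop("4^k exceeds exact double precision for k > 26")
  4^k
}

#' Write / read the sparse count-matrix TSV dialect
#'
#' Three columns (`kmer`, `sample`, `count`), preceded by a header comment line
#' recording `k` and whether values are TSS-normalized. `dense = TRUE` writes a
#' k-mers x samples table instead (sensible only for small k).
#'
#' @param m A `kmer_matrix` or `kmer_abundance`.
#' @param path Output file; a `.gz` suffix gzips it.
#' @param dense Write the dense layout instead of sparse triplets.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, dense = FALSE) {
  stopifnot(inherits(m, "kmer_matrix"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kmerphylo k=%d normalized=%s samples=%s", m$k,
                     tolower(m$normalized),
                     paste(colnames(m$values), collapse = ",")), con)
  if (dense) {
    dm <- as.matrix(m$values)
    utils::write.table(data.frame(kmer = rownames(dm), dm,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    long <- tidy.kmer_matrix(m)
    names(long)[3] <- "count"
    utils::write.table(long, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1)
  hm <- regmatches(
    header,
    regexec("k=([0-9]+) normalized=(true|false) samples=([^ ]+)",
            header))[[1]]
  if (length(hm) != 4)
    stop("not a kmerphylo count-matrix file (bad header): ", path)
  k <- as.integer(hm[2])
  normalized <- hm[3] == "true"
  samples <- strsplit(hm[4], ",", fixed = TRUE)[[1]]
  tab <- utils::read.table(con, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "numeric"))
  kmers <- sort(unique(tab$kmer))
  values <- Matrix::sparseMatrix(i = match(tab$kmer, kmers),
                                 j = match(tab$sample, samples),
                                 x = tab[[3]],
                                 dims = c(length(kmers), length(samples)),
                                 dimnames = list(kmers, samples))
  new_kmer_matrix(values, k, normalized = normalized)
}
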