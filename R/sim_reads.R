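# Synthetic single-cell WGA read simulator.
#
# The generative model: a small reference genome is partitioned into segments;
# each clone carries an integer copy number per segment; a cell's genome is the
# concatenation of each segment repeated copy-number times. Reads are sampled
# segment-copy-wise with weights proportional to length times a per-cell,
# per-segment log-normal amplification factor (whole-genome amplification
# unevenness), uniform start positions, optional reverse-complement strand,
# and iid per-base substitution errors. Qualities are constant because no
# downstream stage consumes them.

#' Build a random reference genome partitioned into segments
#'
#' Generates a uniform-random DNA sequence of the requested length and divides
#' it into `n_segments` contiguous segments of near-equal size. Segments are
#' the unit at which clones gain or lose copies and at which amplification
#' unevenness acts.
#'
#' @param length Genome length in base pairs.
#' @param n_segments Number of contiguous segments partitioning the genome.
#' @param seed Integer seed; the same seed always yields the same genome.
#' @return An object of class `ref_genome`: a list with `sequence` (a single
#'   character string), `length`, and `segments`, a tibble with columns
#'   `segment`, `start`, `end` (1-based, inclusive).
#' @examples
#' ref <- make_reference(1000, n_segments = 4, seed = 1)
#' ref$segments
#' @export
make_reference <- function(length, n_segments, seed = 1L) {
  if (length < 1 || n_segments < 1)
    stop("`length` and `n_segments` must be positive")
  if (n_segments > length)
    stop("`n_segments` must not exceed `length`")
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  # near-equal partition: boundaries at round(i * length / n_segments)
  cuts <- round(seq_len(n_segments) * length / n_segments)
  starts <- c(1, head(cuts, -1) + 1)
  segments <- tibble::tibble(
    segment = seq_len(n_segments),
    start = as.integer(starts),
    end = as.integer(cuts)
  )
  structure(list(sequence = seq, length = as.integer(length),
                 segments = segments),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", x$length, " bp, ", nrow(x$segments), " segments\n",
      sep = "")
  invisible(x)
}

#' Define a clone by its per-segment copy numbers
#'
#' @param clone_id Clone label.
#' @param copy_number Non-negative integer vector, one entry per reference
#'   segment.
#' @param parent Parent clone label, or `NA` for the founding clone. Used only
#'   for bookkeeping; `simulate_dataset()` checks that the parent links form a
#'   rooted tree.
#' @return A `clone_profile` object.
#' @examples
#' clone_profile("A", c(2, 2, 1, 1))
#' @export
clone_profile <- function(clone_id, copy_number, parent = NA_character_) {
  copy_number <- as.integer(copy_number)
  if (any(is.na(copy_number)) || any(copy_number < 0))
    stop("copy numbers must be non-negative integers")
  structure(list(clone_id = as.character(clone_id),
                 copy_number = copy_number,
                 parent = as.character(parent)),
            class = "clone_profile")
}

#' Simulation settings for the read generator
#'
#' Defaults mirror the short-read single-nucleus regime the pipeline targets:
#' 48 bp reads and per-base substitution errors, with amplification unevenness
#' modeled as a per-cell, per-segment log-normal factor `exp(N(0, wga_sigma^2))`
#' multiplying the segment's sampling weight.
#'
#' @param n_cells_per_clone Cells simulated per clone.
#' @param read_length Read length in base pairs.
#' @param coverage Target fold-coverage of each cell genome; the number of
#'   reads is exactly `round(coverage * genome_length / read_length)`.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param wga_sigma Standard deviation of the log amplification factor; 0
#'   disables amplification unevenness.
#' @param revcomp_prob Probability that a read is reported on the reverse
#'   complement strand (0 keeps all reads forward).
#' @param seed Integer seed for all randomness downstream of the reference.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells_per_clone = 20L, read_length = 48L,
                       coverage = 20, error_rate = 0.005, wga_sigma = 0.3,
                       revcomp_prob = 0.5, seed = 1L) {
  stopifnot(read_length >= 1, coverage > 0,
            error_rate >= 0, error_rate <= 1,
            wga_sigma >= 0, revcomp_prob >= 0, revcomp_prob <= 1)
  structure(list(n_cells_per_clone = as.integer(n_cells_per_clone),
                 read_length = as.integer(read_length),
                 coverage = coverage, error_rate = error_rate,
                 wga_sigma = wga_sigma, revcomp_prob = revcomp_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Realize a cell genome from a clone's copy-number profile
#'
#' Concatenates each reference segment repeated `copy_number` times, in
#' segment order. The output length is the copy-number-weighted sum of segment
#' lengths.
#'
#' @param ref A `ref_genome`.
#' @param clone A `clone_profile` whose `copy_number` covers all segments.
#' @return A `cell_genome`: list with `sequence` and `pieces`, a tibble mapping
#'   each segment copy to its interval in the concatenated sequence (columns
#'   `segment`, `start`, `end`).
#' @export
simulate_cell_genome <- function(ref, clone) {
  stopifnot(inherits(ref, "ref_genome"), inherits(clone, "clone_profile"))
  cn <- clone$copy_number
  if (length(cn) != nrow(ref$segments))
    stop("copy_number must have one entry per reference segment (",
         nrow(ref$segments), ")")
  seg_seq <- substring(ref$sequence, ref$segments$start, ref$segments$end)
  idx <- rep(seq_along(cn), times = cn)
  if (length(idx) == 0) {
    warning("all copy numbers are zero: empty cell genome")
    return(structure(list(sequence = "",
                          pieces = tibble::tibble(segment = integer(),
                                                  start = integer(),
                                                  end = integer())),
                     class = "cell_genome"))
  }
  pieces_seq <- seg_seq[idx]
  len <- nchar(pieces_seq)
  end <- cumsum(len)
  pieces <- tibble::tibble(segment = idx,
                           start = as.integer(end - len + 1L),
                           end = as.integer(end))
  structure(list(sequence = paste(pieces_seq, collapse = ""), pieces = pieces),
            class = "cell_genome")
}

rev_comp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# iid per-base substitution across the whole read set; each error picks one of
# the three alternative bases uniformly
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  len <- nchar(seqs)
  hits <- which(runif(sum(len)) < error_rate)
  if (length(hits) == 0) return(seqs)
  cum0 <- c(0, cumsum(len))
  read_idx <- findInterval(hits - 0.5, cum0)
  pos <- hits - cum0[read_idx]
  old <- substring(seqs[read_idx], pos, pos)
  code <- match(old, bases) - 1L
  new <- bases[((code + sample.int(3, length(hits), replace = TRUE)) %% 4) + 1L]
  for (j in seq_along(hits))
    substr(seqs[read_idx[j]], pos[j], pos[j]) <- new[j]
  seqs
}

#' Sample sequencing reads from a cell genome
#'
#' Draws exactly `round(coverage * genome_length / read_length)` fixed-length
#' reads. Each segment copy's sampling weight is its length times a per-cell,
#' per-segment log-normal amplification factor (`wga_sigma`); read starts are
#' uniform within the chosen piece; each read is reverse-complemented with
#' probability `revcomp_prob`; bases are substituted independently with
#' probability `error_rate`.
#'
#' Randomness is drawn from the current RNG state; call `set.seed()` (or go
#' through [simulate_dataset()], which seeds from its config) for
#' reproducibility.
#'
#' @param genome A `cell_genome` from [simulate_cell_genome()], or a plain
#'   character string (treated as one segment).
#' @param cfg A [sim_config()].
#' @return Tibble with columns `read_id` and `sequence`.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.character(genome) && length(genome) == 1) {
    genome <- structure(
      list(sequence = genome,
           pieces = tibble::tibble(segment = 1L, start = 1L,
                                   end = nchar(genome))),
      class = "cell_genome")
  }
  stopifnot(inherits(genome, "cell_genome"))
  glen <- nchar(genome$sequence)
  if (glen == 0) stop("cannot sample reads from an empty genome")
  if (cfg$read_length > glen)
    stop("read_length (", cfg$read_length, ") exceeds genome length (", glen,
         ")")
  n_reads <- round(cfg$coverage * glen / cfg$read_length)
  pieces <- genome$pieces
  # pieces shorter than a read cannot yield one; they drop out of the pool
  plen <- pieces$end - pieces$start + 1L
  ok <- plen >= cfg$read_length
  if (!any(ok)) stop("no segment copy is long enough to hold a read")
  pieces <- pieces[ok, , drop = FALSE]
  plen <- plen[ok]
  # WGA factor is shared by all copies of the same segment within this cell
  n_seg <- max(pieces$segment)
  amp <- exp(rnorm(n_seg, 0, cfg$wga_sigma))
  w <- plen * amp[pieces$segment]
  piece_of <- sample.int(nrow(pieces), n_reads, replace = TRUE, prob = w)
  offset <- floor(runif(n_reads) * (plen[piece_of] - cfg$read_length + 1))
  start <- pieces$start[piece_of] + as.integer(offset)
  seqs <- substring(genome$sequence, start, start + cfg$read_length - 1L)
  if (cfg$revcomp_prob > 0) {
    flip <- runif(n_reads) < cfg$revcomp_prob
    if (any(flip)) seqs[flip] <- rev_comp(seqs[flip])
  }
  seqs <- inject_errors(seqs, cfg$error_rate)
  tibble::tibble(read_id = sprintf("read_%06d", seq_len(n_reads)),
                 sequence = seqs)
}

write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, " constant-quality simulation\n",
                    reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' Simulate a labeled multi-clone single-cell dataset
#'
#' Generates `cfg$n_cells_per_clone` cells for each clone, each with its own
#' amplification-unevenness draw, and returns the reads together with a truth
#' label table. With `out_dir` set, one FASTQ per cell plus a `labels.tsv`
#' (columns `cell_id`, `clone_id`) are written.
#'
#' @param ref A `ref_genome`.
#' @param clones List of [clone_profile()]s (at least two for downstream
#'   two-class analyses; one is allowed but warns).
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory for FASTQ + label output.
#' @return List with `reads` (named list of per-cell read tibbles), `labels`
#'   (tibble `cell_id`, `clone_id`), and `files` (tibble of written paths, or
#'   `NULL`).
#' @examples
#' ref <- make_reference(2000, 4, seed = 1)
#' clones <- list(clone_profile("A", c(2, 2, 1, 1)),
#'                clone_profile("B", c(1, 1, 2, 2), parent = "A"))
#' sim <- simulate_dataset(ref, clones,
#'                         sim_config(n_cells_per_clone = 2, coverage = 2))
#' sim$labels
#' @export
simulate_dataset <- function(ref, clones, cfg = sim_config(),
                             out_dir = NULL) {
  stopifnot(inherits(ref, "ref_genome"), length(clones) >= 1)
  ids <- vapply(clones, `[[`, character(1), "clone_id")
  if (anyDuplicated(ids)) stop("clone ids must be unique")
  parents <- vapply(clones, `[[`, character(1), "parent")
  known <- !is.na(parents)
  if (any(known & !(parents %in% ids)))
    stop("clone parents must reference existing clone ids")
  if (sum(!known) < 1)
    stop("clone graph must have a root (a clone with no parent)")
  if (length(clones) < 2)
    warning("fewer than 2 clones: downstream two-class analyses need >= 2")
  set.seed(cfg$seed)
  reads <- list()
  labels <- list()
  for (cl in clones) {
    g <- simulate_cell_genome(ref, cl)
    for (i in seq_len(cfg$n_cells_per_clone)) {
      cell_id <- sprintf("%s_cell%02d", cl$clone_id, i)
      reads[[cell_id]] <- simulate_reads(g, cfg)
      labels[[cell_id]] <- cl$clone_id
    }
  }
  labels <- tibble::tibble(cell_id = names(labels),
                           clone_id = unlist(labels, use.names = FALSE))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(names(reads), function(id) {
      p <- file.path(out_dir, paste0(id, ".fastq"))
      tryCatch(write_fastq(reads[[id]], p),
               error = function(e) stop("failed writing ", p, ": ",
                                        conditionMessage(e)))
      p
    }, character(1))
    utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- tibble::tibble(cell_id = names(paths),
                            path = unname(paths))
  }
  list(reads = reads, labels = labels, files = files)
}

#' Two-clone benchmark dataset with segment-level copy-number divergence
#'
#' Convenience wrapper encoding the package's standard benchmark: a reference
#' of `ref_length` base pairs in `n_segments` segments and two clones that are
#' diploid everywhere except `n_diverged` segments, where clone B carries
#' `fold` times clone A's copy number. With the defaults (100 kb, 20 segments,
#' 5 diverged segments at 3-fold, 20 cells per clone) the clones are well
#' separated in k-mer space.
#'
#' @param ref_length,n_segments Reference geometry.
#' @param n_diverged Number of segments on which the clones differ.
#' @param fold Copy-number fold change on diverged segments.
#' @param cfg A [sim_config()]; its seed drives both reference and reads.
#' @param out_dir Optional output directory, as in [simulate_dataset()].
#' @return As [simulate_dataset()], plus `ref`, `clones`, and
#'   `diverged_segments` (integer vector of truth segments).
#' @export
simulate_two_clone_dataset <- function(ref_length = 1e5, n_segments = 20,
                                       n_diverged = 5, fold = 3,
                                       cfg = sim_config(), out_dir = NULL) {
  stopifnot(n_diverged >= 1, n_diverged <= n_segments, fold >= 1)
  ref <- make_reference(ref_length, n_segments, seed = cfg$seed)
  cn_a <- rep(2L, n_segments)
  cn_b <- cn_a
  diverged <- seq_len(n_diverged) # first segments, deterministic truth set
  cn_b[diverged] <- as.integer(round(fold * cn_a[diverged]))
  clones <- list(clone_profile("A", cn_a),
                 clone_profile("B", cn_b, parent = "A"))
  out <- simulate_dataset(ref, clones, cfg, out_dir = out_dir)
  out$ref <- ref
  out$clones <- clones
  out$diverged_segments <- diverged
  out
}
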