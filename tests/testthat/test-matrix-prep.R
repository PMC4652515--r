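test_that("sparse-occurrence filtering zeroes low counts and drops rows", {
  m <- as_kmer_matrix(matrix(c(1, 1, 5, 0, 2, 9), 3, byrow = TRUE,
                             dimnames = list(c("AAA", "ACC", "GGG"),
                                             c("s1", "s2"))))
  ident <- filter_sparse(m, min_count = 1)
  expect_equal(as.matrix(ident$matrix), as.matrix(m))
  expect_equal(ident$report$n_removed_sparse, 0)

  f <- filter_sparse(m, min_count = 2)
  expect_equal(rownames(f$matrix$values), c("ACC", "GGG"))
  expect_equal(as.matrix(f$matrix)["ACC", ], c(s1 = 5, s2 = 0))
  expect_equal(f$report$n_removed_sparse, 1)
  expect_equal(f$report$n_retained, 2)
})

test_that("sparse filter agrees with an independent brute-force scan", {
  dm <- random_count_matrix(1000, 6, seed = 31)
  m <- as_kmer_matrix(dm, k = 8)
  for (mc in c(2, 4)) {
    f <- filter_sparse(m, mc)
    # oracle: apply the rule entry-wise on the dense matrix
    dm2 <- dm
    dm2[dm2 < mc] <- 0
    keep <- rowSums(dm2) > 0
    expect_equal(as.matrix(f$matrix), dm2[keep, , drop = FALSE])
    expect_equal(f$report$n_removed_sparse, sum(!keep))
  }
})

test_that("presence filter retains exactly the everywhere-positive rows", {
  m <- as_kmer_matrix(matrix(c(3, 0, 2, 1, 1, 1, 4, 5, 6), 3, byrow = TRUE,
                             dimnames = list(c("AAA", "ACC", "GGG"),
                                             paste0("s", 1:3))))
  f <- filter_ubiquitous(m)
  expect_setequal(rownames(f$matrix$values), c("ACC", "GGG"))
  expect_equal(f$report$n_removed_not_ubiquitous, 1)

  # idempotence and all-positive identity
  f2 <- filter_ubiquitous(f$matrix)
  expect_equal(as.matrix(f2$matrix), as.matrix(f$matrix))
  expect_equal(f2$report$n_removed_not_ubiquitous, 0)

  # relaxed presence fraction
  relax <- filter_ubiquitous(m, presence_fraction = 2 / 3)
  expect_setequal(rownames(relax$matrix$values), c("AAA", "ACC", "GGG"))

  empty <- as_kmer_matrix(matrix(c(1, 0, 0, 1), 2,
                                 dimnames = list(c("AA", "CC"),
                                                 c("s1", "s2"))), k = 2)
  expect_warning(filter_ubiquitous(empty), "no k-mer")
})

test_that("clone-private k-mers are removed exactly when truly private", {
  # clone B lacks segment 1 entirely: its k-mers cannot occur in B cells
  ref <- make_reference(4000, 4, seed = 71)
  clones <- list(clone_profile("A", c(1, 1, 1, 1)),
                 clone_profile("B", c(0, 1, 1, 1)))
  cfg <- sim_config(n_cells_per_clone = 3, coverage = 12, error_rate = 0,
                    wga_sigma = 0, revcomp_prob = 0, seed = 5)
  sim <- simulate_dataset(ref, clones, cfg)
  spectra <- Map(function(r, id) count_kmers(r, 9, id),
                 sim$reads, names(sim$reads))
  m <- merge_spectra(unname(spectra))
  f <- filter_ubiquitous(m)
  seg1 <- substring(ref$sequence, ref$segments$start[1],
                    ref$segments$end[1])
  seg1_kmers <- names(count_kmers(seg1, 9)$counts)
  shared_kmers <- unlist(lapply(2:4, function(s) {
    names(count_kmers(substring(ref$sequence, ref$segments$start[s],
                                ref$segments$end[s]), 9)$counts)
  }))
  private <- setdiff(seg1_kmers, shared_kmers)
  expect_length(intersect(rownames(f$matrix$values), private), 0)
})

test_that("duplicate columns are detected pairwise and dropped", {
  dm <- matrix(c(1, 2, 1, 2, 3, 4), 2,
               dimnames = list(c("AA", "CC"), c("s1", "s2", "s3")))
  m <- as_kmer_matrix(dm, k = 2)
  dup <- detect_duplicates(m)
  expect_equal(dup, tibble::tibble(sample1 = "s1", sample2 = "s2"))

  distinct <- as_kmer_matrix(matrix(1:6, 2,
                                    dimnames = list(c("AA", "CC"),
                                                    paste0("s", 1:3))),
                             k = 2)
  expect_equal(nrow(detect_duplicates(distinct)), 0)

  # 3 identical columns: all 3 unordered pairs; 2 columns dropped
  tri <- as_kmer_matrix(matrix(c(1, 2, 1, 2, 1, 2, 9, 9), 2,
                               dimnames = list(c("AA", "CC"),
                                               c("s1", "s2", "s3", "s4"))),
                        k = 2)
  pairs <- detect_duplicates(tri)
  expect_equal(nrow(pairs), 3)
  expect_setequal(paste(pairs$sample1, pairs$sample2),
                  c("s1 s2", "s1 s3", "s2 s3"))
  dropped <- drop_duplicates(tri)
  expect_setequal(colnames(dropped$matrix$values), c("s1", "s4"))
  expect_setequal(dropped$removed, c("s2", "s3"))
})

test_that("TSS normalization is compositional, scale-free, idempotent", {
  m <- as_kmer_matrix(matrix(c(2, 3, 5, 1, 1, 2), 3,
                             dimnames = list(c("AA", "CC", "GG"),
                                             c("s1", "s2"))), k = 2)
  a <- tss_normalize(m)
  expect_equal(as.matrix(a)[, "s1"], c(AA = .2, CC = .3, GG = .5))
  expect_equal(unname(Matrix::colSums(a$values)), c(1, 1))

  scaled <- as_kmer_matrix(matrix(c(14, 21, 35, 1, 1, 2), 3,
                                  dimnames = dimnames(as.matrix(m))), k = 2)
  expect_equal(as.matrix(tss_normalize(scaled))[, "s1"],
               as.matrix(a)[, "s1"])
  # idempotence up to float tolerance
  expect_equal(as.matrix(tss_normalize(a)), as.matrix(a),
               tolerance = 1e-12)

  zero <- as_kmer_matrix(matrix(c(1, 1, 0, 0), 2,
                                dimnames = list(c("AA", "CC"),
                                                c("ok", "empty"))), k = 2)
  expect_error(tss_normalize(zero), "empty")
})

test_that("uniform columns normalize to 1/n", {
  m <- as_kmer_matrix(matrix(7, 5, 1,
                             dimnames = list(paste0("K", 1:5), "s1")), k = 3)
  expect_equal(unname(as.matrix(tss_normalize(m))[, 1]), rep(0.2, 5))
})

test_that("pipeline report bookkeeping reconciles exactly", {
  sim <- small_two_clone()
  rep <- sim$prep$report
  expect_equal(rep$n_input_kmers,
               rep$n_removed_sparse + rep$n_removed_not_ubiquitous +
                 rep$n_retained)
  expect_equal(nrow(sim$prep$abundance$values), rep$n_retained)
  expect_equal(unname(Matrix::colSums(sim$prep$abundance$values)),
               rep(1, ncol(sim$prep$abundance$values)), tolerance = 1e-9)
})
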