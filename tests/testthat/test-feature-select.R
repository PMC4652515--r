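make_abundance <- function(dm, k = 4) {
  as_kmer_matrix(sweep(dm, 2, colSums(dm), "/"), k = k, normalized = TRUE)
}

test_that("IQR filter removes the first-quartile IQR rows inclusively", {
  # rows engineered so row IQRs across 5 samples are 0.1, 0.2, 0.3, 0.4
  base <- rbind(c(0, .05, .1, .15, .1),
                c(0, .1, .2, .3, .2),
                c(0, .15, .3, .45, .3),
                c(0, .2, .4, .6, .4))
  dimnames(base) <- list(paste0("K", 1:4), paste0("s", 1:5))
  iqrs <- apply(base, 1, function(r) diff(quantile(r, c(.25, .75),
                                                   names = FALSE)))
  a <- kmerphylo:::new_kmer_matrix(Matrix::Matrix(base, sparse = TRUE),
                                   4, normalized = TRUE)
  f <- iqr_filter(a)
  # oracle: quantile convention applied by hand
  q1 <- quantile(iqrs, 0.25, names = FALSE)
  expect_setequal(rownames(f$matrix$values),
                  names(iqrs)[iqrs > q1])
  expect_false("K1" %in% rownames(f$matrix$values))
  expect_equal(f$selection$n_before, 4)
})

test_that("constant rows are removed before varying rows", {
  set.seed(5)
  dm <- rbind(matrix(0.1, 3, 6), matrix(runif(30, 0, 1), 5, 6))
  dimnames(dm) <- list(paste0("K", 1:8), paste0("s", 1:6))
  a <- make_abundance(dm)
  f <- iqr_filter(a)
  expect_false(any(paste0("K", 1:3) %in% rownames(f$matrix$values)))
})

test_that("removal fraction approaches 25% when IQRs are distinct", {
  set.seed(6)
  dm <- matrix(runif(10000 * 8), 10000,
               dimnames = list(paste0("K", 1:10000), paste0("s", 1:8)))
  a <- make_abundance(dm)
  f <- iqr_filter(a)
  frac <- 1 - f$selection$n_after / f$selection$n_before
  expect_gte(frac, 0.24)
  expect_lte(frac, 0.26)
})

test_that("fully tied IQRs warn and remove nothing", {
  # every row identical => every IQR identical
  dm <- matrix(rep(c(.1, .2, .3, .4), each = 4), 4,
               dimnames = list(paste0("K", 1:4), paste0("s", 1:4)))
  a <- kmerphylo:::new_kmer_matrix(Matrix::Matrix(dm, sparse = TRUE),
                                   4, normalized = TRUE)
  expect_warning(f <- iqr_filter(a), "tied")
  expect_equal(f$selection$n_after, 4)
})

test_that("rank-sum p-values match the exact enumeration oracle", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)
  # identical multisets give p = 1 (rank sums sit exactly at the null mean)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2)), 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 3), rep(2, 4)), 1)

  set.seed(9)
  for (n1 in 1:4) {
    for (n2 in n1:4) {
      x <- rnorm(n1)
      y <- rnorm(n2)
      expect_equal(wilcoxon_rank_sum(x, y), enumerate_wilcoxon_p(x, y),
                   tolerance = 1e-12,
                   label = sprintf("sizes %d+%d", n1, n2))
    }
  }
})

test_that("vectorized row-wise p-values match wilcox.test (dual route)", {
  set.seed(10)
  v <- matrix(rnorm(50 * 12), 50)
  v[1:10, ] <- round(v[1:10, ]) # inject ties
  grp1 <- rep(c(TRUE, FALSE), each = 6)
  mine <- kmerphylo:::row_wilcoxon_p(v, grp1)
  ref <- apply(v, 1, function(row) {
    suppressWarnings(wilcox.test(row[grp1], row[!grp1])$p.value)
  })
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)

  # forced approximation path matches too
  mine_approx <- kmerphylo:::row_wilcoxon_p(v, grp1, exact = FALSE)
  ref_approx <- apply(v, 1, function(row) {
    wilcox.test(row[grp1], row[!grp1], exact = FALSE,
                correct = TRUE)$p.value
  })
  expect_equal(unname(mine_approx), unname(ref_approx), tolerance = 1e-10)
})

test_that("Bonferroni threshold, monotonicity, and bookkeeping hold", {
  set.seed(11)
  dm <- matrix(runif(200 * 12, 1, 2), 200,
               dimnames = list(paste0("K", 1:200), paste0("s", 1:12)))
  a <- make_abundance(dm)
  labels <- tibble::tibble(sample_id = paste0("s", 1:12),
                           class = rep(c("p", "m"), each = 6))
  sel <- select_differential(a, labels, alpha = 0.001)
  expect_equal(sel$selection$threshold, 0.001 / 200)
  expect_equal(sel$selection$n_before, 200)
  expect_equal(sel$selection$n_after, nrow(sel$matrix$values))

  # shrinking alpha never grows the kept set
  kept_small <- select_differential(a, labels,
                                    alpha = 1e-5)$selection$scores$keep
  kept_large <- select_differential(a, labels,
                                    alpha = 0.05)$selection$scores$keep
  expect_true(all(kept_large | !kept_small))

  # invariance to sample order and class renaming
  perm <- sample(ncol(a$values))
  a2 <- kmerphylo:::new_kmer_matrix(a$values[, perm], a$k,
                                    normalized = TRUE)
  labels2 <- labels[perm, ]
  labels2$class <- c(p = "X", m = "Y")[labels2$class]
  sel2 <- select_differential(a2, labels2, alpha = 0.001)
  expect_equal(sel2$selection$scores$p_value, sel$selection$scores$p_value)

  expect_error(select_differential(a, tibble::tibble(
    sample_id = paste0("s", 1:12), class = rep(c("a", "b", "c"), 4))),
    "2 classes")
})

test_that("null data keeps roughly nothing; shifted features are found", {
  # pure-null replicates: kept fraction stays at/below alpha on average
  set.seed(12)
  kept_frac <- replicate(20, {
    dm <- matrix(runif(100 * 10, 1, 2), 100,
                 dimnames = list(paste0("K", 1:100), paste0("s", 1:10)))
    a <- make_abundance(dm)
    labels <- tibble::tibble(sample_id = paste0("s", 1:10),
                             class = sample(rep(c("p", "m"), each = 5)))
    sel <- select_differential(a, labels, alpha = 0.05)
    sel$selection$n_after / sel$selection$n_before
  })
  expect_lte(mean(kept_frac), 0.05 + 3 * sd(kept_frac) / sqrt(20) + 1e-9)

  # 10% truly differential rows with a >= 3 IQR shift: most recovered
  set.seed(13)
  n_true <- 50
  dm <- matrix(runif(500 * 30, 1, 2), 500,
               dimnames = list(paste0("K", 1:500), paste0("s", 1:30)))
  shift <- 3 * 0.5 # base IQR of U(1,2) is 0.5
  dm[seq_len(n_true), 16:30] <- dm[seq_len(n_true), 16:30] + shift
  a <- make_abundance(dm)
  labels <- tibble::tibble(sample_id = paste0("s", 1:30),
                           class = rep(c("p", "m"), each = 15))
  sel <- select_differential(a, labels, alpha = 0.001)
  recovered <- mean(sel$selection$scores$keep[seq_len(n_true)])
  expect_gte(recovered, 0.8)
  false_pos <- sum(sel$selection$scores$keep[-seq_len(n_true)])
  expect_lte(false_pos, 2)
})
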