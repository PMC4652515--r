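# Dimensionality reduction and informative-feature selection.
#
# Two stages: (1) unsupervised interquartile-range filtering removes the
# quarter of k-mers whose abundance varies least across samples; (2) a
# Wilcoxon rank-sum test per k-mer against a two-class label vector, with
# Bonferroni control of the family-wise error, keeps the differentially
# abundant features.

check_labels <- function(labels, samples) {
  stopifnot(is.data.frame(labels))
  if (!all(c("sample_id", "class") %in% names(labels))) {
    if (all(c("cell_id", "clone_id") %in% names(labels)))
      labels <- tibble::tibble(sample_id = labels$cell_id,
                               class = labels$clone_id)
    else
      stop("labels need columns sample_id/class (or cell_id/clone_id)")
  }
  labels <- tibble::as_tibble(labels[c("sample_id", "class")])
  if (!setequal(labels$sample_id, samples))
    stop("labels must cover exactly the matrix's samples")
  labels[match(samples, labels$sample_id), ]
}

new_selection_result <- function(scores, n_before, n_after, threshold = NA) {
  structure(list(scores = scores, n_before = n_before, n_after = n_after,
                 threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$n_before, " -> ", x$n_after, " k-mers",
      if (!is.na(x$threshold))
        paste0(" (per-test threshold ", format(x$threshold), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$scores

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_before = x$n_before, n_after = x$n_after,
                 threshold = x$threshold,
                 fraction_kept = x$n_after / x$n_before)
}

row_iqr <- function(v) {
  q <- apply(v, 1, quantile, probs = c(0.25, 0.75), names = FALSE,
             type = 7)
  q[2, ] - q[1, ]
}

#' Remove low-variability k-mers by interquartile range
#'
#' Computes each k-mer's IQR of relative abundance across samples (linear
#' interpolation between order statistics, the `quantile()` type-7 default)
#' and removes the k-mers whose IQR falls at or below the first quartile of
#' all IQR values — about 25% of features when IQRs are distinct. If every
#' IQR is identical nothing is removed (with a warning), since no feature is
#' less variable than another.
#'
#' @param a A `kmer_abundance`.
#' @return List with `matrix` (filtered abundance) and `selection`
#'   (`selection_result` whose `scores` tibble holds per-k-mer IQRs and the
#'   keep flag).
#' @export
iqr_filter <- function(a) {
  stopifnot(inherits(a, "kmer_abundance"), nrow(a$values) >= 4)
  v <- as.matrix(a$values)
  iqr <- row_iqr(v)
  q1 <- quantile(iqr, 0.25, names = FALSE, type = 7)
  keep <- iqr > q1
  if (!any(!keep) || !any(keep)) {
    warning("all k-mer IQRs are tied; nothing removed")
    keep <- rep(TRUE, length(iqr))
  }
  scores <- tibble::tibble(kmer = rownames(v), iqr = iqr, keep = keep)
  list(matrix = new_kmer_matrix(a$values[keep, , drop = FALSE], a$k,
                                normalized = TRUE),
       selection = new_selection_result(scores, nrow(v), sum(keep),
                                        threshold = q1))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The exact null
#' distribution is used when the pooled size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric vectors of abundances for the two groups.
#' @return The two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4)) # exact: 1/3
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

# Vectorized row-wise rank-sum p-values over a features x samples matrix.
# Rows without ties use the exact null distribution (shared pwilcox CDF)
# whenever both group sizes are below 50; tied rows (or larger groups) use
# the normal approximation with tie and continuity correction. Matches
# wilcox.test row by row (dual-route checked in the test suite).
row_wilcoxon_p <- function(v, grp1, exact = NULL) {
  n1 <- sum(grp1)
  n2 <- ncol(v) - n1
  rk <- t(apply(v, 1, rank))
  W <- rowSums(rk[, grp1, drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- apply(v, 1, function(row) {
    d <- rle(sort(row))$lengths
    sum(d^3 - d)
  })
  has_ties <- tie_term > 0
  use_exact <- if (is.null(exact)) (n1 < 50 && n2 < 50) else isTRUE(exact)
  p <- numeric(nrow(v))
  exact_rows <- use_exact & !has_ties
  if (any(exact_rows)) {
    cdf <- stats::pwilcox(0:(n1 * n2), n1, n2) # cdf[w + 1] = P(W <= w)
    cdf0 <- c(0, cdf)
    We <- W[exact_rows]
    lower <- cdf[We + 1]
    upper <- 1 - cdf0[We + 1] # P(W >= We)
    p[exact_rows] <- pmin(1, 2 * pmin(lower, upper))
  }
  if (any(!exact_rows)) {
    idx <- !exact_rows
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - tie_term[idx] / ((n1 + n2) * (n1 + n2 - 1)))
    z <- W[idx] - mu
    z <- z - sign(z) * 0.5 # continuity correction
    pv <- 2 * stats::pnorm(-abs(z) / sqrt(pmax(sigma2, .Machine$double.eps)))
    pv[sigma2 <= 0] <- 1
    p[idx] <- pmin(1, pv)
  }
  p
}

#' Select differentially abundant k-mers between two classes
#'
#' Tests every k-mer with the Wilcoxon rank-sum test between the two classes
#' and keeps those with raw p-value at most `alpha / m` (Bonferroni), where
#' `m` is the number of k-mers tested.
#'
#' @param a A `kmer_abundance` (normally the [iqr_filter()] output).
#' @param labels Tibble mapping samples to exactly two class labels (columns
#'   `sample_id`/`class`, or `cell_id`/`clone_id` as produced by the
#'   simulator).
#' @param alpha Family-wise significance level (default 0.001).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact null
#'   distribution; `NULL` (default) uses it for every k-mer without ties when
#'   both classes have fewer than 50 samples (the [stats::wilcox.test()]
#'   switch), falling back to the tie-corrected normal approximation
#'   otherwise. The exact tail matters here: at 20 + 20 samples the
#'   approximation cannot reach Bonferroni-corrected thresholds that the
#'   exact distribution can.
#' @param adjust `"bonferroni"` (default: keep raw p <= alpha / m) or
#'   `"bh"`, a Benjamini-Hochberg convenience alternative keeping k-mers
#'   with FDR-adjusted p <= alpha.
#' @return List with `matrix` (abundance restricted to kept k-mers) and
#'   `selection` (`selection_result` with per-k-mer p-values).
#' @export
select_differential <- function(a, labels, alpha = 0.001, exact = NULL,
                                adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(a, "kmer_abundance"), alpha > 0, alpha < 1)
  labels <- check_labels(labels, colnames(a$values))
  classes <- unique(labels$class)
  if (length(classes) != 2)
    stop("differential selection needs exactly 2 classes, got ",
         length(classes))
  sizes <- table(labels$class)
  if (any(sizes < 2))
    warning("class(es) with fewer than 2 samples: test power is degenerate")
  v <- as.matrix(a$values)
  grp1 <- labels$class == classes[1]
  m <- nrow(v)
  p <- row_wilcoxon_p(v, grp1, exact = exact)
  if (adjust == "bonferroni") {
    threshold <- alpha / m
    keep <- p <= threshold
  } else {
    threshold <- alpha
    keep <- stats::p.adjust(p, "BH") <= alpha
  }
  scores <- tibble::tibble(kmer = rownames(v), p_value = unname(p),
                           keep = unname(keep))
  list(matrix = new_kmer_matrix(a$values[keep, , drop = FALSE], a$k,
                                normalized = TRUE),
       selection = new_selection_result(scores, m, sum(keep),
                                        threshold = threshold))
}
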