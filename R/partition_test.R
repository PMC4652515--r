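# Class-separation statistic on a distance matrix and its permutation test.
#
# The statistic is the ratio of the mean pairwise distance within classes to
# the mean pairwise distance between classes, pooled over all classes; values
# below 1 mean cells of the same class sit closer together than cells of
# different classes. Significance comes from shuffling the label vector:
# under the null that labels are unrelated to the distance geometry the
# statistic concentrates around 1.

#' Within/between class-separation statistic
#'
#' `mean(d over same-class pairs) / mean(d over different-class pairs)`,
#' pooled across all classes (two or more). The `"sums"` variant divides the
#' raw pair sums instead of the means; with unequal class sizes its null
#' center moves away from 1, so means are the default.
#'
#' @param d A `dist`/`kmer_dist` or symmetric matrix.
#' @param labels Tibble with columns `sample_id`/`class` (or
#'   `cell_id`/`clone_id`), covering exactly the matrix's samples, or a bare
#'   vector of classes in matrix order.
#' @param method `"means"` (default) or `"sums"`.
#' @return The statistic (a single number; smaller means stronger class
#'   cohesion).
#' @export
separation_statistic <- function(d, labels, method = c("means", "sums")) {
  method <- match.arg(method)
  m <- as.matrix(d)
  cls <- labels_vector(labels, rownames(m), nrow(m))
  sep_stat_impl(m, cls, method)
}

labels_vector <- function(labels, sample_names, n) {
  if (is.data.frame(labels)) {
    if (is.null(sample_names))
      stop("distance matrix has no sample names to match labels against")
    lab <- check_labels(labels, sample_names)
    return(as.character(lab$class))
  }
  if (length(labels) != n)
    stop("labels must have one entry per sample")
  as.character(labels)
}

sep_stat_impl <- function(m, cls, method = "means") {
  if (length(unique(cls)) < 2)
    stop("need at least 2 classes")
  same <- outer(cls, cls, "==")
  ut <- upper.tri(m)
  w_sum <- sum(m[ut & same])
  b_sum <- sum(m[ut & !same])
  n_w <- sum(ut & same)
  n_b <- sum(ut & !same)
  if (n_w == 0) stop("no within-class pair (all classes are singletons)")
  if (n_b == 0) stop("no between-class pair")
  if (method == "sums") {
    if (b_sum == 0) stop("between-class distance sum is zero")
    return(w_sum / b_sum)
  }
  b_mean <- b_sum / n_b
  if (b_mean == 0) stop("between-class mean distance is zero")
  (w_sum / n_w) / b_mean
}

# fast path used by the permutation loop: per-class block sums
sep_stat_fast <- function(m, cls, total_sum, method) {
  w_sum <- 0
  n_w <- 0
  for (g in split(seq_along(cls), cls)) {
    k <- length(g)
    if (k < 2) next
    w_sum <- w_sum + sum(m[g, g]) / 2
    n_w <- n_w + k * (k - 1) / 2
  }
  n <- length(cls)
  n_all <- n * (n - 1) / 2
  b_sum <- total_sum - w_sum
  n_b <- n_all - n_w
  if (method == "sums") w_sum / b_sum
  else (w_sum / n_w) / (b_sum / n_b)
}

#' Permutation test of class separation
#'
#' Shuffles the label vector uniformly `n_permutations` times, recomputing
#' the separation statistic each time, and reports the one-sided empirical
#' p-value `p = (1 + #[null <= observed]) / (1 + n_permutations)` (small
#' statistic = classes more clustered than random). The add-one convention
#' means p can never be 0; its floor at 10,000 permutations is about 1e-4.
#'
#' @inheritParams separation_statistic
#' @param n_permutations Number of label shuffles (default 10000).
#' @param seed Integer seed for the shuffles.
#' @return A `partition_test` object: `observed_statistic`, `null_mean`,
#'   `null_sd`, `n_permutations`, `p_value`, `seed`, and the vector of null
#'   draws (`null_values`).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20)
#' d <- dist(x)
#' r <- permutation_test(d, rep(c("a", "b"), each = 10),
#'                       n_permutations = 200, seed = 1)
#' r$p_value
#' @export
permutation_test <- function(d, labels, n_permutations = 10000, seed = 1L,
                             method = c("means", "sums")) {
  method <- match.arg(method)
  stopifnot(n_permutations >= 1)
  m <- as.matrix(d)
  cls <- labels_vector(labels, rownames(m), nrow(m))
  observed <- sep_stat_impl(m, cls, method)
  total_sum <- sum(m[upper.tri(m)])
  set.seed(seed)
  null_values <- vapply(seq_len(n_permutations), function(i) {
    sep_stat_fast(m, sample(cls), total_sum, method)
  }, numeric(1))
  p <- (1 + sum(null_values <= observed)) / (1 + n_permutations)
  structure(list(observed_statistic = observed,
                 null_mean = mean(null_values),
                 null_sd = sd(null_values),
                 n_permutations = as.integer(n_permutations),
                 p_value = p, seed = as.integer(seed),
                 method = method, null_values = null_values),
            class = "partition_test")
}

#' @export
print.partition_test <- function(x, ...) {
  cat("<partition_test>\n",
      "  observed statistic: ", format(x$observed_statistic, digits = 4),
      "\n  null mean (sd):     ", format(x$null_mean, digits = 4), " (",
      format(x$null_sd, digits = 4), ")\n",
      "  permutations:       ", x$n_permutations, "\n",
      "  p-value:            ", format(x$p_value, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.partition_test <- function(x, ...) {
  tibble::tibble(observed_statistic = x$observed_statistic,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 n_permutations = x$n_permutations, p_value = x$p_value)
}

#' @export
glance.partition_test <- function(x, ...) tidy.partition_test(x)

#' @export
autoplot.partition_test <- function(object, ...) {
  df <- data.frame(statistic = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_statistic,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "separation statistic (permutation null)",
                  y = "count",
                  title = sprintf("observed = %.4f, p = %.4g",
                                  object$observed_statistic,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
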