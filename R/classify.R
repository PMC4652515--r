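# Cross-validated classification of cells from selected k-mer features.
#
# The learners are off-the-shelf — a linear-kernel maximum-margin classifier
# (e1071::svm) and a CART decision tree (rpart) — the harness here supplies
# stratified repeated k-fold assignment, class balancing by subsampling, and
# the replicate-level error report.

#' Repeated stratified k-fold cross-validated classification
#'
#' Samples (matrix columns) are split into `n_folds` stratified folds,
#' `n_replicates` times with fresh fold assignments; each fold is held out in
#' turn, the classifier is fit on the rest, and the fold's misclassification
#' rate recorded. A replicate's error is the mean over its folds; the report
#' summarizes the `n_replicates` errors.
#'
#' @param a A `kmer_abundance` (or features x samples matrix), normally the
#'   differential-abundance-selected matrix.
#' @param labels Tibble with `sample_id`/`class` (or `cell_id`/`clone_id`)
#'   columns, or a class vector in column order.
#' @param classifier `"svm"` (linear kernel) or `"tree"` (CART).
#' @param n_folds Folds per replicate (default 10); every class must have at
#'   least `n_folds` members.
#' @param n_replicates Cross-validation replicates (default 10).
#' @param seed Integer seed; fold assignment is reproducible bit for bit.
#' @return A `cv_report`: `classifier`, `n_folds`, `n_replicates`, `errors`
#'   (per-replicate mean misclassification rates), and `summary` (tibble with
#'   min/median/mean/max/sd).
#' @export
crossval_classify <- function(a, labels, classifier = c("svm", "tree"),
                              n_folds = 10, n_replicates = 10, seed = 1L) {
  classifier <- match.arg(classifier)
  v <- abundance_matrix_input(a)
  if (nrow(v) < 1) stop("feature matrix has no rows (empty selection?)")
  cls <- factor(labels_vector(labels, colnames(v), ncol(v)))
  sizes <- table(cls)
  if (any(sizes < n_folds))
    stop("class(es) smaller than n_folds (",
         paste(names(sizes)[sizes < n_folds], collapse = ", "),
         "): lower `n_folds`")
  x <- t(v)
  colnames(x) <- paste0("f", seq_len(ncol(x))) # syntactic feature names
  df <- data.frame(x, check.names = FALSE)
  df$.class <- cls
  set.seed(seed)
  errors <- vapply(seq_len(n_replicates), function(rep) {
    folds <- stratified_folds(cls, n_folds)
    fold_err <- vapply(seq_len(n_folds), function(f) {
      test <- folds == f
      fit <- fit_classifier(df[!test, , drop = FALSE], classifier)
      pred <- predict_classifier(fit, df[test, , drop = FALSE], classifier)
      mean(pred != cls[test])
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  structure(list(classifier = classifier, n_folds = as.integer(n_folds),
                 n_replicates = as.integer(n_replicates), errors = errors,
                 summary = tibble::tibble(min = min(errors),
                                          median = median(errors),
                                          mean = mean(errors),
                                          max = max(errors),
                                          sd = sd(errors))),
            class = "cv_report")
}

stratified_folds <- function(cls, n_folds) {
  folds <- integer(length(cls))
  for (g in split(seq_along(cls), cls)) {
    g <- sample(g)
    folds[g] <- rep_len(sample.int(n_folds), length(g))
  }
  folds
}

fit_classifier <- function(train, classifier) {
  if (classifier == "svm")
    e1071::svm(.class ~ ., data = train, kernel = "linear")
  else
    rpart::rpart(.class ~ ., data = train, method = "class")
}

predict_classifier <- function(fit, test, classifier) {
  if (classifier == "svm") predict(fit, test)
  else predict(fit, test, type = "class")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$classifier, ", ", x$n_replicates, " x ", x$n_folds,
      "-fold CV\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$errors), error = x$errors)
}

#' @export
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(classifier = x$classifier,
                                  n_folds = x$n_folds,
                                  n_replicates = x$n_replicates),
                   x$summary)
}

#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidy.cv_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$error)) +
    ggplot2::geom_boxplot(width = 0.3, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.05, colour = "steelblue") +
    ggplot2::labs(x = object$classifier, y = "misclassification rate",
                  title = sprintf("%d x %d-fold cross-validation",
                                  object$n_replicates, object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Balance two classes by subsampling the majority class
#'
#' Uniformly downsamples the larger class, without replacement, to the size
#' of the smaller one, so accuracy is not inflated by class imbalance.
#'
#' @inheritParams crossval_classify
#' @param seed Integer seed for the subsample.
#' @return List with `matrix` (columns restricted to the balanced sample
#'   set) and `labels` (tibble `sample_id`, `class`).
#' @export
balance_by_subsampling <- function(a, labels, seed = 1L) {
  v <- abundance_matrix_input(a)
  cls <- labels_vector(labels, colnames(v), ncol(v))
  tab <- table(cls)
  if (length(tab) != 2) stop("balancing expects exactly 2 classes")
  n_min <- min(tab)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(cls), cls), function(g) {
    if (length(g) > n_min) sort(sample(g, n_min)) else g
  }), use.names = FALSE)
  keep <- sort(keep)
  out <- if (inherits(a, "kmer_matrix"))
    new_kmer_matrix(a$values[, keep, drop = FALSE], a$k,
                    normalized = a$normalized)
  else v[, keep, drop = FALSE]
  list(matrix = out,
       labels = tibble::tibble(sample_id = colnames(v)[keep],
                               class = cls[keep]))
}
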