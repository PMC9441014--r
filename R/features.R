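#' Build a standardized connectivity feature set
#'
#' Turns per-session connectivity estimates into a samples x features matrix
#' for classification. FC and SC matrices are vectorised by their strictly
#' lower triangle (`n(n-1)/2` features, column-major order); EC models are
#' vectorised by the SC-masked entries of the directed EC matrix, in a fixed
#' column-major order. Each sample vector is then z-scored across features
#' (mean 0, SD 1 within each session).
#'
#' @param x a named list: of [mou_model] objects (EC) or of square numeric
#'   matrices (FC or SC).
#' @param mask an [sc_mask]; required for `metric_tag = "ec"`.
#' @param metric_tag one of `"ec"`, `"fc"`, `"sc"`.
#' @param labels class label per sample (character or factor).
#' @param subject_ids optional subject identifier per sample.
#' @return an object of class `feature_set` with fields `matrix`, `labels`,
#'   `metric_tag`, `feature_index` (data frame mapping feature position to a
#'   region pair; directed for EC), `subject_ids`.
#' @export
build_features <- function(x, mask = NULL, metric_tag = c("ec", "fc", "sc"),
                           labels, subject_ids = names(x)) {
  metric_tag <- match.arg(metric_tag)
  stopifnot(length(x) >= 1L, length(labels) == length(x))
  if (metric_tag == "ec") {
    if (is.null(mask)) stop_invalid("EC features require the SC mask")
    mats <- lapply(x, function(m) {
      if (!inherits(m, "mou_model")) stop_invalid("EC inputs must be mou_model objects")
      if (!identical(dim(m$ec), dim(mask$mask))) stop_invalid("model size does not match mask")
      m$ec
    })
    cells <- which(mask$mask == 1)
    n <- nrow(mask$mask)
    feature_index <- data.frame(
      feature = seq_along(cells),
      source = (cells - 1L) %% n + 1L,
      target = (cells - 1L) %/% n + 1L)
    vecs <- vapply(mats, function(m) m[cells], numeric(length(cells)))
  } else {
    mats <- lapply(x, as.matrix)
    n <- nrow(mats[[1L]])
    if (!all(vapply(mats, function(m) all(dim(m) == n), logical(1)))) {
      stop_invalid("all matrices must be square and of equal size")
    }
    lt <- which(lower.tri(mats[[1L]]))
    feature_index <- data.frame(
      feature = seq_along(lt),
      source = (lt - 1L) %% n + 1L,   # row (the larger index of the pair)
      target = (lt - 1L) %/% n + 1L)  # column
    vecs <- vapply(mats, function(m) m[lt], numeric(length(lt)))
  }
  fmat <- t(vecs)   # samples x features
  sds <- apply(fmat, 1L, sd)
  if (any(sds == 0)) {
    stop_invalid("constant feature vector (SD 0) for sample(s): ",
                 paste(names(x)[sds == 0], collapse = ", "))
  }
  fmat <- t(scale(t(fmat)))  # z-score within each sample
  dimnames(fmat) <- list(names(x), NULL)
  structure(list(matrix = fmat, labels = as.character(labels),
                 metric_tag = metric_tag, feature_index = feature_index,
                 subject_ids = subject_ids),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d samples x %d features, classes: %s\n",
              x$metric_tag, nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

# Subset a feature set by sample index and/or feature index.
subset_features <- function(fs, samples = NULL, features = NULL) {
  out <- fs
  if (!is.null(samples)) {
    out$matrix <- out$matrix[samples, , drop = FALSE]
    out$labels <- out$labels[samples]
    out$subject_ids <- out$subject_ids[samples]
  }
  if (!is.null(features)) {
    out$matrix <- out$matrix[, features, drop = FALSE]
    out$feature_index <- out$feature_index[features, , drop = FALSE]
  }
  out
}

# Fit the requested classifier on train rows and predict test rows.
classify_once <- function(xtr, ytr, xte, classifier, cost = 1) {
  if (classifier == "1nn") {
    # nearest neighbour under distance 1 - Pearson r between feature vectors;
    # ties broken by lowest training-sample index
    r <- cor(t(xte), t(xtr))
    ytr[apply(r, 1L, which.max)]
  } else {
    fit <- e1071::svm(x = xtr, y = factor(ytr), kernel = "linear",
                      cost = cost, scale = FALSE)
    as.character(predict(fit, xte))
  }
}

#' Accuracy distribution of a classifier over repeated random splits
#'
#' For each of `n_splits` random train/test partitions (train fraction
#' `1 - test_fraction` of the samples), fits the classifier on the training
#' samples and records the accuracy on the held-out samples. The 1-nearest-
#' neighbour classifier assigns each test sample the label of the
#' most-correlated training sample (Pearson metric); the SVM is a linear-
#' kernel maximum-margin classifier with fixed regularisation `cost`. A split
#' whose training set lacks one of the classes is re-drawn.
#'
#' @param fs a [build_features()] result.
#' @param classifier_tag `"svm"` or `"1nn"`.
#' @param n_splits number of random splits (default 50).
#' @param test_fraction held-out fraction in (0, 1) (default 0.2).
#' @param seed integer seed; fixed seed gives identical accuracy lists.
#' @param cost SVM regularisation constant.
#' @param shuffle_labels if `TRUE`, labels are permuted uniformly at random
#'   (freshly for each split) before splitting — the surrogate/chance
#'   condition.
#' @param stratified if `TRUE`, the test set is drawn per class
#'   (proportionally), which removes the below-chance majority-class artifact
#'   of small unstratified splits; off by default (plain random splitting).
#' @param split_unit `"sample"` (default: sessions are split independently)
#'   or `"subject"` (all sessions of a subject stay on the same side of the
#'   split, preventing within-subject leakage in pre/post designs).
#' @return an object of class `accuracy_distribution`: list with `accuracies`
#'   (length `n_splits`), `classifier_tag`, `n_splits`, `surrogate`, `seed`.
#' @export
evaluate_classifier <- function(fs, classifier_tag = c("svm", "1nn"),
                                n_splits = 50L, test_fraction = 0.2,
                                seed = 1L, cost = 1,
                                shuffle_labels = FALSE, stratified = FALSE,
                                split_unit = c("sample", "subject")) {
  classifier_tag <- match.arg(classifier_tag)
  split_unit <- match.arg(split_unit)
  stopifnot(inherits(fs, "feature_set"))
  if (split_unit == "subject" &&
      (is.null(fs$subject_ids) || anyNA(fs$subject_ids))) {
    stop_invalid("subject-level splits require subject_ids on the feature set")
  }
  if (n_splits < 1L) stop_invalid("n_splits must be >= 1")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop_invalid("test_fraction must be in (0, 1)")
  }
  labels <- fs$labels
  if (length(unique(labels)) < 2L) {
    stop_invalid("need at least 2 classes to classify")
  }
  ns <- nrow(fs$matrix)
  n_test <- max(1L, round(test_fraction * ns))
  if (n_test >= ns) stop_invalid("test fraction leaves no training samples")
  acc <- with_seed(seed, {
    vapply(seq_len(n_splits), function(s) {
      y <- if (shuffle_labels) sample(labels) else labels
      for (try in 1:100) {
        test <- if (split_unit == "subject") {
          subj <- unique(fs$subject_ids)
          held <- sample(subj, max(1L, round(test_fraction * length(subj))))
          which(fs$subject_ids %in% held)
        } else if (stratified) {
          unlist(lapply(split(seq_len(ns), y), function(idx) {
            sample(idx, max(1L, round(test_fraction * length(idx))))
          }), use.names = FALSE)
        } else {
          sample(ns, n_test)
        }
        if (length(unique(y[-test])) >= 2L) break
        if (try == 100) stop_invalid("could not draw a training set containing both classes")
      }
      pred <- classify_once(fs$matrix[-test, , drop = FALSE], y[-test],
                            fs$matrix[test, , drop = FALSE],
                            classifier_tag, cost)
      mean(pred == y[test])
    }, numeric(1))
  })
  structure(list(accuracies = acc, classifier_tag = classifier_tag,
                 n_splits = as.integer(n_splits),
                 surrogate = isTRUE(shuffle_labels), seed = seed),
            class = "accuracy_distribution")
}

#' @rdname evaluate_classifier
#' @export
surrogate_distribution <- function(fs, classifier_tag = c("svm", "1nn"),
                                   n_splits = 50L, test_fraction = 0.2,
                                   seed = 1L, cost = 1, stratified = FALSE,
                                   split_unit = c("sample", "subject")) {
  evaluate_classifier(fs, classifier_tag, n_splits, test_fraction, seed,
                      cost, shuffle_labels = TRUE, stratified = stratified,
                      split_unit = split_unit)
}

#' @export
print.accuracy_distribution <- function(x, ...) {
  cat(sprintf("<accuracy_distribution> %s%s: mean %.3f over %d splits\n",
              x$classifier_tag, if (x$surrogate) " (surrogate)" else "",
              mean(x$accuracies), x$n_splits))
  invisible(x)
}

#' Compare two accuracy distributions (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum (Mann-Whitney) test on the two accuracy lists.
#'
#' @param a,b [accuracy_distribution] objects or bare numeric vectors.
#' @return list of class `comparison_result` with `statistic`, `p_value` and
#'   `direction` (`"a"`, `"b"` or `"tie"`, by mean accuracy).
#' @export
compare_distributions <- function(a, b) {
  xa <- if (inherits(a, "accuracy_distribution")) a$accuracies else as.numeric(a)
  xb <- if (inherits(b, "accuracy_distribution")) b$accuracies else as.numeric(b)
  if (length(xa) == 0L || length(xb) == 0L) stop_invalid("empty accuracy distribution")
  if (sd(c(xa, xb)) == 0) {
    # every value identical: no rank separation, trivially non-significant
    return(structure(list(statistic = length(xa) * length(xb) / 2,
                          p_value = 1, direction = "tie"),
                     class = "comparison_result"))
  }
  wt <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 direction = if (mean(xa) > mean(xb)) "a"
                             else if (mean(xa) < mean(xb)) "b" else "tie"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> W = %g, p = %.4g, larger: %s\n",
              x$statistic, x$p_value, x$direction))
  invisible(x)
}
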