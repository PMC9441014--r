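#' Rank features by SVM recursive feature elimination
#'
#' Repeatedly fits a linear SVM on the surviving features and removes those
#' with the smallest absolute hyperplane weight, until none remain. Rank 1 is
#' the last surviving feature. To keep large feature sets tractable, 5% of
#' the surviving features are removed per iteration while more than
#' `step_threshold` remain, then one at a time; the final ordering of the
#' top-ranked features is produced by the single-step phase.
#'
#' @param fs a [build_features()] result with exactly two classes.
#' @param step_threshold switch point between the 5%-per-iteration and
#'   one-per-iteration phases (default 200).
#' @param cost SVM regularisation constant.
#' @return integer vector of ranks, one per feature (a permutation of
#'   `1..n_features`).
#' @export
rfe_ranking <- function(fs, step_threshold = 200L, cost = 1) {
  stopifnot(inherits(fs, "feature_set"))
  y <- factor(fs$labels)
  if (nlevels(y) != 2L) stop_invalid("RFE requires exactly 2 classes")
  p <- ncol(fs$matrix)
  if (p < 2L) stop_invalid("RFE requires at least 2 features")
  remaining <- seq_len(p)
  ranks <- integer(p)
  next_rank <- p  # eliminated first = worst rank
  while (length(remaining) > 1L) {
    fit <- e1071::svm(x = fs$matrix[, remaining, drop = FALSE], y = y,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    k <- if (length(remaining) > step_threshold) {
      max(1L, floor(0.05 * length(remaining)))
    } else 1L
    # drop the k smallest |w|; ties resolved by feature position for
    # determinism
    ord <- order(abs(w), remaining)
    drop <- ord[seq_len(k)]
    # within a dropped batch, the weakest feature gets the worst rank
    for (d in drop) {
      ranks[remaining[d]] <- next_rank
      next_rank <- next_rank - 1L
    }
    remaining <- remaining[-drop]
  }
  ranks[remaining] <- next_rank
  ranks
}

#' Extract the discriminative support network by repeated SVM-RFE
#'
#' For each of `n_repetitions` random 80/20 splits, ranks the EC features by
#' [rfe_ranking()] on the training samples and traces held-out accuracy as
#' features are added in rank order. Prefix sizes up to `step_threshold` are
#' evaluated exhaustively and geometrically above it. The selected subset
#' size is the smallest prefix whose mean accuracy across repetitions is
#' maximal (no larger evaluated prefix exceeds it by more than `1e-6`). Edge
#' identities are resolved from the consensus ranking (mean rank across
#' repetitions, ties towards the lexicographically smaller source/target).
#'
#' @param fs an EC [build_features()] result (directed feature index).
#' @param n_repetitions number of split/RFE repetitions (default 10).
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @param cost SVM regularisation constant.
#' @param step_threshold see [rfe_ranking()]; also the densest part of the
#'   accuracy-vs-size trace.
#' @return an object of class `support_network`: `edges` (data frame rank /
#'   source / target), `node_set` (region indices touched), `size`,
#'   `accuracy_trace` (evaluated sizes with mean held-out accuracy),
#'   `mean_rank` (per feature), `feature_index`.
#' @export
select_support_network <- function(fs, n_repetitions = 10L,
                                   test_fraction = 0.2, seed = 1L, cost = 1,
                                   step_threshold = 200L) {
  stopifnot(inherits(fs, "feature_set"))
  if (!all(c("source", "target") %in% names(fs$feature_index))) {
    stop_invalid("feature set lacks a directed feature index")
  }
  p <- ncol(fs$matrix)
  ns <- nrow(fs$matrix)
  n_test <- max(1L, round(test_fraction * ns))
  sizes <- seq_len(min(p, step_threshold))
  if (p > step_threshold) {
    s <- step_threshold
    while (s < p) {
      s <- min(p, ceiling(s * 1.5))
      sizes <- c(sizes, s)
    }
  }
  acc <- matrix(NA_real_, n_repetitions, length(sizes))
  rank_mat <- matrix(NA_real_, n_repetitions, p)
  y <- fs$labels
  with_seed(derive_seed(seed, "rfe"), {
    for (rep in seq_len(n_repetitions)) {
      repeat {
        test <- sample(ns, n_test)
        if (length(unique(y[-test])) == 2L) break
      }
      train_fs <- subset_features(fs, samples = setdiff(seq_len(ns), test))
      rk <- rfe_ranking(train_fs, step_threshold, cost)
      rank_mat[rep, ] <- rk
      ord <- order(rk)
      for (si in seq_along(sizes)) {
        feats <- ord[seq_len(sizes[si])]
        pred <- classify_once(fs$matrix[-test, feats, drop = FALSE],
                              y[-test],
                              fs$matrix[test, feats, drop = FALSE],
                              "svm", cost)
        acc[rep, si] <- mean(pred == y[test])
      }
    }
  })
  mean_acc <- colMeans(acc)
  best <- max(mean_acc)
  size <- sizes[which(mean_acc >= best - 1e-6)[1L]]
  mean_rank <- colMeans(rank_mat)
  consensus <- order(mean_rank, fs$feature_index$source, fs$feature_index$target)
  sel <- consensus[seq_len(size)]
  edges <- data.frame(rank = seq_len(size),
                      source = fs$feature_index$source[sel],
                      target = fs$feature_index$target[sel])
  structure(list(edges = edges,
                 node_set = sort(unique(c(edges$source, edges$target))),
                 size = size,
                 accuracy_trace = data.frame(size = sizes, mean_accuracy = mean_acc),
                 mean_rank = mean_rank,
                 feature_index = fs$feature_index),
            class = "support_network")
}

#' @export
print.support_network <- function(x, ...) {
  cat(sprintf(
    "<support_network> %d directed edges over %d regions (best mean accuracy %.3f)\n",
    x$size, length(x$node_set), max(x$accuracy_trace$mean_accuracy)))
  invisible(x)
}

#' Annotate a support network with parcellation labels
#'
#' @param net a [select_support_network()] result.
#' @param parcellation parcellation table (see [read_parcellation()]).
#' @return data frame with one row per edge: rank, source/target indices,
#'   names and functional networks; direction (source -> target) is the EC
#'   influence direction.
#' @export
annotate_support <- function(net, parcellation) {
  stopifnot(inherits(net, "support_network"))
  idx <- c(net$edges$source, net$edges$target)
  if (any(idx < 1L | idx > nrow(parcellation))) {
    stop_invalid("edge endpoint outside the parcellation (indices 1..",
                 nrow(parcellation), ")")
  }
  data.frame(
    rank = net$edges$rank,
    source_index = net$edges$source,
    source_name = parcellation$name[net$edges$source],
    source_network = parcellation$network[net$edges$source],
    target_index = net$edges$target,
    target_name = parcellation$name[net$edges$target],
    target_network = parcellation$network[net$edges$target])
}

#' @rdname annotate_support
#' @param path output TSV path.
#' @export
write_support_network <- function(net, parcellation, path) {
  utils::write.table(annotate_support(net, parcellation), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
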