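make_planted_fs <- function(n_per_class = 14, p = 100, informative = 1:5,
                            effect = 3, seed = 13, directed_index = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  x[(n_per_class + 1):(2 * n_per_class), informative] <-
    x[(n_per_class + 1):(2 * n_per_class), informative] + effect
  x <- t(scale(t(x)))
  fi <- data.frame(feature = seq_len(p),
                   source = ((seq_len(p) - 1) %% 10) + 1,
                   target = ((seq_len(p) - 1) %/% 10) + 1)
  structure(list(matrix = x, labels = rep(c("pre", "post"), each = n_per_class),
                 metric_tag = "ec", feature_index = fi,
                 subject_ids = paste0("s", seq_len(2 * n_per_class))),
            class = "feature_set")
}

test_that("rfe_ranking returns a permutation and finds the informative feature", {
  # 2 features, only the first separates the classes
  set.seed(1)
  x <- cbind(rep(c(-2, 2), each = 10) + rnorm(20, sd = 0.1), rnorm(20))
  fs <- structure(list(matrix = x, labels = rep(c("a", "b"), each = 10),
                       metric_tag = "ec",
                       feature_index = data.frame(feature = 1:2, source = 1:2,
                                                  target = c(2, 1)),
                       subject_ids = paste0("s", 1:20)),
                  class = "feature_set")
  rk <- rfe_ranking(fs)
  expect_equal(sort(rk), 1:2)
  expect_equal(rk[1], 1L)

  fs100 <- make_planted_fs()
  rk100 <- rfe_ranking(fs100)
  expect_setequal(sort(rk100), 1:100)
  expect_true(all(rk100[1:5] <= 10))   # all informative within top 10 ranks

  fs1 <- fs100; fs1$labels <- rep("same", nrow(fs1$matrix))
  expect_error(rfe_ranking(fs1), "2 classes")
})

test_that("select_support_network recovers planted features", {
  fs <- make_planted_fs(effect = 2)
  net <- select_support_network(fs, n_repetitions = 10, seed = 3)
  planted <- fs$feature_index[1:5, c("source", "target")]
  found <- merge(net$edges, planted)
  expect_gte(nrow(found), 4)          # recall >= 0.8 of 5 planted edges
  # selected size maximises the mean accuracy trace
  best <- max(net$accuracy_trace$mean_accuracy)
  at_size <- net$accuracy_trace$mean_accuracy[net$accuracy_trace$size == net$size]
  expect_gte(at_size, best - 1e-6)
  larger <- net$accuracy_trace$mean_accuracy[net$accuracy_trace$size > net$size]
  expect_true(all(larger <= best + 1e-6))
  # ranks are unique 1..size and the node set is consistent
  expect_equal(sort(net$edges$rank), seq_len(net$size))
  expect_setequal(net$node_set, unique(c(net$edges$source, net$edges$target)))
})

test_that("select_support_network is deterministic under a fixed seed", {
  fs <- make_planted_fs(effect = 2)
  a <- select_support_network(fs, n_repetitions = 5, seed = 11)
  b <- select_support_network(fs, n_repetitions = 5, seed = 11)
  expect_identical(a$edges, b$edges)
})

test_that("consensus-ranking recall never decreases with the planted effect size", {
  # recall of the planted features among the top-10 consensus ranks; the
  # selected-subset size itself shrinks once single features saturate
  # accuracy, so the ranking is the monotone quantity
  recalls <- vapply(c(1, 2, 4), function(eff) {
    fs <- make_planted_fs(effect = eff, seed = 5)
    net <- select_support_network(fs, n_repetitions = 6, seed = 2)
    mean(order(net$mean_rank)[1:10] %in% 1:5)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_gte(recalls[3], 0.4)
})

test_that("annotate_support preserves direction and resolves labels", {
  parc <- make_parcellation(10)
  net <- structure(list(
    edges = data.frame(rank = 1:2, source = c(3, 7), target = c(7, 1)),
    node_set = c(1, 3, 7), size = 2L,
    accuracy_trace = data.frame(size = 1:2, mean_accuracy = c(0.8, 0.9)),
    mean_rank = NULL, feature_index = NULL), class = "support_network")
  ann <- annotate_support(net, parc)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$source_name[1], parc$name[3])
  expect_equal(ann$target_name[1], parc$name[7])
  expect_equal(ann$source_index[2], 7)   # never flipped to (1, 7)
  expect_equal(ann$target_index[2], 1)
  expect_equal(length(unique(c(ann$source_index, ann$target_index))), 3)

  bad <- net; bad$edges$target[1] <- 99
  expect_error(annotate_support(bad, parc), "parcellation")
})
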