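test_that("percentile seeding sizes, priority and degeneracy", {
  set.seed(10)
  metrics <- data.frame(node = sprintf("g%03d", 1:100), degree = 2L,
                        aspl = sample(100), bc = sample(100) / 100,
                        nc = sample(100))
  seeds <- seed_labels(metrics)
  counts <- table(seeds$label)
  expect_equal(unname(counts["H"]), 1)
  expect_lte(counts["I"], 10)
  expect_lte(counts["P"], 10)
  expect_equal(anyDuplicated(seeds$node), 0)

  # a node top in both BC and NC is seeded H (priority H > I > P)
  top_both <- metrics$node[which.max(metrics$bc)]
  metrics$nc[metrics$node == top_both] <- max(metrics$nc) + 1
  seeds2 <- seed_labels(metrics)
  expect_equal(as.character(seeds2$label[seeds2$node == top_both]), "H")

  metrics$bc <- 0.5
  expect_error(seed_labels(metrics), "degenerate")
})

test_that("SMOTE balances classes with interpolated minority points", {
  fx <- separable_metrics(n_per = 20, seed = 2)
  seeds <- fx$seeds
  seeds <- seeds[c(1:2, 21:40, 41:60), ]  # classes (2, 20, 20)
  out <- oversample_minority(seeds, fx$metrics, k_neighbors = 1, seed = 7)
  expect_equal(as.integer(table(out$label)), rep(20L, 3))
  expect_equal(sum(out$synthetic), 18)
  expect_true(all(out$label[out$synthetic] == "H"))

  # every synthetic point is a convex combination of two real same-class rows
  feats <- c("aspl", "bc", "nc")
  real_h <- as.matrix(out[!out$synthetic & out$label == "H", feats])
  for (i in which(out$synthetic)) {
    x <- as.numeric(out[i, feats])
    found <- FALSE
    for (a in seq_len(nrow(real_h))) {
      for (b in seq_len(nrow(real_h))) {
        if (a == b) next
        v <- real_h[b, ] - real_h[a, ]
        t_est <- if (abs(v[1]) > 1e-12) (x[1] - real_h[a, 1]) / v[1] else NA
        if (is.na(t_est) || t_est < -1e-9 || t_est > 1 + 1e-9) next
        if (max(abs(real_h[a, ] + t_est * v - x)) < 1e-9) found <- TRUE
      }
    }
    expect_true(found)
  }
})

test_that("balanced input passes through SMOTE unchanged", {
  fx <- separable_metrics(n_per = 10, seed = 3)
  out <- oversample_minority(fx$seeds, fx$metrics, k_neighbors = 3, seed = 1)
  expect_equal(sum(out$synthetic), 0)
  expect_equal(out$node, fx$seeds$node)
})

test_that("SMOTE refuses classes smaller than k+1", {
  fx <- separable_metrics(n_per = 20, seed = 2)
  seeds <- fx$seeds[c(1:3, 21:40, 41:60), ]  # H has 3 members
  expect_error(oversample_minority(seeds, fx$metrics, k_neighbors = 5),
               "smaller k")
})

test_that("cross-validation separates planted classes and is seeded", {
  fx <- separable_metrics(n_per = 18, seed = 4)
  training <- oversample_minority(fx$seeds, fx$metrics, k_neighbors = 3,
                                  seed = 1)
  cv <- cross_validate(training, folds = 9, replicates = 5, seed = 1)
  s <- summarize_cv(cv)
  expect_gte(s$mean_accuracy, 0.95)
  expect_equal(length(cv[[1]]$fold_accuracy), 9)

  cv_strat <- cross_validate(training, folds = 9, replicates = 5,
                             stratified = TRUE, seed = 1)
  expect_gte(summarize_cv(cv_strat)$mean_accuracy, 0.95)

  # chance level under label permutation
  set.seed(8)
  shuffled <- training
  shuffled$label <- sample(shuffled$label)
  s0 <- summarize_cv(cross_validate(shuffled, folds = 9, replicates = 5,
                                    seed = 1))
  expect_lt(abs(s0$mean_accuracy - 1 / 3), 0.15)

  # determinism under a fixed seed
  expect_identical(cross_validate(training, folds = 9, replicates = 2,
                                  seed = 42),
                   cross_validate(training, folds = 9, replicates = 2,
                                  seed = 42))
})

test_that("stratified CV refuses classes smaller than the fold count", {
  fx <- separable_metrics(n_per = 5, seed = 4)
  training <- oversample_minority(fx$seeds, fx$metrics, k_neighbors = 2,
                                  seed = 1)
  expect_error(cross_validate(training, folds = 9, stratified = TRUE,
                              replicates = 1, seed = 1), "at least 9")
})

test_that("classification assigns confident labels near class centroids", {
  fx <- separable_metrics(n_per = 20, seed = 5)
  training <- oversample_minority(fx$seeds, fx$metrics, k_neighbors = 3,
                                  seed = 1)
  centroid <- colMeans(fx$metrics[1:20, c("aspl", "bc", "nc")])
  probe <- data.frame(node = "probe", degree = 3L, aspl = centroid["aspl"],
                      bc = centroid["bc"], nc = centroid["nc"])
  res <- classify_nodes(training, rbind(fx$metrics, probe), seed = 1)
  probe_row <- res[res$node == "probe", ]
  expect_equal(probe_row$label, "H")
  expect_gt(probe_row$support, 0.8)
  expect_equal(probe_row$source, "predicted")
  # seeds keep their labels
  expect_true(all(res$source[res$node != "probe"] == "seed"))
  expect_equal(res$label[res$node == "H001"], "H")
})

test_that("the support threshold bounds declassification", {
  study <- simulate_study(synthetic_spec(seed = 6))
  m <- node_metrics(study$network)
  seeds <- seed_labels(m)
  training <- oversample_minority(seeds, m, k_neighbors = 2, seed = 1)

  all_unc <- classify_nodes(training, m, support_threshold = 1.0, seed = 1)
  expect_true(all(all_unc$label[all_unc$source == "predicted"] ==
                    "uncertain"))
  none_unc <- classify_nodes(training, m, support_threshold = 0.0, seed = 1)
  expect_false(any(none_unc$label == "uncertain"))

  # monotone: higher threshold never yields fewer uncertain nodes
  thresholds <- c(0, 0.3, 0.5, 0.7, 0.9, 1)
  n_unc <- vapply(thresholds, function(th) {
    sum(classify_nodes(training, m, support_threshold = th,
                       seed = 1)$label == "uncertain")
  }, 1L)
  expect_true(all(diff(n_unc) >= 0))
})

test_that("classification pipeline is deterministic and orders classes", {
  study <- simulate_study(synthetic_spec(seed = 12))
  m <- node_metrics(study$network)
  c1 <- classify_network(m, seed = 9)
  c2 <- classify_network(m, seed = 9)
  expect_identical(c1, c2)

  merged <- merge(m, c1[, c("node", "label")], by = "node")
  mean_bc <- tapply(merged$bc, merged$label, mean)
  expect_gt(mean_bc[["H"]], mean_bc[["I"]])
  expect_gt(mean_bc[["I"]], mean_bc[["P"]])
})
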