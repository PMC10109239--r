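test_that("fold assignment partitions positives into near-equal seeded folds", {
  set.seed(1)
  Y <- matrix(0, 100, 30)
  Y[sample(3000, 1923)] <- 1    # same positive count as a full dataset
  folds <- make_folds(Y, 10, seed = 3)
  sizes <- tabulate(folds$fold, 10)
  expect_true(all(sizes %in% c(192L, 193L)))
  expect_equal(sum(sizes), 1923L)
  expect_equal(sort(unique(folds$fold)), 1:10)
  folds2 <- make_folds(Y, 10, seed = 3)
  expect_identical(folds$fold, folds2$fold)
  # union of test folds is all positives, pairwise disjoint by construction
  expect_equal(nrow(folds$pairs), sum(Y))
  expect_error(make_folds(matrix(c(1, 0), 1, 2), 10, 1), "fewer positives")
})

test_that("ROC AUC matches hand values and the concordant-pair oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(0, 0, 1)), 0)
  expect_warning(v <- roc_auc(c(0.1, 0.2), c(1, 1)), "one class")
  expect_true(is.na(v))
  set.seed(6)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)   # coarse scores force ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.3)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("average precision matches hand enumeration on all short lists", {
  expect_equal(aupr(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(aupr(c(0.3, 0.2), c(1, 1)), 1)
  expect_equal(aupr(c(0.9, 0.8, 0.1), c(1, 0, 1)),
               (1 / 1 + 2 / 3) / 2)
  expect_warning(v <- aupr(c(0.5), c(0)), "no positive")
  expect_true(is.na(v))
  set.seed(9)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) next
    expect_equal(aupr(scores, labels), ap_oracle(scores, labels))
  }
})

test_that("top-ranked recall counts true targets in the score cut", {
  scores <- seq(1, 0.1, length.out = 10)
  labels <- c(1, rep(0, 9))
  expect_equal(top_omega_recall(scores, labels, 0.2), 1)     # ranked 1st
  labels_last <- c(rep(0, 9), 1)
  expect_equal(top_omega_recall(scores, labels_last, 0.5), 0)
  expect_equal(top_omega_recall(scores, labels_last, 1), 1)
  # 2 true of 20 candidates, one inside the top-10% cut
  scores20 <- seq(1, 0.05, length.out = 20)
  labels20 <- numeric(20); labels20[c(2, 15)] <- 1
  expect_equal(top_omega_recall(scores20, labels20, 0.10), 0.5)
  expect_true(is.na(top_omega_recall(scores, numeric(10), 0.1)))
  # monotone in the fraction
  set.seed(4)
  sc <- runif(30); lb <- rbinom(30, 1, 0.3); lb[1] <- 1
  recalls <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5, 1),
                    function(om) top_omega_recall(sc, lb, om), 1)
  expect_true(all(diff(recalls) >= 0))
})

test_that("the paired t-test matches the closed form and degenerate conventions", {
  ident <- rep(0.5, 5)
  r <- paired_t_test(ident, ident)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  r <- paired_t_test(ident + 0.1, ident)
  expect_equal(r$t, Inf); expect_equal(r$p, 0)
  set.seed(5)
  a <- runif(12); b <- runif(12)
  r <- paired_t_test(a, b)
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(12))
  expect_equal(r$t, t_ref)
  expect_equal(r$p, 2 * pt(-abs(t_ref), 11))
  r2 <- paired_t_test(a, b, paired = FALSE)
  expect_equal(r2$p, t.test(a, b)$p.value)
})

test_that("cross-validation never leaks held-out positives into training", {
  ds <- small_synth(seed = 1)
  folds <- make_folds(ds$Y, 4, seed = 2)
  for (f in 1:4) {
    inp <- sdgae:::.fold_training_inputs(ds$Y, folds, f)
    expect_true(all(inp$Y_masked[inp$test_pos] == 0))
    expect_true(all(ds$Y[inp$test_pos] == 1))
    # train pairs exclude every held-out positive
    key <- paste(inp$train_pairs[, 1], inp$train_pairs[, 2])
    held <- paste(inp$test_pos[, 1], inp$test_pos[, 2])
    expect_length(intersect(key, held), 0)
    expect_equal(nrow(inp$train_pairs),
                 prod(dim(ds$Y)) - nrow(inp$test_pos))
    # everything else is untouched
    untouched <- ds$Y; untouched[inp$test_pos] <- 0
    expect_identical(inp$Y_masked, untouched)
  }
})

test_that("cross-validation produces coherent per-fold and per-drug reports", {
  ds <- small_synth(seed = 2)
  ctrl <- cheap_control(epochs = 30L, n_rounds = 30L)
  cv <- sdgae_cv(ds, ctrl, seed = 3)
  expect_length(cv$fold_auc, 4)
  expect_length(cv$fold_aupr, 4)
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
  expect_true(all(cv$fold_aupr >= 0 & cv$fold_aupr <= 1))
  expect_equal(cv$auc, mean(cv$fold_auc))
  # per-drug lists cover exactly the drugs with at least one known target
  expect_length(cv$per_drug_auc, sum(rowSums(ds$Y) >= 1))
  # mean top-ranked recall is non-decreasing in the fraction
  expect_true(all(diff(cv$top_recall) >= -1e-12))
  # every scored entry is a probability
  expect_true(all(cv$Y_cv >= 0 & cv$Y_cv <= 1))
})

test_that("novel-pair ranking excludes known interactions and respects modes", {
  ds <- small_synth(seed = 3)
  ctrl <- cheap_control(epochs = 30L, n_rounds = 30L)
  top <- rank_novel(ds, ctrl, seed = 1, n_top = 20)
  expect_equal(nrow(top), 20)
  expect_true(all(diff(top$score) <= 1e-12))
  known <- paste(ds$drug_ids[which(ds$Y == 1, arr.ind = TRUE)[, 1]],
                 ds$target_ids[which(ds$Y == 1, arr.ind = TRUE)[, 2]])
  expect_length(intersect(paste(top$drug_id, top$target_id), known), 0)
  per_drug <- rank_novel(ds, ctrl, seed = 1, per_drug = 5,
                         oof_negatives = FALSE)
  counts <- table(per_drug$drug_id)
  expect_true(all(counts == 5))
  for (d in names(counts)[1:3]) {
    sc <- per_drug$score[per_drug$drug_id == d]
    expect_true(all(diff(sc) <= 1e-12))
  }
})
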