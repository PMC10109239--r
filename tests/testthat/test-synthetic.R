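test_that("the generator is deterministic and validates across seeds", {
  expect_identical(synthetic_dti_dataset(synth_config(seed = 42)),
                   synthetic_dti_dataset(synth_config(seed = 42)))
  for (seed in 1:20) {
    ds <- synthetic_dti_dataset(synth_config(m = 15, n = 18, c = 3,
                                             seed = seed))
    expect_identical(validate_dataset(ds), character(0))
  }
})

test_that("zero background and no hiding yields a block-diagonal pattern", {
  cfg <- synth_config(m = 12, n = 16, c = 2, pi_in = 0.9, pi_out = 0,
                      frac_unknown_drugs = 0, frac_unknown_targets = 0,
                      seed = 5)
  ds <- synthetic_dti_dataset(cfg)
  gt <- ground_truth(ds)
  cross <- outer(gt$drug_cluster, gt$target_cluster, "!=")
  expect_true(all(ds$Y[cross] == 0))
  expect_gt(sum(ds$Y[!cross]), 0)
})

test_that("positive counts follow the planted binomial model", {
  cfg <- synth_config(m = 30, n = 40, c = 2, frac_unknown_drugs = 0,
                      frac_unknown_targets = 0)
  match_cells <- sum(outer(sort(rep_len(1:2, 30)),
                           sort(rep_len(1:2, 40)), "=="))
  mu <- match_cells * cfg$pi_in + (30 * 40 - match_cells) * cfg$pi_out
  sd3 <- 3 * sqrt(match_cells * cfg$pi_in * (1 - cfg$pi_in) +
                    (1200 - match_cells) * cfg$pi_out * (1 - cfg$pi_out))
  counts <- vapply(1:20, function(s) {
    cfg_s <- synth_config(m = 30, n = 40, c = 2, frac_unknown_drugs = 0,
                          frac_unknown_targets = 0, seed = s)
    sum(synthetic_dti_dataset(cfg_s)$Y)
  }, 1)
  expect_lt(abs(mean(counts) - mu), sd3)
  expect_true(all(abs(counts - mu) < 2 * sd3))
})

test_that("hidden nodes are tracked exactly in the ground truth", {
  cfg <- synth_config(m = 50, n = 40, c = 2, frac_unknown_drugs = 0.2,
                      frac_unknown_targets = 0.1, seed = 8)
  ds <- synthetic_dti_dataset(cfg)
  gt <- ground_truth(ds)
  expect_length(gt$hidden_drugs, 10)    # floor(0.2 * 50)
  expect_length(gt$hidden_targets, 4)
  expect_true(all(rowSums(ds$Y)[gt$hidden_drugs] == 0))
  expect_true(all(colSums(ds$Y)[gt$hidden_targets] == 0))
  # hidden positives are invisible in Y but present in Y_full
  expect_true(all(ds$Y[gt$hidden_pairs] == 0))
  expect_true(all(gt$Y_full[gt$hidden_pairs] == 1))
  # visible positives are never in the hidden set
  vis <- which(ds$Y == 1, arr.ind = TRUE)
  expect_length(intersect(paste(vis[, 1], vis[, 2]),
                          paste(gt$hidden_pairs[, 1],
                                gt$hidden_pairs[, 2])), 0)
})

test_that("every generated similarity view is cluster-informative", {
  for (seed in c(2, 9, 17)) {
    ds <- synthetic_dti_dataset(synth_config(m = 24, n = 30, c = 3,
                                             seed = seed))
    gt <- ground_truth(ds)
    views <- list(
      ds$S_chemical,
      jaccard_similarity(ds$A_drug),
      jaccard_similarity(ds$B_drug_disease),
      jaccard_similarity(ds$B_drug_sideeffect)
    )
    same <- outer(gt$drug_cluster, gt$drug_cluster, "==")
    off <- !diag(24)
    for (V in views)
      expect_gt(mean(V[same & off]), mean(V[!same]))
  }
})

test_that("a similarity-only baseline already recovers hidden interactions", {
  # sanity check of the planted structure: scoring a hidden drug's
  # targets by its similarity-weighted neighbour profile beats chance
  ds <- synthetic_dti_dataset(synth_config(seed = 7))
  gt <- ground_truth(ds)
  fused <- build_fused_similarity(ds)
  # naive two-sided neighbourhood propagation (covers hidden drugs and
  # hidden targets alike)
  scores <- fused$S_drug %*% ds$Y %*% fused$S_target
  hidden <- gt$hidden_pairs
  labels <- matrix(0, nrow(ds$Y), ncol(ds$Y))
  labels[hidden] <- 1
  cand <- ds$Y == 0
  expect_gt(roc_auc(scores[cand], labels[cand]), 0.5)
})

test_that("infeasible cluster counts are rejected", {
  expect_error(synth_config(m = 3, n = 10, c = 4), "more clusters")
})
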