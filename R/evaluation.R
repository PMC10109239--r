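#' Partition known interactions into cross-validation folds
#'
#' Randomly assigns every positive pair of `Y` to one of `n_folds`
#' near-equal test folds. Negative pairs are not folded here: every
#' fold's training set keeps all negatives, and every fold's test set
#' scores the held-out positives against all negatives.
#'
#' @param Y binary interaction matrix.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return List of class `fold_split` with `pairs` (P x 2 index matrix
#'   of positives), `fold` (assignment 1..n_folds), `n_folds`, `seed`.
#' @export
make_folds <- function(Y, n_folds, seed) {
  pairs <- which(Y == 1, arr.ind = TRUE)
  colnames(pairs) <- c("drug", "target")
  P <- nrow(pairs)
  if (P < n_folds)
    stop("make_folds: fewer positives (", P, ") than folds (", n_folds, ")")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), P))
  structure(list(pairs = pairs, fold = fold,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "fold_split")
}

# zero the given positive pairs in a working copy of Y
.mask_positives <- function(Y, pairs) {
  Y[pairs] <- 0
  Y
}

# everything fold f's training stage is allowed to see: the masked
# interaction matrix and the training pairs (all pairs minus held-out
# positives)
.fold_training_inputs <- function(Y, folds, f) {
  test_pos <- folds$pairs[folds$fold == f, , drop = FALSE]
  Y_masked <- .mask_positives(Y, test_pos)
  in_test <- matrix(FALSE, nrow(Y), ncol(Y))
  in_test[test_pos] <- TRUE
  all_pairs <- .all_pairs(nrow(Y), ncol(Y))
  list(test_pos = test_pos, Y_masked = Y_masked,
       train_pairs = all_pairs[!in_test[all_pairs], , drop = FALSE])
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a
#' uniformly chosen negative, ties counting one half — identical to the
#' trapezoidal area under the ROC curve. Computed from midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1]; `NA` (with a warning) if only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    warning("roc_auc: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: the ranked list is scanned in
#' descending score order (ties broken by original position) and the
#' precision at each positive's rank is averaged over positives. No
#' trapezoidal interpolation — the step-curve convention standard for
#' severely imbalanced interaction ranking.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUPR in [0, 1]; `NA` (with a warning) if no positives.
#' @export
aupr <- function(scores, labels) {
  if (sum(labels == 1) == 0) {
    warning("aupr: no positive labels")
    return(NA_real_)
  }
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec * y) / sum(y)
}

#' Recall among the top-ranked fraction of candidates
#'
#' For one drug: the fraction of its true targets ranked within the top
#' `ceiling(omega * n_candidates)` candidates by score.
#'
#' @param scores candidate scores for one drug.
#' @param labels 0/1 truth for the candidates.
#' @param omega fraction in (0, 1].
#' @return Recall in [0, 1]; `NA` if the drug has no true target.
#' @export
top_omega_recall <- function(scores, labels, omega) {
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  cut <- ceiling(omega * length(scores))
  top <- order(-scores, seq_along(scores))[seq_len(cut)]
  sum(labels[top]) / P
}

#' Paired (or two-sample) t-test on per-drug metric lists
#'
#' Compares two equal-length lists of per-drug metrics (e.g. per-drug
#' AUCs of two methods). Degenerate inputs are handled explicitly: when
#' every difference is identical the statistic is 0 with p = 1 if the
#' common difference is zero, and +/-Inf with p = 0 otherwise.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param paired paired test (default) or Welch two-sample.
#' @return List with `t` and `p`.
#' @export
paired_t_test <- function(a, b, paired = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) return(list(t = 0, p = 1))
      return(list(t = sign(mean(d)) * Inf, p = 0))
    }
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) return(list(t = 0, p = 1))
      return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
    }
    ht <- stats::t.test(a, b, paired = FALSE)
  }
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

.omega_grid <- c(0.05, 0.10, 0.15, 0.20, 0.30)

# per-drug metrics from a completed cross-validated score matrix
.per_drug_metrics <- function(Y_cv, Y) {
  keep <- rowSums(Y) >= 1 & rowSums(1 - Y) >= 1
  drugs <- which(keep)
  auc <- vapply(drugs, function(i) roc_auc(Y_cv[i, ], Y[i, ]), 1)
  ap <- vapply(drugs, function(i) aupr(Y_cv[i, ], Y[i, ]), 1)
  rec <- sapply(.omega_grid, function(om)
    vapply(drugs, function(i) top_omega_recall(Y_cv[i, ], Y[i, ], om), 1))
  colnames(rec) <- paste0("top", .omega_grid * 100)
  list(drugs = drugs, auc = auc, aupr = ap, recall = rec)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Ten-fold (by default) cross-validation over positive pairs. For each
#' fold, the held-out positives are set to zero in the working
#' interaction matrix, and **everything downstream is recomputed from
#' the masked matrix** — similarity-based densification, heterogeneous
#' network, embeddings and classifier — so no information about test
#' interactions can leak into training. The fold's test set is the
#' held-out positives plus every negative pair.
#'
#' @param ds a [dti_dataset()].
#' @param control an [sdgae_control()].
#' @param seed seed for the fold split and per-fold fits (defaults to
#'   `control$seed`).
#' @param folds optional precomputed [make_folds()] split (used by the
#'   ablation harness so all arms share one split).
#' @param trace_every passed to [train_embeddings()].
#' @return Object of class `sdgae_cv`: `auc`/`aupr` (means over folds),
#'   `fold_auc`/`fold_aupr`, per-drug metric lists, `top_recall` (mean
#'   recall at 5/10/15/20/30% of candidates), the cross-validated score
#'   matrix `Y_cv`, the `folds` object and the `control`.
#' @export
sdgae_cv <- function(ds, control = sdgae_control(), seed = control$seed,
                     folds = NULL, trace_every = 100L) {
  Y <- ds$Y
  if (is.null(folds)) folds <- make_folds(Y, control$n_folds, seed)
  m <- nrow(Y); n <- ncol(Y)
  neg_mask <- Y == 0
  fold_auc <- numeric(folds$n_folds)
  fold_aupr <- numeric(folds$n_folds)
  pos_scores <- matrix(0, m, n)      # test-fold score of each positive
  neg_sum <- matrix(0, m, n)         # running sum of negative scores
  for (f in seq_len(folds$n_folds)) {
    inp <- .fold_training_inputs(Y, folds, f)
    test_pos <- inp$test_pos
    fit <- sdgae(ds, control = control, Y = inp$Y_masked,
                 train_pairs = inp$train_pairs, seed = seed + f,
                 trace_every = trace_every)
    Y_hat <- fit$Y_hat
    sc <- c(Y_hat[test_pos], Y_hat[neg_mask])
    lab <- c(rep(1, nrow(test_pos)), rep(0, sum(neg_mask)))
    fold_auc[f] <- roc_auc(sc, lab)
    fold_aupr[f] <- aupr(sc, lab)
    pos_scores[test_pos] <- Y_hat[test_pos]
    neg_sum[neg_mask] <- neg_sum[neg_mask] + Y_hat[neg_mask]
  }
  Y_cv <- pos_scores
  Y_cv[neg_mask] <- neg_sum[neg_mask] / folds$n_folds
  pd <- .per_drug_metrics(Y_cv, Y)
  structure(list(
    auc = mean(fold_auc), aupr = mean(fold_aupr),
    fold_auc = fold_auc, fold_aupr = fold_aupr,
    per_drug_auc = pd$auc, per_drug_aupr = pd$aupr,
    per_drug_recall = pd$recall,
    top_recall = colMeans(pd$recall, na.rm = TRUE),
    Y_cv = Y_cv, folds = folds, control = control, seed = seed
  ), class = "sdgae_cv")
}

#' @export
print.sdgae_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s profile)\n",
              x$folds$n_folds, x$control$profile))
  cat(sprintf("  AUC  %.4f (per-fold sd %.4f)\n", x$auc, stats::sd(x$fold_auc)))
  cat(sprintf("  AUPR %.4f (per-fold sd %.4f)\n", x$aupr, stats::sd(x$fold_aupr)))
  cat("  mean top-ranked recall:\n")
  cat(sprintf("    %s%%: %.3f\n", sub("top", "", names(x$top_recall)),
              x$top_recall), sep = "")
  invisible(x)
}

#' Rank unobserved drug-target pairs
#'
#' Trains on every known interaction and scores the unobserved (zero)
#' pairs — the novel-interaction prediction mode. By default negatives
#' are folded so each zero pair is scored by a classifier that did not
#' train on it (out-of-fold scoring); the embedding is learned once
#' from the full interaction matrix.
#'
#' @param ds a [dti_dataset()].
#' @param control an [sdgae_control()].
#' @param seed integer seed.
#' @param n_top number of top candidates to return (`Inf` for all).
#' @param per_drug if a number, return this many top candidates for
#'   every drug instead of a global list.
#' @param oof_negatives score negatives out-of-fold (default) instead
#'   of with a single model trained on all pairs.
#' @return A data frame `drug_id, target_id, score`, sorted by
#'   descending score (within drug for `per_drug` mode). Known-positive
#'   pairs never appear.
#' @export
rank_novel <- function(ds, control = sdgae_control(),
                       seed = control$seed, n_top = 20L,
                       per_drug = NULL, oof_negatives = TRUE) {
  Y <- ds$Y
  m <- nrow(Y); n <- ncol(Y)
  fit <- sdgae(ds, control = control, seed = seed, classifier = !oof_negatives)
  if (oof_negatives) {
    neg_pairs <- which(Y == 0, arr.ind = TRUE)
    set.seed(seed)
    fold <- sample(rep_len(seq_len(control$n_folds), nrow(neg_pairs)))
    pos_pairs <- which(Y == 1, arr.ind = TRUE)
    Y_hat <- matrix(NA_real_, m, n)
    for (f in seq_len(control$n_folds)) {
      tr_pairs <- rbind(pos_pairs, neg_pairs[fold != f, , drop = FALSE])
      tr <- assemble_training_set(fit$embedding, Y, tr_pairs)
      model <- train_pair_classifier(tr$x, tr$y, control, seed = seed + f)
      te <- neg_pairs[fold == f, , drop = FALSE]
      Y_hat[te] <- stats::predict(model, xgboost::xgb.DMatrix(
        .pair_feature_matrix(fit$embedding, te)))
    }
  } else {
    Y_hat <- fit$Y_hat
  }
  cand <- which(Y == 0, arr.ind = TRUE)
  df <- data.frame(drug_id = ds$drug_ids[cand[, 1]],
                   target_id = ds$target_ids[cand[, 2]],
                   score = Y_hat[cand], stringsAsFactors = FALSE)
  if (!is.null(per_drug)) {
    df <- df[order(df$drug_id, -df$score), ]
    df <- do.call(rbind, lapply(split(df, df$drug_id), function(g)
      utils::head(g, per_drug)))
    rownames(df) <- NULL
    return(df)
  }
  df <- df[order(-df$score), ]
  rownames(df) <- NULL
  utils::head(df, n_top)
}

#' Ablation comparison
#'
#' Runs cross-validation for the full model and the two ablated arms —
#' without densification and without the spatial-consistency loss —
#' under one shared fold split and seed, and tabulates AUC/AUPR.
#'
#' @param ds a [dti_dataset()].
#' @param control an [sdgae_control()] for the full arm.
#' @param seed shared seed.
#' @param trace_every passed through to [sdgae_cv()].
#' @return List of class `sdgae_ablation`: `table` (data frame with one
#'   row per arm) and `runs` (the three `sdgae_cv` objects).
#' @export
run_ablation_suite <- function(ds, control = sdgae_control(),
                               seed = control$seed, trace_every = 100L) {
  folds <- make_folds(ds$Y, control$n_folds, seed)
  arms <- list(
    full = control,
    without_ddm = utils::modifyList(control, list(use_ddm = FALSE)),
    without_scc = utils::modifyList(control, list(use_scc = FALSE))
  )
  runs <- lapply(arms, function(ctrl) {
    class(ctrl) <- "sdgae_control"
    sdgae_cv(ds, control = ctrl, seed = seed, folds = folds,
             trace_every = trace_every)
  })
  tab <- data.frame(
    model = names(runs),
    auc = vapply(runs, `[[`, 1, "auc"),
    aupr = vapply(runs, `[[`, 1, "aupr"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, runs = runs, folds = folds, seed = seed),
            class = "sdgae_ablation")
}

#' @export
print.sdgae_ablation <- function(x, ...) {
  cat("Ablation comparison (shared fold split)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
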