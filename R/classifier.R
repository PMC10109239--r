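#' Feature vector of a drug-target pair
#'
#' The concatenation of the drug's and the target's embedding rows,
#' length `2k`.
#'
#' @param emb an `sdgae_embedding`.
#' @param i drug index.
#' @param j target index.
#' @return Numeric vector of length `2 * ncol(Z)`.
#' @export
pair_features <- function(emb, i, j) {
  if (i < 1 || i > nrow(emb$Z_drug) || j < 1 || j > nrow(emb$Z_target))
    stop("pair_features: index out of range")
  c(emb$Z_drug[i, ], emb$Z_target[j, ])
}

# feature matrix for a set of (drug, target) index pairs; pairs is a
# 2-column matrix
.pair_feature_matrix <- function(emb, pairs) {
  cbind(emb$Z_drug[pairs[, 1], , drop = FALSE],
        emb$Z_target[pairs[, 2], , drop = FALSE])
}

.all_pairs <- function(m, n) {
  cbind(drug = rep(seq_len(m), times = n),
        target = rep(seq_len(n), each = m))
}

#' Assemble a classifier training set
#'
#' One row per training pair: concatenated embeddings as features and
#' the label from the **original** interaction matrix `Y` — never from
#' the densified matrix, whose imputed entries are estimates, not
#' observations. By default every pair is used; during cross-validation
#' the held-out positive pairs are excluded.
#'
#' @param emb an `sdgae_embedding`.
#' @param Y original binary interaction matrix.
#' @param pairs 2-column matrix of (drug, target) indices to include;
#'   default all `m * n` pairs.
#' @return List with `x` (matrix), `y` (0/1 vector) and `pairs`.
#' @export
assemble_training_set <- function(emb, Y, pairs = NULL) {
  if (is.null(pairs)) pairs <- .all_pairs(nrow(Y), ncol(Y))
  y <- Y[pairs]
  if (sum(y) == 0L) stop("assemble_training_set: no positive pairs")
  list(x = .pair_feature_matrix(emb, pairs), y = y, pairs = pairs)
}

#' Train the boosted-tree pair classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (binary logistic
#' objective, leaf-wise growth) on pair features. All negatives are
#' used — no subsampling — since the ensemble tolerates the extreme
#' class imbalance of interaction data. Deterministic for a fixed seed
#' (single-threaded, exact histogram construction).
#'
#' @param x feature matrix.
#' @param y 0/1 labels.
#' @param control an [sdgae_control()]; `lr_gbdt`, `n_rounds`,
#'   `n_leaves`, `seed` are used.
#' @param seed seed for tree fitting; defaults to `control$seed`.
#' @return A fitted `xgb.Booster`.
#' @export
train_pair_classifier <- function(x, y, control = sdgae_control(),
                                  seed = control$seed) {
  if (length(unique(y)) < 2L)
    stop("train_pair_classifier: need both classes present")
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y)
  params <- list(
    objective = "binary:logistic",
    eta = control$lr_gbdt,
    max_leaves = control$n_leaves,
    max_depth = 0L,
    grow_policy = "lossguide",
    tree_method = "hist",
    nthread = 1L,
    seed = seed
  )
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = control$n_rounds, verbose = 0)
}

#' Score every drug-target pair
#'
#' @param model fitted classifier from [train_pair_classifier()].
#' @param emb an `sdgae_embedding`.
#' @return `Y_hat`, an m x n matrix of interaction propensities in
#'   [0, 1].
#' @export
predict_all_pairs <- function(model, emb) {
  m <- nrow(emb$Z_drug)
  n <- nrow(emb$Z_target)
  pairs <- .all_pairs(m, n)
  p <- stats::predict(model, xgboost::xgb.DMatrix(
    .pair_feature_matrix(emb, pairs)))
  Y_hat <- matrix(NA_real_, m, n)
  Y_hat[pairs] <- p
  Y_hat
}

#' Write scores as a ranked TSV
#'
#' @param Y_hat score matrix.
#' @param drug_ids,target_ids identifiers.
#' @param path output file.
#' @param pairs optional 2-column index matrix restricting the output
#'   (e.g. candidate pairs only); default all pairs.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(Y_hat, drug_ids, target_ids, path,
                            pairs = NULL) {
  if (is.null(pairs)) pairs <- .all_pairs(nrow(Y_hat), ncol(Y_hat))
  sc <- Y_hat[pairs]
  ord <- order(-sc, pairs[, 1], pairs[, 2])
  df <- data.frame(drug_id = drug_ids[pairs[ord, 1]],
                   target_id = target_ids[pairs[ord, 2]],
                   score = sc[ord], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
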