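#' Fit the drug-target interaction model
#'
#' Runs the full representation-learning and classification pipeline on
#' a dataset: similarity fusion, weighted K-nearest-known-neighbours
#' densification of the interaction matrix (unless `control$use_ddm` is
#' off), heterogeneous-network assembly, graph convolutional autoencoder
#' training with the spatial-consistency Laplacian penalty and optional
#' adversarial regularisation, and a gradient-boosted tree classifier
#' over concatenated drug/target embeddings scoring every pair.
#'
#' Classifier labels always come from the supplied interaction matrix
#' `Y`, never from the densified matrix: imputed interactions inform
#' the graph, not the supervision.
#'
#' @param ds a [dti_dataset()].
#' @param control an [sdgae_control()].
#' @param Y working interaction matrix, defaulting to `ds$Y`.
#'   Cross-validation passes a copy with held-out positives zeroed.
#' @param train_pairs optional 2-column index matrix of pairs the
#'   classifier may train on (default: all pairs).
#' @param seed integer seed (defaults to `control$seed`).
#' @param classifier fit the pair classifier and score all pairs
#'   (default `TRUE`); `FALSE` stops after representation learning.
#' @param trace_every loss-trace granularity in epochs.
#' @return Object of class `sdgae` with components `control`, `fused`,
#'   `densify` (or `NULL`), `graph`, `scc` (or `NULL`), `embedding`,
#'   `model` (or `NULL`), `Y_hat` (or `NULL`), `drug_ids`,
#'   `target_ids`, `seed`, `call`.
#' @examples
#' ds <- synthetic_dti_dataset(synth_config(m = 20, n = 24, c = 2, seed = 1))
#' fit <- sdgae(ds, sdgae_control(profile = "desk", epochs = 30,
#'                                n_rounds = 20, seed = 1))
#' fit
#' @export
sdgae <- function(ds, control = sdgae_control(), Y = ds$Y,
                  train_pairs = NULL, seed = control$seed,
                  classifier = TRUE, trace_every = 1L) {
  stopifnot(inherits(ds, "dti_dataset"))
  fused <- build_fused_similarity(ds)
  dens <- if (control$use_ddm)
    densify_interactions(Y, fused, control) else NULL
  graph <- build_heterograph(ds, fused, dens, control, Y = Y)
  scc <- if (control$use_scc) build_scc(fused, control$p) else NULL
  emb <- train_embeddings(graph, scc, control, seed = seed,
                          trace_every = trace_every)
  model <- NULL
  Y_hat <- NULL
  if (classifier) {
    tr <- assemble_training_set(emb, Y, train_pairs)
    model <- train_pair_classifier(tr$x, tr$y, control, seed = seed)
    Y_hat <- predict_all_pairs(model, emb)
  }
  structure(list(
    control = control, fused = fused, densify = dens, graph = graph,
    scc = scc, embedding = emb, model = model, Y_hat = Y_hat,
    drug_ids = ds$drug_ids, target_ids = ds$target_ids,
    Y = Y, seed = seed, call = match.call()
  ), class = "sdgae")
}

#' @export
print.sdgae <- function(x, ...) {
  m <- x$graph$m; n <- x$graph$n
  tr <- x$embedding$trace
  last <- tr[nrow(tr), ]
  cat("Drug-target interaction model\n")
  cat(sprintf("  %d drugs x %d targets; embedding dim %d (hidden %d)\n",
              m, n, x$control$embed_dim, x$control$hidden_dim))
  cat(sprintf("  stages: densify=%s, spatial consistency=%s, adversarial=%s\n",
              x$control$use_ddm, x$control$use_scc, x$control$use_gan))
  cat(sprintf("  final encoding loss %.4g after %d epochs\n",
              last$L_encoding, x$control$epochs))
  if (!is.null(x$densify) && is.finite(x$densify$e_median))
    cat(sprintf("  densification: %d values imputed, threshold %.4g\n",
                length(x$densify$E), x$densify$e_median))
  if (is.null(x$Y_hat))
    cat("  (representation only; no classifier fitted)\n")
  invisible(x)
}

#' Predict interaction propensities
#'
#' @param object a fitted [sdgae()] model.
#' @param pairs optional 2-column matrix of (drug, target) indices; the
#'   default scores all pairs.
#' @param type `"matrix"` (m x n score matrix; only with the default
#'   `pairs`) or `"pairs"` (data frame `drug_id, target_id, score`).
#' @param ... unused.
#' @return Score matrix or data frame of scores in [0, 1].
#' @export
predict.sdgae <- function(object, pairs = NULL,
                          type = c("matrix", "pairs"), ...) {
  type <- match.arg(type)
  if (is.null(object$model))
    stop("predict.sdgae: model was fitted with classifier = FALSE")
  if (is.null(pairs)) {
    if (type == "matrix") return(object$Y_hat)
    pairs <- .all_pairs(object$graph$m, object$graph$n)
  }
  sc <- object$Y_hat[pairs]
  data.frame(drug_id = object$drug_ids[pairs[, 1]],
             target_id = object$target_ids[pairs[, 2]],
             score = sc, stringsAsFactors = FALSE)
}

#' @export
summary.sdgae <- function(object, ...) {
  out <- list(control = object$control, trace = object$embedding$trace)
  if (!is.null(object$Y_hat)) {
    lab <- as.vector(object$Y)
    sc <- as.vector(object$Y_hat)
    out$train_auc <- roc_auc(sc, lab)
    out$train_aupr <- aupr(sc, lab)
  }
  if (!is.null(object$densify)) {
    out$isolated_before <- isolated_node_count(object$Y)
    out$isolated_after <- isolated_node_count(object$densify$Y_DTI)
  }
  class(out) <- "summary.sdgae"
  out
}

#' @export
print.summary.sdgae <- function(x, ...) {
  cat("Summary of drug-target interaction model\n")
  if (!is.null(x$train_auc))
    cat(sprintf("  resubstitution AUC %.4f, AUPR %.4f\n",
                x$train_auc, x$train_aupr))
  if (!is.null(x$isolated_before))
    cat(sprintf("  isolated nodes (drugs, targets): %d, %d -> %d, %d after densification\n",
                x$isolated_before[1], x$isolated_before[2],
                x$isolated_after[1], x$isolated_after[2]))
  tr <- x$trace
  cat(sprintf("  encoding loss: %.4g (epoch %d) -> %.4g (epoch %d)\n",
              tr$L_encoding[1], tr$epoch[1],
              tr$L_encoding[nrow(tr)], tr$epoch[nrow(tr)]))
  invisible(x)
}

#' Plot training loss traces
#'
#' Encoding, reconstruction and spatial-consistency losses per epoch,
#' with discriminator/generator losses when the adversarial regulariser
#' was active.
#'
#' @param x a fitted [sdgae()] model.
#' @param log_y logarithmic loss axis (default `TRUE`).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sdgae <- function(x, log_y = TRUE, ...) {
  tr <- x$embedding$trace
  cols <- c("L_encoding", "L_reconstitution", "L_spatial_consistency",
            "L_D", "L_G")
  keep <- cols[colSums(!is.na(tr[cols])) > 0]
  M <- as.matrix(tr[keep])
  graphics::matplot(tr$epoch, M, type = "l", lty = 1,
                    col = seq_along(keep), xlab = "epoch",
                    ylab = "loss", log = if (log_y) "y" else "", ...)
  graphics::legend("topright", legend = keep, col = seq_along(keep),
                   lty = 1, bty = "n")
  invisible(x)
}
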