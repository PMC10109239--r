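#' Configuration of the synthetic benchmark generator
#'
#' The generator plants `c` matched drug/target cluster pairs: drugs
#' interact mostly with the targets of their matched cluster, all
#' similarity views carry the same cluster signal, and stated fractions
#' of drugs/targets have their interactions hidden to emulate the
#' isolated ("unknown") nodes of real interaction data. The defaults
#' define the desk-scale benchmark used throughout the test-suite:
#' 60 drugs, 80 targets, 4 cluster pairs, within-cluster interaction
#' probability 0.3 against a 0.01 background, 20% of drugs and 30% of
#' targets hidden, seed 7.
#'
#' @param m,n numbers of drugs and targets.
#' @param c number of matched cluster pairs (`c <= min(m, n)`).
#' @param pi_in,pi_out within-cluster and background interaction
#'   probabilities (`pi_in > pi_out`).
#' @param assoc_rate probability of an association feature (disease,
#'   side effect, within-cluster network edge) in the matching cluster
#'   block.
#' @param sim_noise standard deviation of the jitter added to the
#'   cluster-indicator similarity (then truncated to [0, 1]).
#' @param frac_unknown_drugs,frac_unknown_targets fractions in [0, 1)
#'   of drugs/targets whose interaction row/column is zeroed.
#' @param n_disease,n_sideeffect numbers of disease and side-effect
#'   features.
#' @param seed integer seed.
#' @return Named list of class `synth_config`.
#' @export
synth_config <- function(m = 60L, n = 80L, c = 4L, pi_in = 0.3,
                         pi_out = 0.01, assoc_rate = 0.3,
                         sim_noise = 0.1, frac_unknown_drugs = 0.2,
                         frac_unknown_targets = 0.3, n_disease = 40L,
                         n_sideeffect = 32L, seed = 7L) {
  cfg <- list(m = as.integer(m), n = as.integer(n), c = as.integer(c),
              pi_in = pi_in, pi_out = pi_out, assoc_rate = assoc_rate,
              sim_noise = sim_noise,
              frac_unknown_drugs = frac_unknown_drugs,
              frac_unknown_targets = frac_unknown_targets,
              n_disease = as.integer(n_disease),
              n_sideeffect = as.integer(n_sideeffect),
              seed = as.integer(seed))
  stopifnot(cfg$pi_in > cfg$pi_out, cfg$pi_out >= 0,
            cfg$frac_unknown_drugs >= 0, cfg$frac_unknown_drugs < 1,
            cfg$frac_unknown_targets >= 0, cfg$frac_unknown_targets < 1)
  if (cfg$c > min(cfg$m, cfg$n))
    stop("synth_config: more clusters than drugs or targets")
  class(cfg) <- "synth_config"
  cfg
}

.rbinom_mat <- function(nr, nc, p) matrix(stats::rbinom(nr * nc, 1, p), nr, nc)

# symmetric binary matrix, zero diagonal, entry probability by cluster
.cluster_network <- function(cluster, p_in, p_out) {
  nn <- length(cluster)
  P <- ifelse(outer(cluster, cluster, "=="), p_in, p_out)
  A <- matrix(0, nn, nn)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1, P[up])
  A + t(A)
}

# cluster-block binary association matrix (entities x features)
.cluster_assoc <- function(cluster, n_feat, n_clust, p_in, p_out) {
  feat_cluster <- sort(rep_len(seq_len(n_clust), n_feat))
  P <- ifelse(outer(cluster, feat_cluster, "=="), p_in, p_out)
  matrix(stats::rbinom(length(P), 1, P), nrow = length(cluster))
}

# cluster-indicator similarity with truncated symmetric jitter
.cluster_similarity <- function(cluster, sd) {
  nn <- length(cluster)
  S <- outer(cluster, cluster, "==") * 1
  E <- matrix(stats::rnorm(nn * nn, 0, sd), nn, nn)
  S <- S + (E + t(E)) / 2
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

#' Generate a synthetic drug-target dataset
#'
#' Produces a complete [dti_dataset()] with planted, matched cluster
#' structure: the interaction matrix, both within-type networks, all
#' three association matrices and both precomputed similarity matrices
#' carry the same cluster signal, so similarity fusion recovers the
#' clusters and the densification and spatial-consistency stages have
#' the structure they were designed to exploit. A fraction of drugs and
#' targets is hidden (interaction rows/columns zeroed) to emulate
#' isolated nodes; the zeroed true interactions are retained as ground
#' truth in the `"ground_truth"` attribute (see [ground_truth()]).
#'
#' @param cfg a [synth_config()].
#' @return A [dti_dataset()] with attribute `"ground_truth"`.
#' @export
synthetic_dti_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  dc <- sort(rep_len(seq_len(cfg$c), cfg$m))
  tc <- sort(rep_len(seq_len(cfg$c), cfg$n))
  P <- ifelse(outer(dc, tc, "=="), cfg$pi_in, cfg$pi_out)
  Y_full <- matrix(stats::rbinom(length(P), 1, P), cfg$m, cfg$n)
  A_drug <- .cluster_network(dc, cfg$assoc_rate, cfg$pi_out)
  A_target <- .cluster_network(tc, cfg$assoc_rate, cfg$pi_out)
  B_dd <- .cluster_assoc(dc, cfg$n_disease, cfg$c, cfg$assoc_rate, cfg$pi_out)
  B_ds <- .cluster_assoc(dc, cfg$n_sideeffect, cfg$c, cfg$assoc_rate, cfg$pi_out)
  B_td <- .cluster_assoc(tc, cfg$n_disease, cfg$c, cfg$assoc_rate, cfg$pi_out)
  S_chem <- .cluster_similarity(dc, cfg$sim_noise)
  S_seq <- .cluster_similarity(tc, cfg$sim_noise)
  hidden_drugs <- sort(sample(cfg$m, floor(cfg$frac_unknown_drugs * cfg$m)))
  hidden_targets <- sort(sample(cfg$n, floor(cfg$frac_unknown_targets * cfg$n)))
  Y <- Y_full
  Y[hidden_drugs, ] <- 0
  Y[, hidden_targets] <- 0
  hidden_pairs <- which(Y_full == 1 & Y == 0, arr.ind = TRUE)
  colnames(hidden_pairs) <- c("drug", "target")
  ds <- dti_dataset(
    drug_ids = sprintf("D%03d", seq_len(cfg$m)),
    target_ids = sprintf("T%04d", seq_len(cfg$n)),
    Y = Y, A_drug = A_drug, A_target = A_target,
    B_drug_disease = B_dd, B_drug_sideeffect = B_ds,
    B_target_disease = B_td, S_chemical = S_chem, S_sequence = S_seq
  )
  attr(ds, "ground_truth") <- list(
    Y_full = Y_full, hidden_pairs = hidden_pairs,
    hidden_drugs = hidden_drugs, hidden_targets = hidden_targets,
    drug_cluster = dc, target_cluster = tc, config = cfg
  )
  ds
}

#' Hidden true interactions of a synthetic dataset
#'
#' @param ds a dataset from [synthetic_dti_dataset()].
#' @return List with the full pre-hiding matrix `Y_full`, the
#'   `hidden_pairs` index matrix (true interactions zeroed in `ds$Y`),
#'   the hidden drug/target indices, the planted cluster assignments
#'   and the generating config.
#' @export
ground_truth <- function(ds) {
  gt <- attr(ds, "ground_truth")
  if (is.null(gt))
    stop("ground_truth: dataset carries no ground-truth attribute")
  gt
}
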