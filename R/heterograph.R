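#' Block adjacency of the drug-target heterogeneous network
#'
#' Stacks the drug-drug network, the (densified) drug-target
#' interactions and the target-target network into the
#' `(m+n) x (m+n)` block matrix
#' `[[A_drug, Y_DTI], [t(Y_DTI), A_target]]`. Drugs occupy the first
#' `m` rows, targets the last `n`.
#'
#' @param A_drug binary symmetric m x m matrix.
#' @param A_target binary symmetric n x n matrix.
#' @param Y_DTI binary m x n matrix.
#' @return Symmetric binary `(m+n) x (m+n)` matrix.
#' @export
build_adjacency <- function(A_drug, A_target, Y_DTI) {
  if (!isTRUE(all.equal(A_drug, t(A_drug), check.attributes = FALSE)))
    stop("build_adjacency: A_drug is not symmetric")
  if (!isTRUE(all.equal(A_target, t(A_target), check.attributes = FALSE)))
    stop("build_adjacency: A_target is not symmetric")
  stopifnot(nrow(A_drug) == nrow(Y_DTI), nrow(A_target) == ncol(Y_DTI))
  rbind(cbind(A_drug, Y_DTI), cbind(t(Y_DTI), A_target))
}

#' Node feature matrix of the heterogeneous network
#'
#' Assembles the `(m+n) x (m+n)` feature matrix
#' `[[S_drug, Y_dense], [t(Y_dense), S_target]]`: each node is described
#' by its fused similarity to every node of its own type and its
#' (densified) interaction profile with the other type.
#'
#' @param S_drug,S_target fused similarity matrices.
#' @param Y_dense densified interaction matrix (real-valued).
#' @return Real `(m+n) x (m+n)` matrix.
#' @export
build_features <- function(S_drug, S_target, Y_dense) {
  stopifnot(nrow(S_drug) == nrow(Y_dense),
            nrow(S_target) == ncol(Y_dense))
  rbind(cbind(S_drug, Y_dense), cbind(t(Y_dense), S_target))
}

#' Symmetric degree normalization with self-loops
#'
#' Adds a self-loop to every node, `A' = A + I`, and returns
#' `D^(-1/2) A' D^(-1/2)` where `D(i,i) = sum_j A'(i,j)`. Self-loops
#' guarantee positive degrees, so the result is always defined; its
#' spectral radius is at most 1.
#'
#' @param A_tilde square symmetric non-negative matrix.
#' @return The normalized matrix, symmetric with entries in [0, 1].
#' @export
normalize_adjacency <- function(A_tilde) {
  stopifnot(nrow(A_tilde) == ncol(A_tilde), all(A_tilde >= 0))
  Ap <- A_tilde + diag(nrow(A_tilde))
  dinv <- 1 / sqrt(rowSums(Ap))
  Ap * outer(dinv, dinv)
}

#' Isolated nodes of the drug-target bipartite block
#'
#' @param Y_DTI binary interaction block.
#' @return Named integer vector `c(drugs_isolated, targets_isolated)`:
#'   counts of all-zero rows and columns.
#' @export
isolated_node_count <- function(Y_DTI) {
  c(drugs_isolated = sum(rowSums(Y_DTI) == 0),
    targets_isolated = sum(colSums(Y_DTI) == 0))
}

#' Assemble the heterogeneous graph for a run
#'
#' Combines [build_adjacency()], [build_features()] and
#' [normalize_adjacency()]. When `control$use_ddm` is off the original
#' `Y` stands in for both `Y_DTI` and `Y_dense` (the
#' no-densification ablation arm). With `control$features =
#' "adjacency"` the node features are the raw block adjacency (pure
#' topology) instead of the similarity/interaction profiles.
#'
#' @param ds a [dti_dataset()].
#' @param fused a `fused_similarity` for `ds`.
#' @param dens a `densify_result` for `ds` (ignored when `use_ddm` is
#'   off; may be `NULL` in that case).
#' @param control an [sdgae_control()].
#' @param Y working interaction matrix; defaults to `ds$Y`. Passed
#'   explicitly during cross-validation, where held-out positives are
#'   masked to zero.
#' @return List of class `hetero_graph` with `A_tilde`, `X_tilde`,
#'   `A_bar`, `m`, `n`.
#' @export
build_heterograph <- function(ds, fused, dens = NULL,
                              control = sdgae_control(), Y = ds$Y) {
  if (control$use_ddm) {
    if (is.null(dens)) dens <- densify_interactions(Y, fused, control)
    Y_DTI <- dens$Y_DTI
    Y_dense <- dens$Y_dense
  } else {
    Y_DTI <- Y
    Y_dense <- Y
  }
  A_tilde <- build_adjacency(ds$A_drug, ds$A_target, Y_DTI)
  X_tilde <- if (control$features == "adjacency") A_tilde
             else build_features(fused$S_drug, fused$S_target, Y_dense)
  structure(list(A_tilde = A_tilde, X_tilde = X_tilde,
                 A_bar = normalize_adjacency(A_tilde),
                 m = nrow(ds$Y), n = ncol(ds$Y)),
            class = "hetero_graph")
}

#' Export the heterogeneous network as a typed edge list
#'
#' @param graph a `hetero_graph`.
#' @param ds the originating [dti_dataset()] (for identifiers).
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, ds, path) {
  A <- graph$A_tilde
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  m <- graph$m
  ids <- c(ds$drug_ids, ds$target_ids)
  type <- function(i) ifelse(i <= m, "drug", "target")
  df <- data.frame(
    from = ids[idx[, 1]], from_type = type(idx[, 1]),
    to = ids[idx[, 2]], to_type = type(idx[, 2]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
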