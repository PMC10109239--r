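#' Jaccard similarity between the rows of a binary association matrix
#'
#' Treats row `i` of `B` as the feature set of entity `i` (e.g. the side
#' effects associated with a drug) and returns
#' `S(i, j) = |F_i intersect F_j| / |F_i union F_j|`.
#' When both feature sets are empty the off-diagonal value is 0 by
#' convention (rather than NaN); the diagonal is always 1, so that every
#' entity is maximally similar to itself regardless of feature coverage.
#'
#' @param B binary matrix (entities x features).
#' @return Symmetric matrix with unit diagonal and entries in [0, 1].
#' @export
jaccard_similarity <- function(B) {
  B <- as.matrix(B)
  if (!.is_binary(B)) stop("jaccard_similarity: B must be binary")
  inter <- tcrossprod(B)
  sizes <- rowSums(B)
  union <- outer(sizes, sizes, "+") - inter
  S <- ifelse(union > 0, inter / union, 0)
  diag(S) <- 1
  S
}

#' Fuse similarity views by elementwise maximum
#'
#' @param views list of same-shaped similarity matrices.
#' @return The elementwise maximum across views.
#' @export
fuse_similarities <- function(views) {
  stopifnot(is.list(views), length(views) >= 1L)
  d <- dim(views[[1]])
  for (V in views)
    if (!identical(dim(V), d))
      stop("fuse_similarities: views have mismatched shapes")
  Reduce(pmax, views)
}

#' Fused drug and target similarity matrices
#'
#' Builds every similarity view the dataset supports and fuses each side
#' by elementwise maximum. For drugs: the precomputed chemical-structure
#' similarity plus Jaccard similarities of the drug-drug interaction
#' profiles, drug-disease associations and drug-side effect
#' associations. For targets: the precomputed sequence similarity plus
#' Jaccard similarities of target-target interaction profiles and
#' target-disease associations. For the interaction-profile views the
#' feature set of a node is its neighbour set (the self edge is absent
#' by construction, zero diagonal).
#'
#' @param ds a [dti_dataset()].
#' @return List of class `fused_similarity` with elements `S_drug`
#'   (m x m) and `S_target` (n x n).
#' @export
build_fused_similarity <- function(ds) {
  S_drug <- fuse_similarities(list(
    ds$S_chemical,
    jaccard_similarity(ds$A_drug),
    jaccard_similarity(ds$B_drug_disease),
    jaccard_similarity(ds$B_drug_sideeffect)
  ))
  S_target <- fuse_similarities(list(
    ds$S_sequence,
    jaccard_similarity(ds$A_target),
    jaccard_similarity(ds$B_target_disease)
  ))
  structure(list(S_drug = S_drug, S_target = S_target),
            class = "fused_similarity")
}

#' Heatmap of a similarity submatrix
#'
#' Convenience visual inspection of any index subset of a similarity
#' matrix (for instance, drugs sharing a target).
#'
#' @param S similarity matrix.
#' @param idx indices of the rows/columns to display (default all).
#' @param labels optional identifiers used for axis labels.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
similarity_heatmap <- function(S, idx = seq_len(nrow(S)), labels = NULL,
                               ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("similarity_heatmap requires the 'pheatmap' package")
  M <- S[idx, idx, drop = FALSE]
  if (!is.null(labels)) rownames(M) <- colnames(M) <- labels[idx]
  invisible(pheatmap::pheatmap(M, cluster_rows = FALSE,
                               cluster_cols = FALSE, ...))
}

#' Write a matrix as tab-separated text
#'
#' @param M matrix.
#' @param path output file.
#' @param row_ids,col_ids optional identifiers; when supplied a header
#'   column/row is written.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path, row_ids = NULL, col_ids = NULL) {
  if (is.null(row_ids) && is.null(col_ids)) {
    utils::write.table(M, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    dimnames(M) <- list(row_ids, col_ids)
    utils::write.table(M, path, sep = "\t", quote = FALSE,
                       row.names = !is.null(row_ids),
                       col.names = !is.null(col_ids))
  }
  invisible(path)
}
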