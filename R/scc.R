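#' Mutual p-nearest-neighbour weight graph
#'
#' For each node `i`, the p-nearest-neighbour set `N_p(i)` contains `i`
#' itself plus the `p - 1` nodes with largest similarity to `i` (known
#' or unknown alike). The weight between `i` and `j` is 1 when each is
#' in the other's set, 0 when neither is, and 0.5 otherwise — a mutual
#' neighbour relation counts fully, a one-sided one at half weight. Ties
#' at the set boundary are broken by ascending index so sets have
#' exactly `p` members.
#'
#' @param S similarity matrix (unit diagonal expected).
#' @param p neighbour count, `1 <= p <= nrow(S)`.
#' @return Symmetric matrix with entries in \{0, 0.5, 1\} and unit
#'   diagonal.
#' @export
p_nearest_graph <- function(S, p) {
  nn <- nrow(S)
  stopifnot(p >= 1L, p <= nn)
  M <- matrix(FALSE, nn, nn) # M[i, j]: j in N_p(i)
  for (i in seq_len(nn)) {
    M[i, i] <- TRUE
    if (p > 1L) {
      others <- setdiff(seq_len(nn), i)
      ord <- order(-S[i, others], others)
      M[i, others[ord[seq_len(p - 1L)]]] <- TRUE
    }
  }
  (M & t(M)) * 1 + (xor(M, t(M))) * 0.5
}

#' Sparsify a similarity matrix and form its graph Laplacian
#'
#' Multiplies the similarity elementwise by the neighbour weight graph,
#' `S_hat = N * S`, and returns the degree diagonal
#' `D(i,i) = sum_r S_hat(i,r)` and Laplacian `L = D - S_hat`. The
#' Laplacian of a symmetric non-negative matrix is positive
#' semi-definite with zero row sums.
#'
#' @param S similarity matrix.
#' @param N weight graph from [p_nearest_graph()].
#' @return List with `S_hat`, `D` (diagonal matrix) and `L`.
#' @export
sparsify_similarity <- function(S, N) {
  stopifnot(identical(dim(S), dim(N)))
  S_hat <- N * S
  deg <- rowSums(S_hat)
  list(S_hat = S_hat, D = diag(deg, nrow(S)), L = diag(deg, nrow(S)) - S_hat)
}

#' Spatial-consistency structures for both node types
#'
#' @param fused a `fused_similarity`.
#' @param p neighbour count.
#' @return List of class `sparse_similarity` with drug/target `S_hat`,
#'   `L`, `D`.
#' @export
build_scc <- function(fused, p) {
  sd <- sparsify_similarity(fused$S_drug,
                            p_nearest_graph(fused$S_drug, p))
  st <- sparsify_similarity(fused$S_target,
                            p_nearest_graph(fused$S_target, p))
  structure(list(S_hat_drug = sd$S_hat, L_drug = sd$L, D_drug = sd$D,
                 S_hat_target = st$S_hat, L_target = st$L,
                 D_target = st$D),
            class = "sparse_similarity")
}

#' Spatial-consistency loss
#'
#' `lambda_l (||Z_D||_F^2 + ||Z_T||_F^2)
#'  + lambda_d sum_{i,r} S_hat_drug(i,r) ||Z_D[i,] - Z_D[r,]||^2
#'  + lambda_t sum_{j,q} S_hat_target(j,q) ||Z_T[j,] - Z_T[q,]||^2`
#' — a Tikhonov term plus weighted embedding-distance penalties over the
#' mutual-nearest-neighbour-sparsified similarities, keeping nodes that
#' are close in the original space close in the embedding space. The
#' distance sums run over ordered pairs, so the equivalent trace form is
#' `2 * Tr(t(Z) L Z)` per side; both forms are implemented and agree.
#'
#' @param Z_drug m x k drug embedding block.
#' @param Z_target n x k target embedding block.
#' @param scc a `sparse_similarity` from [build_scc()].
#' @param lambda_l,lambda_d,lambda_t non-negative weights.
#' @param form `"trace"` (default, used in training) or `"sum"` (the
#'   literal double sum, used as cross-check).
#' @return Non-negative scalar.
#' @export
scc_loss <- function(Z_drug, Z_target, scc, lambda_l, lambda_d,
                     lambda_t, form = c("trace", "sum")) {
  form <- match.arg(form)
  tik <- lambda_l * (sum(Z_drug^2) + sum(Z_target^2))
  if (form == "trace") {
    # Tr(t(Z) L Z) = sum(Z * (L Z))
    term_d <- 2 * sum(Z_drug * (scc$L_drug %*% Z_drug))
    term_t <- 2 * sum(Z_target * (scc$L_target %*% Z_target))
  } else {
    pair_sum <- function(Z, W) {
      acc <- 0
      for (i in seq_len(nrow(Z)))
        for (r in seq_len(nrow(Z)))
          acc <- acc + W[i, r] * sum((Z[i, ] - Z[r, ])^2)
      acc
    }
    term_d <- pair_sum(Z_drug, scc$S_hat_drug)
    term_t <- pair_sum(Z_target, scc$S_hat_target)
  }
  tik + lambda_d * term_d + lambda_t * term_t
}
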