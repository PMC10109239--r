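#' K nearest known neighbours of a node
#'
#' Returns the `K` *known* nodes (those flagged in `known`) most similar
#' to node `i`, excluding `i` itself, in descending similarity order.
#' Unknown nodes — those whose interaction profile is all zero — carry
#' no interaction information and are excluded. Ties are broken by
#' ascending index for determinism. Fewer than `K` neighbours are
#' returned when fewer known nodes exist; none when there are no known
#' nodes.
#'
#' @param S similarity matrix.
#' @param known logical/0-1 vector flagging known nodes.
#' @param i node index.
#' @param K neighbour count (>= 1).
#' @return List with `indices` and `weights` (similarities, descending).
#' @export
k_nearest_known_neighbours <- function(S, known, i, K) {
  stopifnot(K >= 1L)
  cand <- setdiff(which(as.logical(known)), i)
  if (length(cand) == 0L)
    return(list(indices = integer(0), weights = numeric(0)))
  s <- S[i, cand]
  ord <- order(-s, cand)
  take <- ord[seq_len(min(K, length(cand)))]
  list(indices = cand[take], weights = s[take])
}

# Decay-weighted neighbour estimate for all rows of Y given the row-side
# similarity S (m x m). Returns list(est = m x n matrix, has = logical
# vector marking rows with at least one known neighbour).
.wknkn_side <- function(Y, S, K, eta) {
  m <- nrow(Y)
  known <- rowSums(Y) > 0
  est <- matrix(0, m, ncol(Y))
  has <- logical(m)
  for (i in seq_len(m)) {
    nb <- k_nearest_known_neighbours(S, known, i, K)
    if (length(nb$indices) == 0L) next
    w <- eta^(seq_along(nb$indices) - 1) * nb$weights
    denom <- sum(nb$weights)
    if (denom <= 0) next
    est[i, ] <- crossprod(Y[nb$indices, , drop = FALSE], w) / denom
    has[i] <- TRUE
  }
  list(est = est, has = has)
}

#' Weighted K-nearest-known-neighbours densification
#'
#' Estimates the likelihood of unexplored drug-target interactions from
#' the interaction profiles of each node's most similar *known*
#' neighbours. The drug-side estimate for pair (i, j) is the decayed,
#' similarity-weighted average
#' `sum_a eta^(a-1) S_drug(i, d_a) Y(d_a, j) / sum_a S_drug(i, d_a)`
#' over the `K` nearest known drugs `d_a` of drug `i`; the target-side
#' estimate is symmetric over known target neighbours of target `j`. The
#' two sides are combined (mean by default) and the result is taken
#' entrywise against the original `Y` with `max`, so recorded
#' interactions are never down-weighted. Rows/columns with no known
#' neighbour fall back to the other side's estimate alone, or to `Y`
#' when both sides are empty.
#'
#' @param Y binary m x n interaction matrix.
#' @param S_drug,S_target fused similarity matrices (m x m, n x n).
#' @param K neighbour count (>= 1).
#' @param eta decay in (0, 1].
#' @param side_combine `"mean"` (default) or `"max"` combination of the
#'   drug- and target-side estimates.
#' @return `Y_dense`, a real m x n matrix in [0, 1] with
#'   `Y_dense >= Y` elementwise.
#' @export
wknkn <- function(Y, S_drug, S_target, K, eta, side_combine = "mean") {
  stopifnot(eta > 0, eta <= 1, K >= 1L)
  d <- .wknkn_side(Y, S_drug, K, eta)
  tt <- .wknkn_side(t(Y), S_target, K, eta)
  est_d <- d$est
  est_t <- t(tt$est)
  both <- outer(d$has, tt$has, "&")
  only_d <- outer(d$has, !tt$has, "&")
  only_t <- outer(!d$has, tt$has, "&")
  comb <- matrix(0, nrow(Y), ncol(Y))
  comb[both] <- if (side_combine == "max")
    pmax(est_d, est_t)[both] else ((est_d + est_t) / 2)[both]
  comb[only_d] <- est_d[only_d]
  comb[only_t] <- est_t[only_t]
  Y_dense <- pmax(Y, comb)
  Y_dense[Y_dense > 1] <- 1
  Y_dense[Y_dense < 0] <- 0
  Y_dense
}

#' Median-threshold discretization of a densified interaction matrix
#'
#' Collects the multiset `E` of imputed values — entries of `Y_dense`
#' strictly between 0 and 1 at positions where the original `Y` is 0 —
#' and thresholds `Y_dense` at the median of `E`: entries at or above
#' the median become 1, the rest 0. Original interactions remain 1
#' (1 >= median of values < 1). For an even-sized `E` the default
#' convention takes the lower of the two central values, keeping the
#' threshold an attained imputed value so "at or above" is non-vacuous.
#'
#' @param Y original binary matrix.
#' @param Y_dense densified matrix, `Y_dense >= Y` elementwise.
#' @param median_rule `"lower"` (default) or `"interpolate"`.
#' @return List with `Y_DTI` (binary matrix), `e_median` (threshold, or
#'   `NA` when no imputation occurred) and `E` (sorted imputed values).
#' @export
discretize_interactions <- function(Y, Y_dense, median_rule = "lower") {
  stopifnot(all(Y_dense - Y >= -1e-12))
  E <- sort(Y_dense[Y == 0 & Y_dense > 0 & Y_dense < 1])
  if (length(E) == 0L)
    return(list(Y_DTI = Y, e_median = NA_real_, E = E))
  e_median <- if (median_rule == "interpolate") stats::median(E)
              else E[ceiling(length(E) / 2)]
  Y_DTI <- (Y_dense >= e_median) * 1
  list(Y_DTI = Y_DTI, e_median = e_median, E = E)
}

#' Densify a drug-target interaction matrix
#'
#' Runs the weighted K-nearest-known-neighbours imputation ([wknkn()])
#' followed by median thresholding ([discretize_interactions()]) — the
#' preprocessing stage that shrinks the number of isolated nodes in the
#' drug-target bipartite graph before graph convolution.
#'
#' @param Y binary interaction matrix.
#' @param fused a `fused_similarity` (or list with `S_drug`, `S_target`).
#' @param control an [sdgae_control()]; `K`, `eta`, `side_combine` and
#'   `median_rule` are used.
#' @return List of class `densify_result` with `Y_dense`, `Y_DTI`,
#'   `e_median` and `E`.
#' @export
densify_interactions <- function(Y, fused, control = sdgae_control()) {
  Y_dense <- wknkn(Y, fused$S_drug, fused$S_target,
                   K = control$K, eta = control$eta,
                   side_combine = control$side_combine)
  disc <- discretize_interactions(Y, Y_dense,
                                  median_rule = control$median_rule)
  structure(list(Y_dense = Y_dense, Y_DTI = disc$Y_DTI,
                 e_median = disc$e_median, E = disc$E),
            class = "densify_result")
}
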