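# Independent reference implementations used to cross-check the package.
# All are deliberately naive (set operations, double loops, explicit
# pair counting) and shared across test files.

jaccard_oracle <- function(B) {
  r <- nrow(B)
  S <- diag(r)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    if (i == j) next
    fi <- which(B[i, ] == 1)
    fj <- which(B[j, ] == 1)
    u <- length(union(fi, fj))
    S[i, j] <- if (u == 0) 0 else length(intersect(fi, fj)) / u
  }
  S
}

# naive per-entry imputation: explicit neighbour sums for each pair
wknkn_oracle <- function(Y, S_drug, S_target, K, eta) {
  m <- nrow(Y); n <- ncol(Y)
  est <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    nb_d <- k_nearest_known_neighbours(S_drug, rowSums(Y) > 0, i, K)
    ed <- NA_real_
    if (length(nb_d$indices) > 0) {
      w <- eta^(seq_along(nb_d$indices) - 1) * nb_d$weights
      ed <- sum(w * Y[nb_d$indices, j]) / sum(nb_d$weights)
    }
    nb_t <- k_nearest_known_neighbours(S_target, colSums(Y) > 0, j, K)
    et <- NA_real_
    if (length(nb_t$indices) > 0) {
      w <- eta^(seq_along(nb_t$indices) - 1) * nb_t$weights
      et <- sum(w * Y[i, nb_t$indices]) / sum(nb_t$weights)
    }
    est[i, j] <-
      if (is.na(ed) && is.na(et)) 0
      else if (is.na(ed)) et
      else if (is.na(et)) ed
      else (ed + et) / 2
  }
  pmin(pmax(pmax(Y, est), 0), 1)
}

# brute-force concordant-pair AUC (ties count one half)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

# hand enumeration of average precision over the ranked list
ap_oracle <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  hits <- 0; acc <- 0
  for (r in seq_along(y)) {
    if (y[r] == 1) { hits <- hits + 1; acc <- acc + hits / r }
  }
  acc / sum(y)
}
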