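.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

#' Initialise encoder weights
#'
#' Seeded Glorot-uniform initialisation of the two GCN layer weights.
#'
#' @param n_nodes number of graph nodes (m + n).
#' @param hidden_dim hidden-layer width l.
#' @param embed_dim embedding dimension k.
#' @return List with `W1` ((m+n) x l) and `W2` (l x k).
#' @export
init_encoder <- function(n_nodes, hidden_dim, embed_dim) {
  list(W1 = .glorot(n_nodes, hidden_dim),
       W2 = .glorot(hidden_dim, embed_dim))
}

#' Two-layer graph convolutional encoder
#'
#' `Z = tanh(A_bar sigmoid(A_bar X W1) W2)`: two graph convolutions over
#' the symmetric-normalised, self-looped adjacency, with a sigmoid
#' hidden activation and tanh output, so all embedding entries lie in
#' (-1, 1). Drugs occupy the first m rows of `Z`, targets the rest.
#'
#' @param A_bar normalized adjacency from [normalize_adjacency()].
#' @param X_tilde node feature matrix.
#' @param params encoder weights from [init_encoder()].
#' @return Embedding matrix `Z`, `(m+n) x k`.
#' @export
gcn_encode <- function(A_bar, X_tilde, params) {
  .gcn_forward(A_bar %*% X_tilde, A_bar, params)$Z
}

# forward pass with cache; AX = A_bar %*% X_tilde precomputed
.gcn_forward <- function(AX, A_bar, params) {
  U1 <- AX %*% params$W1
  H <- .sigmoid(U1)
  AH <- A_bar %*% H
  Z <- tanh(AH %*% params$W2)
  list(Z = Z, H = H, AH = AH)
}

# gradient of the loss wrt W1/W2 given dL/dZ
.gcn_backward <- function(dZ, cache, AX, A_bar, params) {
  dU2 <- dZ * (1 - cache$Z^2)
  gW2 <- crossprod(cache$AH, dU2)
  dH <- A_bar %*% tcrossprod(dU2, params$W2)
  dU1 <- dH * cache$H * (1 - cache$H)
  gW1 <- crossprod(AX, dU1)
  list(W1 = gW1, W2 = gW2)
}

#' Inner-product decoder
#'
#' Reconstructs edge propensities from embeddings:
#' `A_hat(i, j) = sigmoid(z_i . z_j)`. Symmetric with entries in (0, 1).
#'
#' @param Z embedding matrix.
#' @return Reconstructed adjacency `A_hat`.
#' @export
decode_embeddings <- function(Z) {
  .sigmoid(tcrossprod(Z))
}

#' Adjacency reconstruction loss
#'
#' Sum of squared entrywise differences between the heterogeneous
#' network adjacency and its reconstruction.
#'
#' @param A_tilde block adjacency.
#' @param A_hat decoded propensities, same shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(A_tilde, A_hat) {
  stopifnot(identical(dim(A_tilde), dim(A_hat)))
  sum((A_tilde - A_hat)^2)
}

#' Binary cross-entropy
#'
#' `-(y log p + (1 - y) log(1 - p))` with `p` clamped to
#' `[1e-7, 1 - 1e-7]` so the value is always finite.
#'
#' @param p predicted probabilities in [0, 1].
#' @param y labels in \{0, 1\}.
#' @return Elementwise loss, same length as `p`.
#' @export
bce_loss <- function(p, y) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Initialise the discriminator
#'
#' A small feed-forward network `k -> 64 -> 32 -> 1` with rectified
#' hidden activations and a sigmoid output head mapping an embedding
#' vector to the probability that it was drawn from the Gaussian
#' reference.
#'
#' @param embed_dim input (embedding) dimension k.
#' @param hidden widths of the two hidden layers.
#' @return List of weight matrices/bias vectors of class
#'   `sdgae_discriminator`.
#' @export
init_discriminator <- function(embed_dim, hidden = c(64L, 32L)) {
  structure(list(
    W1 = .glorot(embed_dim, hidden[1]), b1 = numeric(hidden[1]),
    W2 = .glorot(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
    W3 = .glorot(hidden[2], 1L), b3 = numeric(1L)
  ), class = "sdgae_discriminator")
}

# forward with cache; X is a batch of row vectors
.disc_forward <- function(D, X) {
  U1 <- sweep(X %*% D$W1, 2, D$b1, "+")
  H1 <- pmax(U1, 0)
  U2 <- sweep(H1 %*% D$W2, 2, D$b2, "+")
  H2 <- pmax(U2, 0)
  U3 <- drop(H2 %*% D$W3) + D$b3
  list(p = .sigmoid(U3), U1 = U1, H1 = H1, U2 = U2, H2 = H2)
}

# mean-BCE gradient wrt discriminator params and input, for labels y
.disc_backward <- function(D, X, cache, y, n_total) {
  dU3 <- (cache$p - y) / n_total
  gW3 <- crossprod(cache$H2, dU3)
  gb3 <- sum(dU3)
  dH2 <- matrix(dU3, ncol = 1) %*% t(D$W3)
  dU2 <- dH2 * (cache$U2 > 0)
  gW2 <- crossprod(cache$H1, dU2)
  gb2 <- colSums(dU2)
  dH1 <- tcrossprod(dU2, D$W2)
  dU1 <- dH1 * (cache$U1 > 0)
  gW1 <- crossprod(X, dU1)
  gb1 <- colSums(dU1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       dX = tcrossprod(dU1, D$W1))
}

#' Predict with the discriminator
#'
#' @param object an `sdgae_discriminator`.
#' @param newdata matrix of embedding row vectors.
#' @param ... unused.
#' @return Vector of probabilities in (0, 1).
#' @export
predict.sdgae_discriminator <- function(object, newdata, ...) {
  .disc_forward(object, as.matrix(newdata))$p
}

#' Discriminator loss
#'
#' Mean binary cross-entropy of the discriminator on encoder embeddings
#' (label 0, "fake") plus on Gaussian reference samples (label 1,
#' "real"), each averaged over the m + n nodes.
#'
#' @param D an `sdgae_discriminator` or a function mapping a matrix of
#'   row vectors to probabilities.
#' @param Z embedding matrix (fake batch).
#' @param Z_prime Gaussian reference matrix, same shape (real batch).
#' @return Scalar loss.
#' @export
discriminator_loss <- function(D, Z, Z_prime) {
  f <- if (is.function(D)) D else function(X) .disc_forward(D, X)$p
  mean(bce_loss(f(Z), 0)) + mean(bce_loss(f(Z_prime), 1))
}

#' Generator loss
#'
#' Mean binary cross-entropy of the discriminator on encoder embeddings
#' scored against label 1 — small when the encoder fools the
#' discriminator.
#'
#' @inheritParams discriminator_loss
#' @return Scalar loss.
#' @export
generator_loss <- function(D, Z) {
  f <- if (is.function(D)) D else function(X) .disc_forward(D, X)$p
  mean(bce_loss(f(Z), 1))
}

# Adam optimiser state kept in an environment; params is a named list of
# arrays, grads matches its names.
.adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st
}

.adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$b1 * st$m[[nm]] + (1 - st$b1) * g
    st$v[[nm]] <- st$b2 * st$v[[nm]] + (1 - st$b2) * g^2
    params[[nm]] <- params[[nm]] -
      st$lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
  }
  params
}

# encoder-loss gradient wrt Z (reconstruction + optional SCC blocks)
.encoding_dZ <- function(Z, A_hat, A_tilde, scc, control, m) {
  G <- 2 * (A_hat - A_tilde) * A_hat * (1 - A_hat)
  dZ <- (G + t(G)) %*% Z
  if (control$use_scc && !is.null(scc)) {
    di <- seq_len(m)
    ti <- (m + 1):nrow(Z)
    dZ[di, ] <- dZ[di, ] + 2 * control$lambda_l * Z[di, , drop = FALSE] +
      4 * control$lambda_d * (scc$L_drug %*% Z[di, , drop = FALSE])
    dZ[ti, ] <- dZ[ti, ] + 2 * control$lambda_l * Z[ti, , drop = FALSE] +
      4 * control$lambda_t * (scc$L_target %*% Z[ti, , drop = FALSE])
  }
  dZ
}

# scalar encoder loss for a given forward pass
.encoding_loss <- function(Z, A_tilde, scc, control, m) {
  rec <- reconstruction_loss(A_tilde, decode_embeddings(Z))
  sc <- if (control$use_scc && !is.null(scc))
    scc_loss(Z[seq_len(m), , drop = FALSE],
             Z[(m + 1):nrow(Z), , drop = FALSE], scc,
             control$lambda_l, control$lambda_d, control$lambda_t)
  else 0
  c(rec = rec, scc = sc, enc = rec + sc)
}

#' Train drug/target embeddings
#'
#' Optimises the graph convolutional autoencoder with Adam for
#' `control$epochs` full-batch epochs. Each epoch runs, in order: a
#' discriminator step on fresh standard-normal reference samples (when
#' `control$use_gan`), an encoder step on the encoding loss
#' (reconstruction + spatial consistency), and a generator step pushing
#' the embeddings towards the Gaussian reference (when `use_gan`). All
#' randomness (weight initialisation, reference sampling) comes from
#' `seed`, so runs repeat exactly.
#'
#' @param graph a `hetero_graph` from [build_heterograph()].
#' @param scc a `sparse_similarity` from [build_scc()], or `NULL` when
#'   `control$use_scc` is off.
#' @param control an [sdgae_control()].
#' @param seed integer seed; defaults to `control$seed`.
#' @param trace_every record losses every this many epochs (first and
#'   last epoch always recorded).
#' @return List of class `sdgae_embedding` with `Z`, `Z_drug`,
#'   `Z_target`, encoder `params`, the `discriminator` (or `NULL`) and a
#'   data frame `trace` of per-epoch losses (`epoch`, `L_reconstitution`,
#'   `L_spatial_consistency`, `L_encoding`, `L_D`, `L_G`).
#' @export
train_embeddings <- function(graph, scc = NULL,
                             control = sdgae_control(),
                             seed = control$seed, trace_every = 1L) {
  if (control$use_scc && is.null(scc))
    stop("train_embeddings: control$use_scc is on but no scc supplied")
  set.seed(seed)
  nn <- nrow(graph$A_bar)
  m <- graph$m
  k <- control$embed_dim
  params <- init_encoder(nn, control$hidden_dim, k)
  D <- if (control$use_gan) init_discriminator(k) else NULL
  opt_enc <- .adam_new(params, control$lr_repr)
  opt_disc <- if (control$use_gan) .adam_new(unclass(D), control$lr_repr)
  AX <- graph$A_bar %*% graph$X_tilde
  rec_rows <- unique(c(seq(1L, control$epochs, by = trace_every),
                       control$epochs))
  trace <- data.frame(epoch = rec_rows, L_reconstitution = NA_real_,
                      L_spatial_consistency = NA_real_,
                      L_encoding = NA_real_, L_D = NA_real_,
                      L_G = NA_real_)
  ti <- 1L
  for (epoch in seq_len(control$epochs)) {
    L_D <- NA_real_; L_G <- NA_real_
    if (control$use_gan) {
      # discriminator step: fresh Gaussian reference, detached Z
      fw <- .gcn_forward(AX, graph$A_bar, params)
      Zp <- matrix(stats::rnorm(nn * k), nn, k)
      cf <- .disc_forward(D, fw$Z)
      cr <- .disc_forward(D, Zp)
      L_D <- mean(bce_loss(cf$p, 0)) + mean(bce_loss(cr$p, 1))
      gf <- .disc_backward(D, fw$Z, cf, 0, nn)$grads
      gr <- .disc_backward(D, Zp, cr, 1, nn)$grads
      g <- Map(`+`, gf, gr)
      Dn <- .adam_step(opt_disc, unclass(D), g)
      D <- structure(Dn, class = "sdgae_discriminator")
    }
    # encoder step on L_encoding
    fw <- .gcn_forward(AX, graph$A_bar, params)
    A_hat <- decode_embeddings(fw$Z)
    losses <- .encoding_loss(fw$Z, graph$A_tilde, scc, control, m)
    if (!all(is.finite(losses)))
      stop("train_embeddings: non-finite encoding loss at epoch ", epoch)
    dZ <- .encoding_dZ(fw$Z, A_hat, graph$A_tilde, scc, control, m)
    grads <- .gcn_backward(dZ, fw, AX, graph$A_bar, params)
    params <- .adam_step(opt_enc, params, grads)
    if (control$use_gan) {
      # generator step: L_G gradient through the encoder
      fw <- .gcn_forward(AX, graph$A_bar, params)
      cg <- .disc_forward(D, fw$Z)
      L_G <- mean(bce_loss(cg$p, 1))
      dZ_g <- .disc_backward(D, fw$Z, cg, 1, nn)$dX
      grads <- .gcn_backward(dZ_g, fw, AX, graph$A_bar, params)
      params <- .adam_step(opt_enc, params, grads)
    }
    if (ti <= length(rec_rows) && epoch == rec_rows[ti]) {
      trace[ti, -1] <- c(losses[["rec"]], losses[["scc"]],
                         losses[["enc"]], L_D, L_G)
      ti <- ti + 1L
    }
  }
  Z <- .gcn_forward(AX, graph$A_bar, params)$Z
  structure(list(Z = Z, Z_drug = Z[seq_len(m), , drop = FALSE],
                 Z_target = Z[(m + 1):nn, , drop = FALSE],
                 params = params, discriminator = D, trace = trace,
                 seed = seed),
            class = "sdgae_embedding")
}
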