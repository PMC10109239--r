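sig <- function(x) 1 / (1 + exp(-x))

# small random graph + features for encoder tests
enc_fixture <- function(seed = 1, nn = 6, l = 4, k = 3) {
  set.seed(seed)
  A <- matrix(rbinom(nn * nn, 1, 0.4), nn, nn)
  A <- (A + t(A) > 0) * 1; diag(A) <- 0
  list(A_tilde = A, A_bar = normalize_adjacency(A),
       X = random_similarity(nn),
       params = init_encoder(nn, l, k))
}

test_that("the encoder forward pass matches step-by-step dense arithmetic", {
  fx <- enc_fixture()
  Z <- gcn_encode(fx$A_bar, fx$X, fx$params)
  H <- sig(fx$A_bar %*% fx$X %*% fx$params$W1)
  Z_ref <- tanh(fx$A_bar %*% H %*% fx$params$W2)
  expect_equal(Z, Z_ref, tolerance = 1e-10)
  expect_lt(max(abs(Z)), 1)             # tanh range
  # zero output weights collapse the embedding
  fx$params$W2[] <- 0
  expect_equal(gcn_encode(fx$A_bar, fx$X, fx$params),
               matrix(0, 6, 3))
})

test_that("the inner-product decoder is symmetric with sigmoid-scaled entries", {
  Z <- rbind(c(1, 0), c(0, 1), c(1, 1))
  A_hat <- decode_embeddings(Z)
  expect_equal(A_hat[1, 2], 0.5)        # orthogonal rows
  expect_equal(A_hat[3, 3], sig(2))
  expect_symmetric(A_hat)
  Z2 <- rbind(c(2, 0), c(2, 0))
  expect_equal(decode_embeddings(Z2)[1, 2], sig(4))
})

test_that("reconstruction loss is a plain sum of squared differences", {
  fx <- enc_fixture(2)
  A_hat <- decode_embeddings(gcn_encode(fx$A_bar, fx$X, fx$params))
  expect_equal(reconstruction_loss(A_hat, A_hat), 0)
  bumped <- A_hat; bumped[2, 3] <- bumped[2, 3] + 0.5
  expect_equal(reconstruction_loss(A_hat, bumped), 0.25)
  acc <- 0
  for (i in 1:6) for (j in 1:6) acc <- acc + (fx$A_tilde[i, j] - A_hat[i, j])^2
  expect_equal(reconstruction_loss(fx$A_tilde, A_hat), acc,
               tolerance = 1e-12)
})

test_that("binary cross-entropy has the closed-form values and finite clamps", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_true(is.finite(bce_loss(0, 1)))
  expect_equal(bce_loss(0, 1), -log(1e-7))
})

test_that("adversarial losses match their closed forms and elementwise oracles", {
  nn <- 10; k <- 4
  Z <- matrix(rnorm(nn * k), nn, k)
  Zp <- matrix(rnorm(nn * k), nn, k)
  blind <- function(X) rep(0.5, nrow(X))
  expect_equal(discriminator_loss(blind, Z, Zp), 2 * log(2))
  expect_equal(generator_loss(blind, Z), log(2))
  perfect <- function(X) rep(1e-7, nrow(X))
  fooled <- function(X) rep(1 - 1e-7, nrow(X))
  expect_lt(abs(discriminator_loss(function(X)
    if (identical(X, Zp)) fooled(X) else perfect(X), Z, Zp)), 1e-5)
  expect_lt(generator_loss(fooled, Z), 1e-6)
  # against a real discriminator: elementwise oracle
  set.seed(3)
  D <- init_discriminator(k)
  p_f <- predict(D, Z); p_r <- predict(D, Zp)
  expect_equal(discriminator_loss(D, Z, Zp),
               mean(-log(1 - pmin(pmax(p_f, 1e-7), 1 - 1e-7))) +
                 mean(-log(pmin(pmax(p_r, 1e-7), 1 - 1e-7))),
               tolerance = 1e-12)
  expect_equal(generator_loss(D, Z),
               mean(-log(pmin(pmax(p_f, 1e-7), 1 - 1e-7))),
               tolerance = 1e-12)
  expect_true(all(p_f > 0 & p_f < 1))
})

test_that("backpropagated encoder gradients match finite differences", {
  fx <- enc_fixture(4)
  m <- 3                                 # treat first 3 nodes as drugs
  ctrl <- cheap_control()
  fused <- list(S_drug = fx$X[1:3, 1:3], S_target = fx$X[4:6, 4:6])
  diag(fused$S_drug) <- 1; diag(fused$S_target) <- 1
  scc <- build_scc(fused, p = 2)
  loss_at <- function(params) {
    Z <- gcn_encode(fx$A_bar, fx$X, params)
    reconstruction_loss(fx$A_tilde, decode_embeddings(Z)) +
      scc_loss(Z[1:3, ], Z[4:6, ], scc, ctrl$lambda_l, ctrl$lambda_d,
               ctrl$lambda_t)
  }
  AX <- fx$A_bar %*% fx$X
  fw <- sdgae:::.gcn_forward(AX, fx$A_bar, fx$params)
  dZ <- sdgae:::.encoding_dZ(fw$Z, decode_embeddings(fw$Z), fx$A_tilde,
                             scc, ctrl, m)
  grads <- sdgae:::.gcn_backward(dZ, fw, AX, fx$A_bar, fx$params)
  eps <- 1e-6
  for (nm in c("W1", "W2")) {
    for (idx in list(c(1, 1), c(2, 3), c(3, 2))) {
      pp <- fx$params; pp[[nm]][idx[1], idx[2]] <- pp[[nm]][idx[1], idx[2]] + eps
      pm <- fx$params; pm[[nm]][idx[1], idx[2]] <- pm[[nm]][idx[1], idx[2]] - eps
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[nm]][idx[1], idx[2]], fd, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic, bookkeeps its losses, and descends", {
  ds <- small_synth(seed = 9)
  fused <- build_fused_similarity(ds)
  ctrl <- cheap_control(epochs = 60L)
  graph <- build_heterograph(ds, fused, control = ctrl)
  scc <- build_scc(fused, ctrl$p)
  emb1 <- train_embeddings(graph, scc, ctrl, seed = 11)
  emb2 <- train_embeddings(graph, scc, ctrl, seed = 11)
  expect_identical(emb1$Z, emb2$Z)
  # loss bookkeeping at every logged epoch
  tr <- emb1$trace
  expect_equal(tr$L_encoding,
               tr$L_reconstitution + tr$L_spatial_consistency)
  expect_lt(tr$L_encoding[nrow(tr)], tr$L_encoding[1])
  expect_lt(max(abs(emb1$Z)), 1)
  expect_identical(dim(emb1$Z_drug), c(20L, ctrl$embed_dim))
  expect_identical(dim(emb1$Z_target), c(24L, ctrl$embed_dim))
})

test_that("disabling the spatial-consistency term zeroes its logged loss", {
  ds <- small_synth(seed = 10)
  fused <- build_fused_similarity(ds)
  ctrl <- cheap_control(use_scc = FALSE, use_gan = FALSE, epochs = 25L)
  graph <- build_heterograph(ds, fused, control = ctrl)
  emb <- train_embeddings(graph, NULL, ctrl, seed = 2)
  tr <- emb$trace
  expect_true(all(tr$L_spatial_consistency == 0))
  expect_equal(tr$L_encoding, tr$L_reconstitution)
  expect_true(all(is.na(tr$L_D)))
  # without the adversarial pair, a re-run is a pure deterministic descent
  emb2 <- train_embeddings(graph, NULL, ctrl, seed = 2)
  expect_equal(emb$Z, emb2$Z, tolerance = 1e-10)
})
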