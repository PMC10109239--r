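# Shared fixtures: all built in code, sized for speed.

# tiny hand-buildable dataset (3 drugs x 2 targets)
tiny_dataset <- function() {
  dti_dataset(
    drug_ids = c("d1", "d2", "d3"),
    target_ids = c("t1", "t2"),
    Y = matrix(c(1, 0, 0, 0, 1, 0), nrow = 3),
    A_drug = matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3),
    A_target = matrix(0, 2, 2),
    B_drug_disease = matrix(c(1, 1, 0, 0, 1, 1), 3, 2),
    B_drug_sideeffect = matrix(c(1, 0, 0, 0, 1, 0), 3, 2),
    B_target_disease = matrix(c(1, 0, 0, 1), 2, 2),
    S_chemical = {
      S <- matrix(0.2, 3, 3); S[1, 2] <- S[2, 1] <- 0.9; diag(S) <- 1; S
    },
    S_sequence = {
      S <- matrix(0.3, 2, 2); diag(S) <- 1; S
    }
  )
}

# small clustered dataset for mid-weight tests
small_synth <- function(seed = 1, m = 20, n = 24, c = 2, ...) {
  synthetic_dti_dataset(synth_config(m = m, n = n, c = c, seed = seed, ...))
}

# cheap training control: enough epochs to move, fast enough to loop
cheap_control <- function(...) {
  args <- utils::modifyList(
    list(profile = "desk", epochs = 40L, n_rounds = 30L,
         n_folds = 4L, seed = 1L),
    list(...))
  do.call(sdgae_control, args)
}

# random similarity matrix: symmetric, unit diagonal, entries in [0,1]
random_similarity <- function(nn) {
  S <- matrix(stats::runif(nn * nn), nn, nn)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
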