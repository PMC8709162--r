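# Shared fixtures, all generated in code.

# random symmetric binary adjacency with unit diagonal (connected not
# required; used where connectivity is irrelevant)
random_adjacency <- function(M, p = 0.6) {
  A <- matrix(0, M, M)
  A[upper.tri(A)] <- as.numeric(runif(M * (M - 1) / 2) < p)
  A <- A + t(A)
  diag(A) <- 1
  A
}

# random row-stochastic weight matrix conforming to A, built without the
# package's chromosome code (independent of the operators under test)
random_feasible_weights <- function(A) {
  M <- nrow(A)
  W <- matrix(0, M, M)
  for (i in seq_len(M)) {
    nb <- which(A[i, ] == 1)
    w <- runif(length(nb))
    W[i, nb] <- w / sum(w)
  }
  W
}

# a noiseless ordinal panel generated from known weights on a full graph
make_noiseless_panel <- function(M = 3, n = 30, T_steps = 6) {
  A <- matrix(1, M, M)
  W <- generate_weight_matrix(A)
  x0 <- runif(M)
  X <- simulate_opinions(W, x0, T_steps - 1)
  sc <- ordinal_scale(n)
  scores <- matrix(back_transform(X, sc), M)
  list(panel = opinion_panel(scores, sc, A), W = W, x0 = x0, latent = X)
}

expect_feasible <- function(W, A, tol = 1e-9) {
  expect_true(all(W >= 0) && all(W <= 1))
  expect_true(all(abs(rowSums(W) - 1) <= tol))
  expect_true(all(W[A == 0] == 0))
}
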