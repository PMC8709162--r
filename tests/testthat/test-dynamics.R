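test_that("a DeGroot step is the weighted average of current opinions", {
  W <- diag(3)
  x <- c(0.2, 0.5, 0.9)
  expect_equal(degroot_step(W, x), x)
  expect_equal(degroot_step(matrix(0.5, 2, 2), c(0, 1)), c(0.5, 0.5))
  set.seed(2)
  Wr <- random_feasible_weights(random_adjacency(5))
  expect_equal(degroot_step(Wr, rep(0.37, 5)), rep(0.37, 5))  # consensus fixed
  expect_error(degroot_step(W, c(0.1, 0.2)), "dimension")
})

test_that("bounded-confidence mask zeroes far pairs and renormalises", {
  W <- matrix(0.5, 2, 2)
  x <- c(0.1, 0.9)
  expect_identical(bounded_confidence_mask(W, x, delta = 1), W)
  expect_equal(bounded_confidence_mask(W, x, delta = 0.5), diag(2))
  # strict inequality: a difference exactly at the threshold keeps the link
  expect_identical(bounded_confidence_mask(W, x, delta = 0.8), W)
  set.seed(3)
  for (rep in 1:20) {
    A <- random_adjacency(5)
    Wr <- random_feasible_weights(A)
    xr <- runif(5)
    Wt <- bounded_confidence_mask(Wr, xr, delta = 0.3)
    expect_equal(rowSums(Wt), rep(1, 5), tolerance = 1e-9)
    expect_true(all(Wt[A == 0] == 0))
    expect_equal(diag(Wt) == 0, diag(Wr) == 0)  # self-weights never removed
  }
  # an agent with zero self-weight cut off from everyone keeps its opinion
  W0 <- matrix(c(0, 1, 0.5, 0.5), 2, 2, byrow = TRUE)
  Wt <- bounded_confidence_mask(W0, c(0.05, 0.95), delta = 0.5)
  expect_equal(Wt[1, ], c(1, 0))
})

test_that("decay factor is lambda^t with a full-weight first step", {
  expect_equal(decay_factor(0.5, 0), 1)
  expect_equal(decay_factor(1, 17), 1)
  expect_equal(decay_factor(0.5, 3), 0.125)
  expect_error(decay_factor(0.5, -1), "non-negative")
})

test_that("model step composes mask then decay and reduces to DeGroot", {
  set.seed(4)
  A <- random_adjacency(6)
  W <- random_feasible_weights(A)
  x <- runif(6)
  plain <- degroot_step(W, x)
  expect_identical(model_step(W, x, t = 3, degroot_dynamics(1, 1)), plain)
  expect_identical(model_step(W, x, t = 0, degroot_dynamics(1, 0.4)), plain)
  # closed form with delta = 1: (1 - lambda^t) x + lambda^t W x
  lam_t <- 0.6^2
  expect_equal(model_step(W, x, t = 2, degroot_dynamics(1, 0.6)),
               (1 - lam_t) * x + lam_t * plain)
})

test_that("simulated trajectories stay in [0,1] and contract under DeGroot", {
  set.seed(5)
  for (rep in 1:10) {
    A <- random_adjacency(6)
    W <- random_feasible_weights(A)
    x0 <- runif(6)
    dyn <- degroot_dynamics(delta = sample(c(0.3, 0.8, 1), 1),
                            lambda = sample(c(0.2, 0.7, 1), 1))
    X <- simulate_opinions(W, x0, 15, dyn)
    expect_true(all(X >= 0 & X <= 1))
    expect_equal(X[, 1], x0)
  }
  # plain DeGroot: opinion spread is non-increasing
  W <- random_feasible_weights(matrix(1, 5, 5))
  X <- simulate_opinions(W, runif(5), 20)
  spread <- apply(X, 2, function(v) max(v) - min(v))
  expect_true(all(diff(spread) <= 1e-12))
})

test_that("trajectories match a brute-force product loop", {
  expect_error(simulate_opinions(diag(2), c(0.1, 0.2), 0), "at least 1")
  set.seed(6)
  for (rep in 1:10) {
    W <- random_feasible_weights(random_adjacency(4))
    x0 <- runif(4)
    X <- simulate_opinions(W, x0, 8)
    x <- x0
    for (t in 1:8) {
      x <- pmin(pmax(drop(W %*% x), 0), 1)
      expect_identical(X[, t + 1], x)
    }
  }
  X <- simulate_opinions(diag(3), c(0.1, 0.5, 0.9), 20)
  expect_true(all(X == c(0.1, 0.5, 0.9)))
})

test_that("adjacency and weight validators enforce the invariants", {
  A <- random_adjacency(4)
  expect_silent(validate_adjacency(A))
  bad <- A; bad[1, 2] <- 1; bad[2, 1] <- 0
  expect_error(validate_adjacency(bad), "symmetric")
  bad <- A; diag(bad) <- 0
  expect_error(validate_adjacency(bad), "diagonal")
  W <- random_feasible_weights(A)
  expect_silent(validate_weights(W, A))
  expect_error(validate_weights(W * 0.9, A), "sum to 1")
  if (any(A == 0)) {
    W4 <- W; idx <- which(A == 0)[1]
    W4[idx] <- 0.1; W4 <- W4 / rowSums(W4)
    expect_error(validate_weights(W4, A), "structurally zero")
  }
})
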