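test_that("modeled trajectories step through unobserved gaps", {
  set.seed(41)
  fx <- make_noiseless_panel(M = 4, n = 10, T_steps = 4)
  # identity weights freeze the initial opinions
  pid <- opinion_panel(fx$panel$scores, fx$panel$scale, fx$panel$adjacency)
  Xid <- modeled_trajectory(diag(4), pid)
  expect_true(all(Xid == Xid[, 1]))
  # observed steps (0, 3): columns t0..t3 exist, t1 and t2 are simulated
  gap <- opinion_panel(fx$panel$scores[, c(1, 4)], fx$panel$scale,
                       fx$panel$adjacency, observed_steps = c(0, 3))
  X <- modeled_trajectory(fx$W, gap)
  expect_identical(colnames(X), c("t0", "t1", "t2", "t3"))
  # matches a brute-force product loop from the mid-bin initial opinions
  x <- forward_transform(gap$scores[, 1], gap$scale)
  for (t in 1:3) x <- pmin(pmax(drop(fx$W %*% x), 0), 1)
  expect_equal(unname(X[, 4]), unname(x))
})

test_that("the objective gates continuous error by bin deviation", {
  set.seed(42)
  fx <- make_noiseless_panel(M = 3, n = 30, T_steps = 6)
  expect_equal(objective_value(fx$W, fx$panel), 0)
  # single stubborn agent modeled at 0.5 against observed level 5 of 5:
  # bin deviation 2, continuous gap 0.4
  A1 <- matrix(1, 1, 1)
  p1 <- opinion_panel(matrix(c(3L, 5L), 1), ordinal_scale(5), A1)
  expect_equal(objective_value(matrix(1, 1, 1), p1), 2 * 0.4)
  expect_equal(row_objective(matrix(1, 1, 1), p1, 1), 2 * 0.4)
  expect_error(row_objective(matrix(1, 1, 1), p1, 2), "out of range")
  # agent-level decomposition
  set.seed(43)
  A <- random_adjacency(5)
  W <- random_feasible_weights(A)
  sc <- ordinal_scale(7)
  scores <- matrix(sample(1:7, 20, replace = TRUE), 5)
  pan <- opinion_panel(scores, sc, A)
  expect_equal(objective_value(W, pan),
               sum(sapply(1:5, function(i) row_objective(W, pan, i))))
  # compiled objective used inside the GA agrees with the R definition
  obs <- pan$scores[, -1, drop = FALSE]
  x0 <- forward_transform(pan$scores[, 1], sc)
  expect_equal(degrootfit:::cpp_objective(W, x0, obs, 1:3, 7),
               objective_value(W, pan))
})

test_that("random chromosomes are feasible and reproducible", {
  expect_identical(random_chromosome(diag(3)), diag(3))
  set.seed(44)
  for (rep in 1:10) {
    A <- random_adjacency(sample(2:8, 1))
    expect_feasible(random_chromosome(A), A)
  }
  set.seed(45); W1 <- random_chromosome(random_adjacency(5))
  set.seed(45); W2 <- random_chromosome(random_adjacency(5))
  expect_identical(W1, W2)
})

test_that("the GA recovers a perfect ordinal fit on noiseless data", {
  set.seed(46)
  fx <- make_noiseless_panel(M = 3, n = 30, T_steps = 6)
  fit <- degroot_fit(fx$panel, seed = 1)
  expect_s3_class(fit, "degroot_fit")
  expect_equal(fit$objective, 0)
  expect_true(fit$converged)
  expect_feasible(fit$weights, fx$panel$adjacency)
  # best-so-far objective is non-increasing (elitist survival)
  expect_true(all(diff(fit$trace) <= 0))
  # same seed, same fit
  fit2 <- degroot_fit(fx$panel, seed = 1)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$objective, fit2$objective)
})

test_that("multiple restarts average to a feasible matrix", {
  set.seed(47)
  fx <- make_noiseless_panel(M = 3, n = 10, T_steps = 4)
  ctl <- ga_control(n_generations = 150)
  fit <- degroot_fit(fx$panel, control = ctl, runs = 3, seed = 9)
  expect_length(fit$runs, 3)
  expect_feasible(fit$average_weights, fx$panel$adjacency)
  expect_equal(fit$objective,
               min(vapply(fit$runs, `[[`, numeric(1), "objective")))
  # averaging identities
  W <- fit$weights
  expect_equal(average_fits(list(W, W, W)), W)
  expect_equal(average_fits(list(diag(3), matrix(1 / 3, 3, 3))),
               (diag(3) + matrix(1 / 3, 3, 3)) / 2)
  expect_error(average_fits(list()), "no matrices")
})

test_that("fit methods expose coefficients, fit, residuals, predictions", {
  set.seed(48)
  fx <- make_noiseless_panel(M = 4, n = 20, T_steps = 4)
  fit <- degroot_fit(fx$panel, control = ga_control(n_generations = 300),
                     seed = 3)
  expect_identical(coef(fit), fit$weights)
  expect_identical(coef(fit, "average"), fit$average_weights)
  f <- fitted(fit)
  expect_identical(dim(f), dim(fx$panel$scores))
  r <- residuals(fit)
  expect_true(all(r[, 1] == 0))  # t0 reproduced exactly
  rb <- residuals(fit, type = "bins")
  expect_true(all(rb == round(rb)))
  P <- predict(fit, n_steps = 20)
  expect_identical(dim(P), c(4L, 21L))
  expect_true(all(P >= 0 & P <= 1))
  O <- predict(fit, n_steps = 5, type = "ordinal")
  expect_true(all(O >= 1 & O <= 20))
  sims <- simulate(fit, nsim = 2, n_steps = 6)
  expect_length(sims, 2)
  expect_identical(sims[[1]], sims[[2]])  # deterministic dynamics
  expect_output(print(fit), "DeGroot model fit")
  expect_output(print(summary(fit)), "objective")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("ga control validates counts and rates", {
  expect_error(ga_control(population_size = 0), "positive")
  expect_error(ga_control(mutation_rate = 1.2), "\\[0, 1\\]")
  expect_error(ga_control(mutation_sd = 0), "positive")
})

test_that("panels validate their scores, steps, and adjacency", {
  A <- matrix(1, 2, 2)
  expect_error(opinion_panel(matrix(c(1L, 6L, 2L, 3L), 2), 5, A), "1..5")
  expect_error(opinion_panel(matrix(1L, 2, 2), 5, A,
                             observed_steps = c(1, 2)), "t = 0")
  expect_error(opinion_panel(matrix(c(1L, NA, 2L, 3L), 2), 5, A), "missing")
  expect_error(opinion_panel(matrix(1L, 3, 2), 5, A), "match")
  p <- opinion_panel(matrix(c(1L, 2L, 3L, 4L), 2), 5, A,
                     observed_steps = c(0, 3))
  expect_identical(colnames(p$scores), c("t0", "t3"))
  expect_output(print(p), "observed steps t0, t3")
})
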