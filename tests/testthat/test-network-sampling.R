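test_that("ER generator hits the target degree and rejects bad inputs", {
  set.seed(21)
  A <- generate_er_network(10, 9)
  expect_true(all(A == 1))  # link probability 1 gives the complete graph
  expect_error(generate_er_network(10, 9.5), "target degree")
  set.seed(7); A1 <- generate_er_network(10, 5)
  set.seed(7); A2 <- generate_er_network(10, 5)
  expect_identical(A1, A2)
  expect_silent(validate_adjacency(A1))
  # mean off-diagonal degree near the target over repeated accepted draws
  set.seed(22)
  degs <- replicate(200, {
    A <- generate_er_network(30, 5)
    mean(rowSums(A) - 1)
  })
  expect_equal(mean(degs), 5, tolerance = 0.05)
})

test_that("weight generator draws Beta self-weights over true neighbours", {
  expect_identical(generate_weight_matrix(diag(4)), diag(4))
  set.seed(23)
  for (spread in c("uniform", "dirichlet")) {
    A <- generate_er_network(12, 5)
    W <- generate_weight_matrix(A, spread = spread)
    expect_feasible(W, A)
  }
  # empirical mean self-weight matches the Beta(2, 2) mean of 0.5
  set.seed(24)
  selfs <- unlist(replicate(250, {
    A <- generate_er_network(40, 8)
    diag(generate_weight_matrix(A))
  }, simplify = FALSE))
  expect_gte(length(selfs), 1e4)
  expect_equal(mean(selfs), 0.5, tolerance = 0.01)
  expect_equal(var(selfs), 0.05, tolerance = 0.05)  # Beta(2,2) variance 1/20
})

test_that("initial opinions are reproducible Uniform(0,1) draws", {
  set.seed(25); a <- generate_initial_opinions(50)
  set.seed(25); b <- generate_initial_opinions(50)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  set.seed(26)
  big <- generate_initial_opinions(1e5)
  expect_equal(mean(big), 0.5, tolerance = 0.01)
  expect_equal(var(big), 1 / 12, tolerance = 0.005)
})

# independent reference implementation of the recruitment procedure,
# consuming randomness in the documented order
reference_snowball <- function(A, p) {
  N <- nrow(A)
  deg <- rowSums(A) - 1
  top <- which(deg == max(deg))
  seed <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
  tried <- rep(FALSE, N); tried[seed] <- TRUE
  sampled <- seed; wave <- 0L
  for (w in 1:2) {
    recruiters <- sampled[wave == w - 1]
    for (r in recruiters) {
      for (ag in sort(which(A[r, ] == 1))) {
        if (ag == r || tried[ag]) next
        tried[ag] <- TRUE
        if (runif(1) < p || p == 1) {
          sampled <- c(sampled, ag)
          wave <- c(wave, w)
        }
      }
    }
  }
  list(sampled = sampled, wave = wave, seed = seed)
}

test_that("snowball sampling follows the two-wave recruitment contract", {
  set.seed(27)
  # star graph: centre is the seed and everyone is wave 1
  star <- diag(6); star[1, 2:6] <- 1; star[2:6, 1] <- 1
  s <- snowball_sample(star, p = 1)
  expect_identical(s$seed_id, 1L)
  expect_identical(sort(s$sampled_ids), 1:6)
  expect_true(all(s$wave[-1] == 1))
  # determinism and agreement with the reference implementation
  for (rep in 1:25) {
    A <- generate_er_network(15, 4)
    p <- sample(c(0.5, 1), 1)
    seed_val <- sample.int(1e6, 1)
    set.seed(seed_val)
    got <- tryCatch(snowball_sample(A, p),
                    degroot_rejection = function(e) NULL)
    set.seed(seed_val)
    ref <- reference_snowball(A, p)
    if (is.null(got)) {
      expect_lt(length(ref$sampled), 4)
      next
    }
    expect_identical(got$sampled_ids, as.integer(ref$sampled))
    expect_identical(unname(got$wave), ref$wave)
    # every recruit is a true-network neighbour of its recruiter
    for (k in seq_len(nrow(got$recruitment_edges))) {
      e <- got$recruitment_edges[k, ]
      expect_equal(A[e[1], e[2]], 1)
    }
  }
})

test_that("small samples are rejected with a catchable signal", {
  # a triangle can only ever yield three agents
  tri <- matrix(1, 3, 3)
  set.seed(28)
  expect_error(snowball_sample(tri, p = 1), class = "degroot_rejection")
})

test_that("adjacency varieties follow their constructions and nest", {
  # seed with three spokes plus a chain seed-a-b: a recruits b in wave 2
  A <- diag(5)
  for (e in list(c(1, 2), c(1, 3), c(1, 4), c(2, 5)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  set.seed(29)
  s <- snowball_sample(A, p = 1)
  expect_identical(s$seed_id, 1L)
  expect_identical(unname(s$wave[as.character(5)]), 2L)
  correct <- adjacency_variety(A, s, "correct")
  build <- adjacency_variety(A, s, "build")
  rmv <- adjacency_variety(A, s, "remove")
  compl <- adjacency_variety(A, s, "complete")
  # chain agent b keeps its single wave-1 link: build equals correct here
  expect_identical(build, correct)
  expect_true(all(compl == 1))
  # remove = complete minus the links the seed is known not to have
  expected_rmv <- compl
  b_pos <- which(s$sampled_ids == 5)
  expected_rmv[1, b_pos] <- expected_rmv[b_pos, 1] <- 0
  expect_identical(unname(rmv), unname(expected_rmv))
  set.seed(30)
  for (rep in 1:20) {
    A <- generate_er_network(20, 5)
    s <- tryCatch(snowball_sample(A, 0.5),
                  degroot_rejection = function(e) NULL)
    if (is.null(s)) next
    correct <- adjacency_variety(A, s, "correct")
    build <- adjacency_variety(A, s, "build")
    rmv <- adjacency_variety(A, s, "remove")
    compl <- adjacency_variety(A, s, "complete")
    expect_true(all(build <= correct))
    expect_true(all(correct <= rmv))
    expect_true(all(rmv <= compl))
    for (V in list(correct, build, rmv, compl)) {
      expect_true(all(diag(V) == 1))
      expect_true(all(V == t(V)))
    }
    # seed-wave-1 links survive in build
    w1 <- which(s$wave == 1)
    expect_true(all(build[1, w1] == correct[1, w1]))
    # the seed's unknown links stay absent in remove
    expect_identical(rmv[1, ], correct[1, ])
  }
})

test_that("with p = 1 the correct variety of a 2-hop-complete net is full", {
  set.seed(31)
  A <- generate_er_network(8, 7)  # complete graph: diameter 1
  s <- snowball_sample(A, p = 1)
  expect_identical(length(s$sampled_ids), 8L)
  correct <- adjacency_variety(A, s, "correct")
  expect_true(all(correct == 1))
})
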