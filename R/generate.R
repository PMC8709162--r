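#' Generate a connected Erdős–Rényi network
#'
#' Links each off-diagonal pair independently with probability
#' `d / (N - 1)`, so the expected degree is the target degree `d`, and
#' rejects draws until the graph is connected (which also guarantees
#' minimum degree 1 for `N > 1`). Self-links are added on the diagonal.
#' Networks generated this way stand in for the small, dense clusters that
#' snowball recruitment reaches in practice.
#'
#' Uses the current R random stream; call `set.seed()` for reproducibility.
#'
#' @param N Number of agents.
#' @param d Target mean degree, `1 <= d <= N - 1`.
#' @param max_tries Attempts before giving up with an error.
#' @return An `N x N` binary adjacency matrix with unit diagonal.
#' @export
generate_er_network <- function(N, d, max_tries = 1000) {
  if (N < 2) stop("`N` must be at least 2", call. = FALSE)
  if (d < 1 || d > N - 1)
    stop("target degree `d` must lie in [1, N - 1]", call. = FALSE)
  p <- d / (N - 1)
  for (try in seq_len(max_tries)) {
    A <- matrix(0, N, N)
    n_pairs <- N * (N - 1) / 2
    A[upper.tri(A)] <- as.numeric(runif(n_pairs) < p)
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::is_connected(g)) {
      diag(A) <- 1
      return(A)
    }
  }
  stop(sprintf("no connected network in %d tries (N = %d, d = %g)",
               max_tries, N, d), call. = FALSE)
}

#' Generate a random row-stochastic weight matrix on a network
#'
#' Each agent's self-weight is drawn from a Beta distribution with mean
#' `self_weight` and concentration `kappa` (\eqn{\alpha + \beta =}
#' `kappa`; the defaults give Beta(2, 2) with mean 0.5). The remaining
#' mass `1 - w_ii` is spread across the agent's true neighbours, either
#' equally (`spread = "uniform"`) or with symmetric-Dirichlet random
#' shares (`spread = "dirichlet"`). An isolated agent (self-link only)
#' gets self-weight 1.
#'
#' @param A Adjacency matrix (validated).
#' @param self_weight Target mean self-weight in (0, 1).
#' @param kappa Beta concentration \eqn{\alpha + \beta}.
#' @param spread How to split non-self mass across neighbours.
#' @return A row-stochastic weight matrix conforming to `A`.
#' @export
generate_weight_matrix <- function(A, self_weight = 0.5, kappa = 4,
                                   spread = c("uniform", "dirichlet")) {
  spread <- match.arg(spread)
  validate_adjacency(A)
  if (self_weight <= 0 || self_weight >= 1)
    stop("`self_weight` must lie in (0, 1)", call. = FALSE)
  N <- nrow(A)
  W <- matrix(0, N, N, dimnames = dimnames(A))
  alpha <- self_weight * kappa
  beta <- (1 - self_weight) * kappa
  for (i in seq_len(N)) {
    nb <- which(A[i, ] == 1 & seq_len(N) != i)
    if (length(nb) == 0L) {
      W[i, i] <- 1
      next
    }
    wii <- rbeta(1, alpha, beta)
    share <- switch(spread,
      uniform = rep(1 / length(nb), length(nb)),
      dirichlet = {
        g <- stats::rgamma(length(nb), shape = 1)
        g / sum(g)
      })
    W[i, i] <- wii
    W[i, nb] <- (1 - wii) * share
    W[i, ] <- W[i, ] / sum(W[i, ])  # exact row sum
  }
  W
}

#' Draw initial opinions
#'
#' Independent Uniform(0, 1) draws, one per agent.
#'
#' @param N Number of agents.
#' @export
generate_initial_opinions <- function(N) {
  if (N < 1) stop("`N` must be positive", call. = FALSE)
  runif(N)
}

#' Generate a full ground truth: network, weights, opinions, trajectory
#'
#' Convenience wrapper running the whole data-generating process: a
#' connected Erdős–Rényi network, a random weight matrix with the target
#' self-weight, Uniform(0,1) initial opinions, and a simulated latent
#' trajectory over `n_steps` updates under the given dynamics.
#'
#' @inheritParams generate_er_network
#' @inheritParams generate_weight_matrix
#' @param n_steps Updates to simulate past the initial state (default 20,
#'   giving time steps `t0..t20`).
#' @param dynamics A [degroot_dynamics()] specification for the
#'   data-generating process.
#' @return A list of class `degroot_truth` with elements `adjacency`,
#'   `weights`, `x0`, `trajectory`, and `dynamics`.
#' @export
generate_ground_truth <- function(N, d, self_weight = 0.5, kappa = 4,
                                  n_steps = 20,
                                  dynamics = degroot_dynamics(),
                                  spread = "uniform", max_tries = 1000) {
  A <- generate_er_network(N, d, max_tries = max_tries)
  W <- generate_weight_matrix(A, self_weight, kappa, spread = spread)
  x0 <- generate_initial_opinions(N)
  X <- simulate_opinions(W, x0, n_steps, dynamics)
  structure(list(adjacency = A, weights = W, x0 = x0, trajectory = X,
                 dynamics = dynamics),
            class = "degroot_truth")
}

#' @export
print.degroot_truth <- function(x, ...) {
  cat(sprintf("Ground-truth network of %d agents, %d time steps simulated\n",
              nrow(x$adjacency), ncol(x$trajectory) - 1))
  print(x$dynamics)
  invisible(x)
}
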