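#' Validate an adjacency matrix
#'
#' Adjacency matrices here are square, symmetric, binary, and carry unit
#' diagonals: an agent is always "linked" to itself so that it can weight
#' its own current opinion. Zeros force structural zeros in any conforming
#' weight matrix.
#'
#' @param A Square numeric matrix of 0/1 entries.
#' @return `A` (with a unit diagonal enforced), invisibly classed as plain
#'   matrix; errors if the invariants fail.
#' @export
validate_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (any(!(A %in% c(0, 1))))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (any(A != t(A)))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(A) != 1))
    stop("adjacency must have unit diagonal (self-links)", call. = FALSE)
  A
}

#' Validate a weight matrix against an adjacency matrix
#'
#' A weight matrix is row-stochastic — each row holds the shares of total
#' influence on one agent and sums to 1 — with entries in \eqn{[0, 1]} and
#' structural zeros wherever the adjacency matrix has no link.
#'
#' @param W Square numeric matrix.
#' @param A Optional adjacency matrix enforcing structural zeros.
#' @param tol Row-sum tolerance (default 1e-9).
#' @return `W`, invisibly; errors if the invariants fail.
#' @export
validate_weights <- function(W, A = NULL, tol = 1e-9) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("weight matrix must be square", call. = FALSE)
  if (any(W < 0) || any(W > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(W) - 1) > tol))
    stop("weight-matrix rows must sum to 1", call. = FALSE)
  if (!is.null(A) && any(W[A == 0] != 0))
    stop("weights must be structurally zero where adjacency is 0",
         call. = FALSE)
  W
}

#' Dynamics specification for opinion updates
#'
#' Bundles the bounded-confidence threshold `delta` and the decay base
#' `lambda`. With `delta = 1` and `lambda = 1` the dynamics reduce to the
#' plain DeGroot model.
#'
#' @param delta Bounded-confidence threshold \eqn{\Delta \in (0, 1]}:
#'   agents whose opinions differ by more than `delta` cannot influence
#'   each other at that step.
#' @param lambda Decay base \eqn{\lambda \in (0, 1]}: at step `t` agents
#'   place weight \eqn{\lambda^t} on the usual update and the rest on their
#'   own current opinion, so receptivity decays over time.
#' @return An object of class `degroot_dynamics`.
#' @export
degroot_dynamics <- function(delta = 1, lambda = 1) {
  stopifnot(length(delta) == 1L, length(lambda) == 1L)
  if (!is.finite(delta) || delta <= 0 || delta > 1)
    stop("`delta` must lie in (0, 1]", call. = FALSE)
  if (!is.finite(lambda) || lambda <= 0 || lambda > 1)
    stop("`lambda` must lie in (0, 1]", call. = FALSE)
  structure(list(delta = delta, lambda = lambda), class = "degroot_dynamics")
}

#' @export
print.degroot_dynamics <- function(x, ...) {
  kind <- if (x$delta == 1 && x$lambda == 1) "plain DeGroot"
          else "DeGroot with extensions"
  cat(sprintf("%s dynamics: delta = %g, lambda = %g\n", kind,
              x$delta, x$lambda))
  invisible(x)
}

#' One DeGroot update
#'
#' Each agent replaces its opinion with the weighted average of its
#' neighbours' (and its own) current opinions: \eqn{X(t+1) = W X(t)}.
#'
#' @param W Row-stochastic weight matrix.
#' @param x Numeric opinion vector in \eqn{[0,1]^N}.
#' @return Updated opinion vector; entries remain in \eqn{[0, 1]} because
#'   each is a convex combination.
#' @export
degroot_step <- function(W, x) {
  if (!is.matrix(W) || ncol(W) != length(x))
    stop("dimension mismatch between weight matrix and opinion vector",
         call. = FALSE)
  drop(W %*% x)
}

#' Bounded-confidence restriction of a weight matrix
#'
#' Zeroes the mutual weights of every agent pair whose current opinions
#' differ by strictly more than `delta`, then redistributes the removed
#' mass proportionally within each affected row, so the result is again
#' row-stochastic. Self-weights are never removed. With `delta = 1` the
#' matrix is returned unchanged (opinion differences never exceed 1).
#'
#' If a row loses its entire mass (possible only when the self-weight is
#' zero), the row falls back to the unit self-weight vector: an agent cut
#' off from everyone retains its own opinion.
#'
#' @inheritParams degroot_step
#' @param delta Threshold in (0, 1].
#' @return The time-varying weight matrix \eqn{W(t)}.
#' @export
bounded_confidence_mask <- function(W, x, delta) {
  if (delta >= 1) return(W)
  far <- abs(outer(x, x, "-")) > delta  # strict inequality; diagonal FALSE
  Wt <- W
  Wt[far] <- 0
  kept <- rowSums(Wt)
  for (i in which(kept < 1)) {
    if (kept[i] > 0) {
      Wt[i, ] <- Wt[i, ] / kept[i]
    } else {
      Wt[i, ] <- 0
      Wt[i, i] <- 1
    }
  }
  Wt
}

#' Decay factor at a time step
#'
#' The receptivity multiplier \eqn{\lambda_t = \lambda^t}; equals 1 at
#' `t = 0` for any base, so the first update is always at full weight.
#'
#' @param lambda Decay base in (0, 1].
#' @param t Non-negative integer time index.
#' @export
decay_factor <- function(lambda, t) {
  if (any(t < 0) || any(t != round(t)))
    stop("`t` must be a non-negative integer", call. = FALSE)
  lambda ^ t
}

#' One update under bounded-confidence and decay extensions
#'
#' Applies the bounded-confidence mask to `W` at the current opinions,
#' then takes a decay-damped step
#' \eqn{X(t+1) = ((1-\lambda_t) I + \lambda_t W(t)) X(t)} with
#' \eqn{\lambda_t = \lambda^t}. Reduces to [degroot_step()] when
#' `delta = 1` and `lambda = 1`.
#'
#' @inheritParams degroot_step
#' @param t Current time index (the step computes the opinions at `t + 1`).
#' @param dynamics A [degroot_dynamics()] specification.
#' @export
model_step <- function(W, x, t, dynamics = degroot_dynamics()) {
  Wt <- bounded_confidence_mask(W, x, dynamics$delta)
  lam_t <- decay_factor(dynamics$lambda, t)
  if (lam_t == 1) return(degroot_step(Wt, x))
  (1 - lam_t) * x + lam_t * degroot_step(Wt, x)
}

#' Simulate an opinion trajectory
#'
#' Iterates [model_step()] from the initial opinions, returning the full
#' trajectory with one column per time step (`t0` is the initial state).
#'
#' @inheritParams model_step
#' @param x0 Initial opinion vector in \eqn{[0,1]^N}.
#' @param n_steps Number of updates to simulate (at least 1).
#' @return An `N x (n_steps + 1)` matrix with columns named `t0`, `t1`, ...
#' @examples
#' W <- matrix(0.5, 2, 2)
#' simulate_opinions(W, c(0, 1), n_steps = 3)
#' @export
simulate_opinions <- function(W, x0, n_steps, dynamics = degroot_dynamics()) {
  if (n_steps < 1) stop("`n_steps` must be at least 1", call. = FALSE)
  if (any(x0 < 0) || any(x0 > 1))
    stop("initial opinions must lie in [0, 1]", call. = FALSE)
  N <- length(x0)
  out <- matrix(NA_real_, N, n_steps + 1,
                dimnames = list(rownames(W), paste0("t", 0:n_steps)))
  out[, 1] <- x0
  x <- x0
  for (t in 0:(n_steps - 1)) {
    x <- model_step(W, x, t, dynamics)
    # guard against representation error creeping past the unit interval
    x <- pmin(pmax(x, 0), 1)
    out[, t + 2] <- x
  }
  out
}
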