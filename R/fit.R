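#' Control parameters for the genetic algorithm
#'
#' The fitter evolves a population of candidate weight matrices
#' (chromosomes) whose genes are matrix rows — each gene is the influence
#' profile on one agent. Operators: tournament *selection* of parents,
#' per-gene convex *blending*, whole-gene *crossover*, Normal-perturbation
#' *mutation* (clipped at zero and renormalised), and elitist *survival*.
#' Every operator maps feasible chromosomes (row-stochastic, structural
#' zeros respected) to feasible chromosomes.
#'
#' @param population_size Chromosomes per generation.
#' @param n_generations Maximum generations.
#' @param tournament_size Candidates per selection tournament.
#' @param blend_rate Probability a child is blended with its second parent.
#' @param crossover_rate Probability a child undergoes row crossover.
#' @param mutation_rate Per-row mutation probability.
#' @param mutation_sd Standard deviation of the Normal perturbation.
#' @param elite_count Best individuals copied unchanged into the next
#'   generation.
#' @param tolerance Early-stop threshold on the objective (0 stops only on
#'   a perfect ordinal fit).
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(population_size = 100, n_generations = 3000,
                       tournament_size = 2, blend_rate = 0.4,
                       crossover_rate = 0.4, mutation_rate = 0.2,
                       mutation_sd = 0.1, elite_count = 1,
                       tolerance = 0) {
  ctl <- list(population_size = as.integer(population_size),
              n_generations = as.integer(n_generations),
              tournament_size = as.integer(tournament_size),
              blend_rate = blend_rate, crossover_rate = crossover_rate,
              mutation_rate = mutation_rate, mutation_sd = mutation_sd,
              elite_count = as.integer(elite_count), tolerance = tolerance)
  counts <- c("population_size", "n_generations", "tournament_size",
              "elite_count")
  if (any(unlist(ctl[counts]) < 1))
    stop("GA counts must be positive", call. = FALSE)
  rates <- c("blend_rate", "crossover_rate", "mutation_rate")
  if (any(unlist(ctl[rates]) < 0) || any(unlist(ctl[rates]) > 1))
    stop("GA rates must lie in [0, 1]", call. = FALSE)
  if (ctl$mutation_sd <= 0) stop("`mutation_sd` must be positive",
                                 call. = FALSE)
  structure(ctl, class = "ga_control")
}

#' GA operators on weight-matrix chromosomes
#'
#' Exposed mainly for inspection and testing; [degroot_fit()] applies the
#' same compiled routines internally. All three preserve feasibility:
#' rows sum to one, entries stay in \eqn{[0, 1]}, and structural zeros of
#' the adjacency are respected.
#'
#' @param W1,W2 Feasible weight matrices of equal shape.
#' @param W Feasible weight matrix.
#' @param A Adjacency matrix defining the permitted entries.
#' @param sd Mutation standard deviation.
#' @return A feasible weight matrix.
#' @name ga-operators
NULL

#' @rdname ga-operators
#' @export
ga_blend <- function(W1, W2) cpp_blend(W1, W2)

#' @rdname ga-operators
#' @export
ga_crossover <- function(W1, W2) cpp_crossover(W1, W2)

#' @rdname ga-operators
#' @export
ga_mutate <- function(W, A, sd = 0.1) cpp_mutate(W, A, sd)

#' Random feasible weight matrix on an adjacency structure
#'
#' Independent Uniform(0, 1) variates on the permitted entries of each
#' row, normalised to sum one. Used to initialise the GA population.
#'
#' @param A Adjacency matrix.
#' @return A row-stochastic weight matrix conforming to `A`.
#' @export
random_chromosome <- function(A) {
  W <- cpp_random_chromosome(validate_adjacency(A))
  dimnames(W) <- dimnames(A)
  W
}

#' Modeled opinion trajectory implied by a weight matrix
#'
#' Starting from the mid-bin (forward-transformed) initial observed
#' scores, iterates plain DeGroot updates through the last observed step —
#' including through unobserved intermediate steps, so influence can
#' travel indirectly across gaps in the observation schedule.
#'
#' @param W Weight matrix conforming to the panel's adjacency.
#' @param panel An [opinion_panel()].
#' @return An `M x (max step + 1)` matrix of continuous opinions with
#'   columns `t0`, `t1`, ...
#' @export
modeled_trajectory <- function(W, panel) {
  if (ncol(W) != nrow(panel$scores))
    stop("weight matrix size must match the panel", call. = FALSE)
  x0 <- forward_transform(panel$scores[, 1], panel$scale)
  t_max <- max(panel$observed_steps)
  if (t_max == 0L)
    return(matrix(x0, ncol = 1, dimnames = list(rownames(panel$scores), "t0")))
  out <- simulate_opinions(W, x0, t_max)
  rownames(out) <- rownames(panel$scores)
  out
}

#' Bin-gated fitting objective
#'
#' The quantity the GA minimises: over every agent and every observed
#' step past the initial one, the continuous deviation between modeled
#' and observed opinion, multiplied by their ordinal bin deviation — so
#' deviations are penalised only when the modeled opinion also lands in
#' the wrong bin, and larger bin misses are penalised more. Zero exactly
#' when every modeled opinion is in the correct bin. `row_objective()`
#' restricts the sum to one agent; the total is the sum of the rows.
#'
#' @inheritParams modeled_trajectory
#' @return Non-negative scalar.
#' @export
objective_value <- function(W, panel) {
  sum(vapply(seq_len(nrow(panel$scores)), function(i)
    row_objective(W, panel, i), numeric(1)))
}

#' @rdname objective_value
#' @param agent Agent (row) index.
#' @export
row_objective <- function(W, panel, agent) {
  if (agent < 1 || agent > nrow(panel$scores))
    stop("`agent` out of range", call. = FALSE)
  X <- modeled_trajectory(W, panel)
  later <- panel$observed_steps[-1]
  f <- 0
  for (k in seq_along(later)) {
    xh <- X[agent, later[k] + 1]
    xo <- forward_transform(panel$scores[agent, k + 1], panel$scale)
    f <- f + bin_deviation(xh, xo, panel$scale) * abs(xh - xo)
  }
  f
}

#' Fit a DeGroot opinion-diffusion model with a genetic algorithm
#'
#' Estimates the row-stochastic influence-weight matrix of a DeGroot
#' model from an ordinal opinion panel on a (possibly partially observed)
#' social network. The search minimises [objective_value()] subject to
#' row-stochasticity and the structural zeros of the panel's adjacency
#' matrix. Because even a perfect ordinal fit can correspond to several
#' weight matrices, running several seeded restarts (`runs > 1`) and
#' averaging the resulting matrices — averaging preserves the sum-to-one
#' constraint — is recommended for interpretation.
#'
#' @param panel An [opinion_panel()] with at least two observed steps.
#' @param control A [ga_control()] list of GA hyperparameters.
#' @param runs Number of independent GA restarts.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   once before the first run, making the whole fit reproducible.
#' @return An object of class `degroot_fit` with components `weights`
#'   (best run), `average_weights` (entrywise mean across runs, also
#'   row-stochastic), `objective`, `ordinal_fit_rmse`, `generations`,
#'   `converged`, `runs` (per-run weights and objectives), `panel`, and
#'   `control`.
#' @examples
#' set.seed(1)
#' truth <- generate_ground_truth(N = 4, d = 2, n_steps = 5)
#' sc <- ordinal_scale(10)
#' scores <- apply(truth$trajectory[, 1:4], 2, back_transform, scale = sc)
#' panel <- opinion_panel(scores, sc, truth$adjacency)
#' fit <- degroot_fit(panel, control = ga_control(n_generations = 200),
#'                    seed = 1)
#' coef(fit)
#' @export
degroot_fit <- function(panel, control = ga_control(), runs = 1,
                        seed = NULL) {
  stopifnot(inherits(panel, "opinion_panel"))
  if (length(panel$observed_steps) < 2)
    stop("fitting needs at least two observed time steps", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  later <- panel$observed_steps[-1]
  obs <- panel$scores[, -1, drop = FALSE]
  x0 <- forward_transform(panel$scores[, 1], panel$scale)
  run_list <- vector("list", runs)
  for (r in seq_len(runs)) {
    res <- cpp_ga_fit(panel$adjacency, x0, obs, as.integer(later),
                      panel$scale$n_points,
                      control$population_size, control$n_generations,
                      control$tournament_size, control$blend_rate,
                      control$crossover_rate, control$mutation_rate,
                      control$mutation_sd, control$elite_count,
                      control$tolerance)
    dimnames(res$weights) <- dimnames(panel$adjacency)
    run_list[[r]] <- res
  }
  objs <- vapply(run_list, `[[`, numeric(1), "objective")
  best <- which.min(objs)
  W_best <- run_list[[best]]$weights
  W_avg <- average_fits(lapply(run_list, `[[`, "weights"))
  fit_rmse <- panel_ordinal_fit_rmse(W_best, panel)
  structure(list(weights = W_best, average_weights = W_avg,
                 objective = objs[best], ordinal_fit_rmse = fit_rmse,
                 generations = run_list[[best]]$generations,
                 converged = run_list[[best]]$converged,
                 trace = run_list[[best]]$trace,
                 runs = run_list, panel = panel, control = control),
            class = "degroot_fit")
}

# Ordinal-fit RMSE of a weight matrix on its own panel (bin deviations at
# the observed steps past initial, scaled by the number of levels).
panel_ordinal_fit_rmse <- function(W, panel) {
  X <- modeled_trajectory(W, panel)
  later <- panel$observed_steps[-1]
  n <- panel$scale$n_points
  B2 <- 0
  for (k in seq_along(later)) {
    xh <- X[, later[k] + 1]
    xo <- forward_transform(panel$scores[, k + 1], panel$scale)
    B2 <- B2 + sum(bin_deviation(xh, xo, panel$scale)^2)
  }
  sqrt(B2 / (nrow(panel$scores) * length(later) * n^2))
}

#' Average weight matrices across runs
#'
#' Entrywise mean of a list of equally shaped weight matrices. Averaging
#' preserves row-stochasticity and the common structural zeros, so the
#' result is itself a feasible weight matrix.
#'
#' @param results Non-empty list of weight matrices.
#' @export
average_fits <- function(results) {
  if (length(results) == 0L) stop("no matrices to average", call. = FALSE)
  Reduce(`+`, results) / length(results)
}

#' @export
print.degroot_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "DeGroot model fit by genetic algorithm (%d agent%s, %d run%s)\n",
    nrow(x$weights), if (nrow(x$weights) == 1) "" else "s",
    length(x$runs), if (length(x$runs) == 1) "" else "s"))
  cat(sprintf("  objective: %.4g   ordinal-fit RMSE: %.4g   generations: %d%s\n",
              x$objective, x$ordinal_fit_rmse, x$generations,
              if (x$converged) " (converged)" else ""))
  cat("Estimated weights (best run):\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' @export
summary.degroot_fit <- function(object, ...) {
  objs <- vapply(object$runs, `[[`, numeric(1), "objective")
  structure(list(fit = object, run_objectives = objs,
                 perfect_runs = sum(objs == 0)),
            class = "summary.degroot_fit")
}

#' @export
print.summary.degroot_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (length(x$run_objectives) > 1) {
    cat(sprintf("\nRun objectives: %s (%d/%d perfect ordinal fits)\n",
                paste(signif(x$run_objectives, 3), collapse = ", "),
                x$perfect_runs, length(x$run_objectives)))
    cat("Run-averaged weights (row-stochastic):\n")
    print(round(x$fit$average_weights, digits))
  }
  invisible(x)
}

#' @export
coef.degroot_fit <- function(object, which = c("best", "average"), ...) {
  switch(match.arg(which), best = object$weights,
         average = object$average_weights)
}

#' @export
fitted.degroot_fit <- function(object, ...) {
  X <- modeled_trajectory(object$weights, object$panel)
  X[, object$panel$observed_steps + 1, drop = FALSE]
}

#' @export
residuals.degroot_fit <- function(object,
                                  type = c("continuous", "bins"), ...) {
  type <- match.arg(type)
  obs_cont <- forward_transform(object$panel$scores, object$panel$scale)
  dim(obs_cont) <- dim(object$panel$scores)
  dimnames(obs_cont) <- dimnames(object$panel$scores)
  f <- fitted(object)
  if (type == "continuous") return(obs_cont - f)
  r <- back_transform(obs_cont, object$panel$scale) -
    back_transform(f, object$panel$scale)
  dim(r) <- dim(f); dimnames(r) <- dimnames(f)
  r
}

#' Predict future opinions from a fitted DeGroot model
#'
#' Simulates the fitted deterministic dynamics from the panel's initial
#' opinions through `n_steps` updates, returning either continuous
#' opinions or their ordinal back-transforms.
#'
#' @param object A [degroot_fit()].
#' @param n_steps Last time step to simulate (default 20).
#' @param type Continuous opinions or ordinal levels.
#' @param ... Unused.
#' @return `M x (n_steps + 1)` matrix with columns `t0..t<n_steps>`.
#' @export
predict.degroot_fit <- function(object, n_steps = 20,
                                type = c("continuous", "ordinal"), ...) {
  type <- match.arg(type)
  x0 <- forward_transform(object$panel$scores[, 1], object$panel$scale)
  X <- simulate_opinions(object$weights, x0, n_steps)
  rownames(X) <- rownames(object$panel$scores)
  if (type == "ordinal") {
    O <- back_transform(X, object$panel$scale)
    dim(O) <- dim(X); dimnames(O) <- dimnames(X)
    return(O)
  }
  X
}

#' @export
simulate.degroot_fit <- function(object, nsim = 1, seed = NULL,
                                 n_steps = 20, ...) {
  # dynamics are deterministic given the weights; nsim > 1 varies nothing
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, predict(object, n_steps = n_steps, type = "ordinal"),
            simplify = FALSE)
}

#' @export
plot.degroot_fit <- function(x, n_steps = max(x$panel$observed_steps), ...) {
  X <- predict(x, n_steps = n_steps)
  graphics::matplot(0:n_steps, t(X), type = "l", lty = 1,
                    xlab = "time step", ylab = "opinion (continuous)",
                    ylim = c(0, 1), ...)
  obs <- forward_transform(x$panel$scores, x$panel$scale)
  dim(obs) <- dim(x$panel$scores)
  for (i in seq_len(nrow(obs)))
    graphics::points(x$panel$observed_steps, obs[i, ], col = i, pch = 16)
  invisible(x)
}
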