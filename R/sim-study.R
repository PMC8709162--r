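#' Deterministic per-cell seed
#'
#' Derives a reproducible seed for one (cell, replicate) pair by hashing
#' the cell's field values together with the master seed. Results are
#' therefore invariant to the order in which cells are run.
#'
#' @param master_seed Integer master seed.
#' @param ... Cell field values (coerced to character).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
cell_seed <- function(master_seed, ...) {
  key <- paste(master_seed, ..., sep = "|")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Generate the data for one simulation cell
#'
#' Runs the data-generating side of a simulation cell: a connected
#' Erdős–Rényi ground truth simulated for 20 updates under the cell's
#' dynamics, ordinal back-transformed opinions, a two-wave snowball
#' sample (regenerating the whole truth when a sample of fewer than four
#' agents is rejected), the requested adjacency variety, and the observed
#' panel holding the sampled agents' ordinal opinions at `t = 0..T-1`.
#'
#' @param N,d Network size and target degree.
#' @param self_weight Target mean self-weight.
#' @param T_steps Number of time steps given to the fitter.
#' @param n Ordinal scale levels.
#' @param p Snowball recruitment probability.
#' @param adjacency Variety kind given to the fitter.
#' @param delta,lambda Data-generating dynamics parameters.
#' @param max_tries Regeneration budget for rejected samples/networks.
#' @return List with `truth`, `sample`, `variety` (the matrix), `panel`,
#'   and `rejections` (how many samples were rejected before acceptance).
#' @export
draw_cell_data <- function(N = 10, d = 5, self_weight = 0.5, T_steps = 6,
                           n = 30, p = 1, adjacency = "correct",
                           delta = 1, lambda = 1, max_tries = 1000) {
  dyn <- degroot_dynamics(delta, lambda)
  sc <- ordinal_scale(n)
  rejections <- 0
  for (try in seq_len(max_tries)) {
    truth <- generate_ground_truth(N, d, self_weight, n_steps = 20,
                                   dynamics = dyn, max_tries = max_tries)
    sample <- tryCatch(snowball_sample(truth$adjacency, p),
                       degroot_rejection = function(e) NULL)
    if (!is.null(sample)) break
    rejections <- rejections + 1
    sample <- NULL
  }
  if (is.null(sample))
    stop("sample generation budget exhausted", call. = FALSE)
  A_fit <- adjacency_variety(truth$adjacency, sample, adjacency)
  ords <- matrix(back_transform(truth$trajectory[sample$sampled_ids,
                                                 seq_len(T_steps)], sc),
                 nrow = length(sample$sampled_ids))
  panel <- opinion_panel(ords, sc, A_fit,
                         observed_steps = 0:(T_steps - 1))
  list(truth = truth, sample = sample, variety = A_fit, panel = panel,
       rejections = rejections)
}

#' Run one cell of the simulation study
#'
#' Generates a cell's data with [draw_cell_data()], fits the DeGroot
#' model to the sampled ordinal panel with [degroot_fit()], and scores
#' the fit with [evaluate_fit()]. Fully deterministic given the cell
#' fields, replicate index, and master seed.
#'
#' @inheritParams draw_cell_data
#' @param replicate Replicate index within the cell.
#' @param master_seed Master seed of the study.
#' @param control GA hyperparameters.
#' @return One-row data frame (a metrics record) with the cell fields,
#'   sampled size `M`, the four RMSEs, the GA objective, and the
#'   generations run.
#' @export
run_cell <- function(N = 10, d = 5, self_weight = 0.5, T_steps = 6,
                     n = 30, p = 1, adjacency = "correct", delta = 1,
                     lambda = 1, replicate = 1, master_seed = 1,
                     control = ga_control(), max_tries = 1000) {
  seed <- cell_seed(master_seed, N, d, self_weight, T_steps, n, p,
                    adjacency, delta, lambda, replicate)
  set.seed(seed)
  rec <- data.frame(N = N, d = d, self_weight = self_weight, T = T_steps,
                    n = n, p = p, adjacency = adjacency, delta = delta,
                    lambda = lambda, replicate = replicate,
                    cell_seed = seed, M = NA_integer_,
                    recovery_rmse = NA_real_, modeling_rmse = NA_real_,
                    prediction_rmse = NA_real_,
                    ordinal_fit_rmse = NA_real_, objective = NA_real_,
                    generations = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- tryCatch({
    dat <- draw_cell_data(N, d, self_weight, T_steps, n, p, adjacency,
                          delta, lambda, max_tries)
    fit <- degroot_fit(dat$panel, control = control)
    m <- evaluate_fit(dat$truth, dat$sample, adjacency, fit, T_steps)
    rec$M <- length(dat$sample$sampled_ids)
    rec$recovery_rmse <- m$recovery_rmse
    rec$modeling_rmse <- m$modeling_rmse
    rec$prediction_rmse <- m$prediction_rmse
    rec$ordinal_fit_rmse <- m$ordinal_fit_rmse
    rec$objective <- fit$objective
    rec$generations <- fit$generations
    rec
  }, error = function(e) {
    warning(sprintf("cell failed (%s); recorded with NA metrics",
                    conditionMessage(e)), call. = FALSE)
    rec
  })
  out
}

#' Run a grid of simulation cells
#'
#' One metrics record per (cell, replicate). Cell seeds are derived
#' deterministically from the master seed and the cell's field values, so
#' the output is invariant to the order of the grid rows. Failed cells
#' are recorded with `NA` metrics rather than aborting the study.
#'
#' @param grid Data frame with columns `N, d, self_weight, T, n, p,
#'   adjacency, delta, lambda` (see [default_grid()], [full_grid()]).
#' @param replicates Replicates per cell (the study design uses 10).
#' @param master_seed Master seed.
#' @param control GA hyperparameters.
#' @param verbose Print progress.
#' @return Data frame with columns `N, d, self_weight, T, n, p,
#'   adjacency, delta, lambda, replicate, cell_seed, M, recovery_rmse,
#'   modeling_rmse, prediction_rmse, ordinal_fit_rmse, objective,
#'   generations`.
#' @export
run_grid <- function(grid, replicates = 10, master_seed = 1,
                     control = ga_control(), verbose = FALSE) {
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  need <- c("N", "d", "self_weight", "T", "n", "p", "adjacency",
            "delta", "lambda")
  missing_cols <- setdiff(need, names(grid))
  if (length(missing_cols))
    stop("grid lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- vector("list", nrow(grid) * replicates)
  k <- 0
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      k <- k + 1
      if (verbose)
        message(sprintf("cell %d/%d replicate %d", g, nrow(grid), r))
      rows[[k]] <- run_cell(grid$N[g], grid$d[g], grid$self_weight[g],
                            grid$T[g], grid$n[g], grid$p[g],
                            as.character(grid$adjacency[g]),
                            grid$delta[g], grid$lambda[g],
                            replicate = r, master_seed = master_seed,
                            control = control)
    }
  }
  do.call(rbind, rows)
}

#' Simulation-study input grids
#'
#' `full_grid()` is the complete factorial design of the study inputs:
#' network sizes 10/20/50, target degrees 5/9, 2/3/6 fitted time steps,
#' 5/7/10/20/30-point scales, recruitment probabilities 0.5/1, four
#' adjacency varieties, and bounded-confidence and decay parameters
#' 0.1/0.5/0.9/1 each (1 = plain DeGroot). At 10 replicates per cell this
#' is far too large for a desktop run; `default_grid()` is a reduced
#' design on the smallest network that still spans the contrasts of
#' interest (adjacency variety, scale precision, and dynamics
#' misspecification one factor at a time).
#'
#' @return Data frame of cell definitions for [run_grid()].
#' @export
full_grid <- function() {
  expand.grid(N = c(10, 20, 50), d = c(5, 9), self_weight = 0.5,
              T = c(2, 3, 6), n = c(5, 7, 10, 20, 30), p = c(0.5, 1),
              adjacency = c("correct", "build", "remove", "complete"),
              delta = c(0.1, 0.5, 0.9, 1), lambda = c(0.1, 0.5, 0.9, 1),
              stringsAsFactors = FALSE)
}

#' @rdname full_grid
#' @export
default_grid <- function() {
  base <- data.frame(N = 10, d = 5, self_weight = 0.5, T = 6, n = 30,
                     p = 0.5, adjacency = "remove", delta = 1, lambda = 1,
                     stringsAsFactors = FALSE)
  vary <- function(field, values) {
    do.call(rbind, lapply(values, function(v) {
      row <- base
      row[[field]] <- v
      row
    }))
  }
  out <- rbind(vary("adjacency", c("correct", "build", "remove",
                                   "complete")),
               vary("n", c(5, 7, 10, 20, 30)),
               vary("T", c(2, 3, 6)),
               vary("lambda", c(0.1, 0.5, 0.9, 1)),
               vary("delta", c(0.1, 0.5, 0.9, 1)))
  unique(out)
}
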