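#' Parameter-recovery RMSE
#'
#' Root-mean-square error between true and estimated weights over the
#' entries not fixed at structural zero, i.e. over the `P` free parameters
#' counted by the evaluation adjacency matrix (self-links included).
#'
#' When agents are missing from a sampled network, the true weight matrix
#' is reduced to the sampled agents *without* renormalising, so its rows
#' may sum to less than one — the mass placed on missing agents is simply
#' unobservable. For fits using the *build* variety, evaluate against the
#' *correct* matrix instead, so the incorrectly imposed structural zeros
#' are penalised (see [evaluate_fit()], which applies this convention).
#'
#' @param true_weights True weight matrix reduced to the sampled agents.
#' @param est_weights Estimated weight matrix of the same shape.
#' @param eval_adjacency Adjacency matrix whose unit entries mark the free
#'   parameters.
#' @return Non-negative scalar.
#' @export
recovery_rmse <- function(true_weights, est_weights, eval_adjacency) {
  stopifnot(all(dim(true_weights) == dim(est_weights)),
            all(dim(true_weights) == dim(eval_adjacency)))
  free <- eval_adjacency == 1
  P <- sum(free)
  sqrt(sum((true_weights[free] - est_weights[free])^2) / P)
}

#' @rdname recovery_rmse
#' @param true_row,est_row One agent's true and estimated weight rows.
#' @param eval_row_adjacency 0/1 vector marking that row's free entries.
#' @export
row_recovery_rmse <- function(true_row, est_row, eval_row_adjacency) {
  stopifnot(length(true_row) == length(est_row),
            length(true_row) == length(eval_row_adjacency))
  free <- eval_row_adjacency == 1
  if (!any(free)) stop("no free entries in row", call. = FALSE)
  sqrt(sum((true_row[free] - est_row[free])^2) / sum(free))
}

#' Modeling and prediction RMSE on latent opinions
#'
#' Both compare the fitted model's continuous trajectory with the true
#' latent (continuous) trajectory of the sampled agents. Of the 21
#' simulated time steps `t = 0..20`, the first `T` are given to the
#' fitter: `modeling_rmse()` scores the `T - 1` fitted steps past initial
#' (initial opinions are reproduced by construction and not assessed),
#' and `prediction_rmse()` scores the `21 - T` held-out future steps
#' `t = T..20`.
#'
#' @param latent True continuous trajectory of the sampled agents
#'   (`M x 21` for steps `t0..t20`).
#' @param modeled Fitted model's trajectory, same shape.
#' @param T_steps Number of time steps given to the fitter (`T >= 2` for
#'   modeling, `T <= 20` for prediction).
#' @return Non-negative scalar.
#' @export
modeling_rmse <- function(latent, modeled, T_steps) {
  stopifnot(all(dim(latent) == dim(modeled)))
  if (T_steps < 2) stop("modeling RMSE needs T >= 2", call. = FALSE)
  M <- nrow(latent)
  ts <- 2:T_steps  # columns for t = 1..T-1
  sqrt(sum((modeled[, ts] - latent[, ts])^2) / (M * (T_steps - 1)))
}

#' @rdname modeling_rmse
#' @export
prediction_rmse <- function(latent, modeled, T_steps) {
  stopifnot(all(dim(latent) == dim(modeled)))
  last_t <- ncol(latent) - 1
  if (T_steps > last_t)
    stop("no prediction steps left past T", call. = FALSE)
  M <- nrow(latent)
  ts <- (T_steps + 1):(last_t + 1)  # columns for t = T..last
  sqrt(sum((modeled[, ts] - latent[, ts])^2) / (M * (last_t + 1 - T_steps)))
}

#' Ordinal-fit RMSE
#'
#' The only fit diagnostic available in a real application, where latent
#' opinions and true weights are unknown: the RMSE of the ordinal bin
#' deviations between modeled and observed opinions on the fitted steps
#' `t = 1..T-1`, scaled by the number of scale levels `n` so that values
#' are comparable across scales (the maximum possible value is
#' `(n-1)/n`).
#'
#' @inheritParams modeling_rmse
#' @param observed Continuous representation of the observed opinions
#'   (mid-bin transforms), same shape as `modeled`, or an integer matrix
#'   of ordinal scores.
#' @param scale An [ordinal_scale()] or level count.
#' @export
ordinal_fit_rmse <- function(observed, modeled, T_steps, scale) {
  stopifnot(all(dim(observed)[1] == dim(modeled)[1]))
  if (T_steps < 2) stop("ordinal-fit RMSE needs T >= 2", call. = FALSE)
  n <- n_points_of(scale)
  if (all(observed == round(observed)) && max(observed) > 1) {
    observed <- (observed - 0.5) / n  # ordinal scores to mid-bin values
  }
  M <- nrow(modeled)
  ts <- 2:T_steps
  B <- abs(matrix(back_transform(modeled[, ts], scale), M) -
           matrix(back_transform(observed[, ts], scale), M))
  sqrt(sum(B^2) / (M * (T_steps - 1) * n^2))
}

#' Mean influence placed on leaders versus non-leaders
#'
#' Summarises an estimated weight matrix by the average weight agents
#' place on designated opinion leaders versus other agents, excluding
#' self-weights and restricted to agents with at least one permitted link
#' to a leader. Optionally drops weights at or below a threshold, since
#' correctly estimated structural zeros can mask real influence averages
#' (interpret with care: true zero influence is dropped too).
#'
#' @param weights Estimated weight matrix.
#' @param leader Logical vector flagging leader agents (at least one).
#' @param adjacency Optional adjacency matrix restricting which entries
#'   count as permitted links (default: all off-diagonal entries).
#' @param exclude_below Optional threshold; weights `<=` it are excluded.
#' @return A list with `leader`, `non_leader` mean weights (`NA` when the
#'   group is empty) and their `difference`.
#' @export
leader_influence_summary <- function(weights, leader, adjacency = NULL,
                                     exclude_below = NULL) {
  M <- nrow(weights)
  leader <- as.logical(leader)
  if (!any(leader)) stop("at least one leader required", call. = FALSE)
  if (is.null(adjacency)) adjacency <- matrix(1, M, M)
  permitted <- adjacency == 1
  diag(permitted) <- FALSE
  leads_to_leader <- rowSums(permitted[, leader, drop = FALSE]) > 0
  keep <- function(j_flag) {
    sel <- permitted & matrix(j_flag, M, M, byrow = TRUE) & leads_to_leader
    w <- weights[sel]
    if (!is.null(exclude_below)) w <- w[w > exclude_below]
    if (length(w) == 0) NA_real_ else mean(w)
  }
  on_leader <- keep(leader)
  on_other <- keep(!leader)
  list(leader = on_leader, non_leader = on_other,
       difference = on_leader - on_other)
}

#' Score a fitted model against its ground truth
#'
#' Computes the four simulation-study metrics for one fitted run:
#' recovery RMSE of the weights, modeling and prediction RMSE on the
#' latent continuous trajectory, and ordinal-fit RMSE. The true weight
#' matrix and latent trajectory are reduced to the sampled agents; for
#' fits that used the *build* variety, recovery is evaluated against the
#' *correct* matrix so that its wrongly imposed structural zeros are
#' penalised.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param sample The [snowball_sample()] the panel came from.
#' @param variety_kind Adjacency variety given to the fitter.
#' @param fit A [degroot_fit()] on the sampled panel.
#' @param T_steps Number of time steps that were given to the fitter.
#' @return Named list with the four RMSEs.
#' @export
evaluate_fit <- function(truth, sample, variety_kind, fit, T_steps) {
  ids <- sample$sampled_ids
  W_true <- truth$weights[ids, ids, drop = FALSE]
  eval_adj <- if (variety_kind == "build") {
    A <- truth$adjacency[ids, ids, drop = FALSE]; diag(A) <- 1; A
  } else {
    fit$panel$adjacency
  }
  latent <- truth$trajectory[ids, , drop = FALSE]
  last_t <- ncol(latent) - 1
  modeled <- predict(fit, n_steps = last_t)
  list(
    recovery_rmse = recovery_rmse(W_true, fit$weights, eval_adj),
    modeling_rmse = modeling_rmse(latent, modeled, T_steps),
    prediction_rmse = prediction_rmse(latent, modeled, T_steps),
    ordinal_fit_rmse = ordinal_fit_rmse(
      (fit$panel$scores - 0.5) / fit$panel$scale$n_points,
      modeled[, seq_len(T_steps), drop = FALSE], T_steps, fit$panel$scale))
}
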