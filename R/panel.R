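#' Observed ordinal opinion panel
#'
#' The data object handed to the fitter: ordinal opinion scores for `M`
#' agents at a set of observed time steps, together with the ordinal scale
#' and the adjacency matrix the fit must conform to. The first observed
#' step must be `t = 0` — the initial opinions anchor the simulation — but
#' later steps may skip indices (two survey waves three months apart are
#' naturally coded as `t = 0` and `t = 3` with `t = 1, 2` unobserved, so
#' the model can carry influence through the gap). The fitter requires
#' complete scores; panels with missing values are rejected.
#'
#' @param scores Integer matrix, agents in rows, one column per observed
#'   step, values in `1..n_points`.
#' @param scale An [ordinal_scale()] or the number of levels.
#' @param adjacency `M x M` adjacency matrix given to the fitter (any
#'   [adjacency_variety()]).
#' @param observed_steps Strictly increasing integer time indices, one per
#'   column of `scores`, starting at 0. Defaults to `0:(K-1)`.
#' @return An object of class `opinion_panel`.
#' @export
opinion_panel <- function(scores, scale, adjacency,
                          observed_steps = seq_len(ncol(scores)) - 1L) {
  scores <- as.matrix(scores)
  if (anyNA(scores))
    stop("panel has missing scores; impute before fitting", call. = FALSE)
  scale <- if (inherits(scale, "ordinal_scale")) scale else ordinal_scale(scale)
  validate_adjacency(adjacency)
  if (nrow(adjacency) != nrow(scores))
    stop("adjacency size must match the number of agents", call. = FALSE)
  observed_steps <- as.integer(observed_steps)
  if (length(observed_steps) != ncol(scores))
    stop("`observed_steps` must have one entry per score column",
         call. = FALSE)
  if (observed_steps[1] != 0L)
    stop("the first observed step must be t = 0", call. = FALSE)
  if (length(observed_steps) > 1 && any(diff(observed_steps) <= 0))
    stop("`observed_steps` must be strictly increasing", call. = FALSE)
  if (any(scores != round(scores)) || any(scores < 1) ||
      any(scores > scale$n_points))
    stop(sprintf("scores must be integers in 1..%d", scale$n_points),
         call. = FALSE)
  storage.mode(scores) <- "integer"
  colnames(scores) <- paste0("t", observed_steps)
  if (is.null(rownames(scores))) {
    rownames(scores) <- rownames(adjacency) %||%
      paste0("agent", seq_len(nrow(scores)))
  }
  structure(list(scores = scores, scale = scale, adjacency = adjacency,
                 observed_steps = observed_steps),
            class = "opinion_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.opinion_panel <- function(x, ...) {
  cat(sprintf(
    "Opinion panel: %d agents, %d-point scale, observed steps %s\n",
    nrow(x$scores), x$scale$n_points,
    paste0("t", x$observed_steps, collapse = ", ")))
  print(x$scores)
  invisible(x)
}

#' Read / write delimited tables for panels and matrices
#'
#' Plain-text interchange: square matrices (adjacency or weights) are
#' written as tab-separated tables with agent identifiers as both row and
#' column names; panels as tables with agents in rows and observed time
#' steps as columns named `t0`, `t3`, ...
#'
#' @param path File path.
#' @name degroot-io
NULL

#' @rdname degroot-io
#' @param x Square numeric matrix.
#' @export
write_matrix_table <- function(x, path) {
  df <- as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname degroot-io
#' @export
read_matrix_table <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE))
}

#' @rdname degroot-io
#' @param panel An [opinion_panel()].
#' @export
write_panel_table <- function(panel, path) {
  write.table(as.data.frame(panel$scores), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' @rdname degroot-io
#' @param scale,adjacency Passed to [opinion_panel()] when reassembling
#'   the panel from its table (step indices are parsed from the `t...`
#'   column headers).
#' @export
read_panel_table <- function(path, scale, adjacency) {
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                    check.names = FALSE)
  steps <- suppressWarnings(as.integer(sub("^t", "", colnames(tab))))
  if (anyNA(steps))
    stop("panel columns must be named t<step>, e.g. t0, t3", call. = FALSE)
  opinion_panel(as.matrix(tab), scale, adjacency, observed_steps = steps)
}
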