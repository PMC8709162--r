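#' Ordinal opinion scales
#'
#' Opinions are measured on an `n_points`-level ordinal scale (a Likert item
#' or a composite score) but modeled as latent continuous values on
#' \eqn{[0, 1]}. An `ordinal_scale` object carries the number of levels and
#' drives the forward (ordinal to continuous) and back (continuous to
#' ordinal) transformations.
#'
#' The unit interval is divided into `n_points` sub-intervals ("bins") of
#' equal width; ordinal level \eqn{x} maps to the midpoint of the
#' \eqn{x}-th bin, and a continuous opinion maps back to the index of the
#' bin containing it.
#'
#' @param n_points Integer number of ordinal levels, at least 2.
#' @return An object of class `ordinal_scale`.
#' @examples
#' sc <- ordinal_scale(5)
#' forward_transform(1:5, sc)
#' back_transform(c(0, 0.41, 1), sc)
#' @export
ordinal_scale <- function(n_points) {
  if (length(n_points) != 1L || !is.finite(n_points) ||
      n_points != as.integer(n_points) || n_points < 2) {
    stop("`n_points` must be a single integer >= 2", call. = FALSE)
  }
  structure(list(n_points = as.integer(n_points)), class = "ordinal_scale")
}

#' @export
print.ordinal_scale <- function(x, ...) {
  cat(sprintf("Ordinal scale with %d levels (bin width %.4g)\n",
              x$n_points, 1 / x$n_points))
  invisible(x)
}

n_points_of <- function(scale) {
  if (inherits(scale, "ordinal_scale")) return(scale$n_points)
  ordinal_scale(scale)$n_points  # accept a bare integer
}

#' Transform ordinal levels to continuous opinions
#'
#' Level `x` on an `n`-point scale becomes the midpoint \eqn{(x - 0.5)/n}
#' of the `x`-th equal-width sub-interval of \eqn{[0, 1]}.
#'
#' @param x Integer vector of ordinal levels in `1..n`.
#' @param scale An [ordinal_scale()] (or a bare level count).
#' @return Numeric vector of continuous opinions in \eqn{(0, 1)}.
#' @seealso [back_transform()], [bin_deviation()]
#' @export
forward_transform <- function(x, scale) {
  n <- n_points_of(scale)
  if (length(x) == 0L) return(numeric(0))
  if (any(!is.finite(x)) || any(x != round(x)))
    stop("ordinal levels must be integers", call. = FALSE)
  if (any(x < 1) || any(x > n))
    stop(sprintf("ordinal levels must lie in 1..%d", n), call. = FALSE)
  (x - 0.5) / n
}

#' Transform continuous opinions back to ordinal levels
#'
#' A continuous opinion `y` is multiplied by the number of levels `n` and
#' rounded up (`ceiling`), so it maps to the index of the sub-interval
#' containing it; `y = 0` maps to level 1. Products within 1e-12 of an
#' integer are snapped to it first, so opinions intended to sit exactly on
#' a bin boundary are not pushed up a bin by floating-point representation
#' error (bin midpoints never sit on boundaries, but simulated trajectories
#' can).
#'
#' @param y Numeric vector of opinions in \eqn{[0, 1]}.
#' @inheritParams forward_transform
#' @return Integer vector of ordinal levels in `1..n`.
#' @export
back_transform <- function(y, scale) {
  n <- n_points_of(scale)
  if (length(y) == 0L) return(integer(0))
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1))
    stop("continuous opinions must lie in [0, 1]", call. = FALSE)
  z <- y * n
  snap <- abs(z - round(z)) < 1e-12
  z[snap] <- round(z[snap])
  lvl <- as.integer(ceiling(z))
  lvl[lvl < 1L] <- 1L  # y = 0 edge case
  lvl
}

#' Bin deviation between two continuous opinions
#'
#' The absolute difference, on the ordinal scale, between the bins that two
#' continuous opinions fall into. A deviation of 0 means the modeled
#' opinion is in the "correct bin". This is the factor that gates the
#' fitting objective: continuous deviations are only penalised when the
#' opinions also differ ordinally.
#'
#' @param y_hat,y_obs Numeric vectors of opinions in \eqn{[0, 1]}
#'   (recycled to a common length).
#' @inheritParams forward_transform
#' @return Non-negative integer vector, bounded by `n - 1`.
#' @export
bin_deviation <- function(y_hat, y_obs, scale) {
  abs(back_transform(y_hat, scale) - back_transform(y_obs, scale))
}

#' Rescale an arbitrary integer score range to 1..n
#'
#' Composite scales are often reported on a shifted range (a sum of eight
#' 4-point items ranges 8 to 32, a 25-point scale). Subtracting
#' `min_score - 1` maps such scores onto `1..n` as the transformations
#' expect.
#'
#' @param x Integer vector of raw scores.
#' @param min_score Smallest attainable raw score (default `min(x)`).
#' @return Integer vector on a 1-based scale.
#' @examples
#' rescale_ordinal(c(8, 20, 32), min_score = 8)  # -> 1, 13, 25
#' @export
rescale_ordinal <- function(x, min_score = min(x)) {
  if (any(!is.finite(x)) || any(x != round(x)))
    stop("scores must be integers", call. = FALSE)
  as.integer(x - (min_score - 1L))
}
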