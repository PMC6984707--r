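#' Synthetic (ground truth, observed) score pairs with tunable reliability
#'
#' The generator emulates a continuous score on \[0, 10\] measured by an
#' unreliable instrument.  Ground truth x is uniform on \[0, 10\].  The
#' instrument reading f(x) adds uniform noise U(-sigma, sigma) along the
#' diagonal; in the asymmetric regime (beta = 1) the noise is scaled by the
#' logistic factor 1 / (1 + exp(-0.75 x + 5)), so readings are nearly exact
#' at the low end of the scale and noisy at the high end, and out-of-range
#' values are reflected back into the interval.  In the symmetric regime
#' (beta = 0) the spread is constant and the pooled readings are rescaled
#' into \[0, 10\].  Finally, a fraction (1 - omega) of observations is
#' replaced by pure uniform background noise: with probability omega the
#' observation is the instrument reading, otherwise it is U(0, 10).
#'
#' @name synthetic-data
NULL

#' Fold values into an interval by mirror reflection
#'
#' Repeatedly reflects out-of-range values at the interval bounds until
#' they land inside.  Idempotent on in-range values.
#'
#' @param value Numeric vector.
#' @param lower,upper Interval bounds, `lower < upper`.
#' @return Numeric vector of the same length, inside `[lower, upper]`.
#' @examples
#' reflect_into_interval(c(-2, 12, 23), 0, 10)  # 2, 8, 3
#' @export
reflect_into_interval <- function(value, lower = 0, upper = 10) {
  stopifnot(lower < upper)
  w <- upper - lower
  v <- (value - lower) %% (2 * w)
  lower + ifelse(v > w, 2 * w - v, v)
}

#' Affinely rescale a sample to span an interval
#'
#' Maps the sample minimum and maximum onto `lower` and `upper`; order is
#' preserved.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param lower,upper Target interval bounds.
#' @return Rescaled numeric vector.
#' @export
rescale_into_interval <- function(values, lower = 0, upper = 10) {
  stopifnot(lower < upper)
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("degenerate scale: cannot rescale a constant sequence", call. = FALSE)
  lower + (values - rng[1]) / (rng[2] - rng[1]) * (upper - lower)
}

#' Sample a synthetic dataset of (ground truth, observed) pairs
#'
#' @param beta Asymmetry switch: 1 = asymmetric (logistic noise profile,
#'   reflection at the bounds), 0 = symmetric (constant spread, pooled
#'   rescaling into the interval).
#' @param omega Coupling in \[0, 1\]: probability that an observation comes
#'   from the instrument reading rather than uniform background noise
#'   (omega = 0 gives pure noise, omega = 1 no background noise).
#' @param sigma Non-negative half-width of the diagonal noise.
#' @param n Number of samples (study default 750).
#' @param seed Optional integer seed; a fixed seed reproduces the dataset
#'   bit for bit.
#' @return A `synthetic_dataset`: data frame with columns `x`, `y` (both in
#'   \[0, 10\]) and a `params` attribute recording the generator settings.
#' @export
sample_dataset <- function(beta, omega, sigma, n = 750L, seed = NULL) {
  stopifnot(beta %in% c(0, 1), length(omega) == 1L, omega >= 0, omega <= 1,
            length(sigma) == 1L, sigma >= 0, length(n) == 1L, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n, 0, 10)
  u <- stats::runif(n, -sigma, sigma)
  if (beta == 1) {
    f <- reflect_into_interval(x + u / (1 + exp(-0.75 * x + 5)), 0, 10)
  } else {
    f <- x + u
    if (min(f) < 0 || max(f) > 10) f <- rescale_into_interval(f, 0, 10)
  }
  background <- stats::runif(n, 0, 10)
  from_instrument <- stats::runif(n) < omega
  y <- ifelse(from_instrument, f, background)
  new_synthetic_dataset(x, y,
    params = list(beta = beta, omega = omega, sigma = sigma, n = n, seed = seed))
}

new_synthetic_dataset <- function(x, y, params) {
  d <- data.frame(x = x, y = y)
  attr(d, "params") <- params
  class(d) <- c("synthetic_dataset", "data.frame")
  d
}

#' Regular grid of points over the unit square of scores
#'
#' A full Cartesian grid on \[0, 10\] x \[0, 10\]: the coordinates are
#' independent by construction, so any mutual-information estimator should
#' report (approximately) zero on it.  Used as a sanity input.
#'
#' @param points_per_axis Number of equally spaced points per axis (>= 2).
#' @return A `synthetic_dataset` with `points_per_axis^2` rows.
#' @export
grid_dataset <- function(points_per_axis) {
  stopifnot(points_per_axis >= 2)
  s <- seq(0, 10, length.out = points_per_axis)
  g <- expand.grid(x = s, y = s, KEEP.OUT.ATTRS = FALSE)
  new_synthetic_dataset(g$x, g$y,
    params = list(grid = TRUE, points_per_axis = points_per_axis))
}

#' Synthetic inter-rater rating fixture with asymmetric reliability
#'
#' Emulates the study's rating matrix: each rater's score for a vignette is
#' drawn from a normal centred on the vignette's gold-standard score,
#' rounded to the nearest integer and clipped to 0..10.  The dispersion is
#' `sd_high` for responder vignettes (gold >= 7) and `sd_low` otherwise;
#' the default `sd_high < sd_low` mimics the tighter agreement observed at
#' the top of the scale.
#'
#' @param gold Gold-standard scores per vignette.
#' @param n_raters Number of raters.
#' @param sd_low,sd_high Rating standard deviations below / at-or-above the
#'   responder threshold.
#' @param seed Optional integer seed.
#' @return A `rating_matrix` (round-trips through [write_ratings()] /
#'   [read_ratings()] unchanged).
#' @export
generate_rating_fixture <- function(gold = alda_gold_standard, n_raters = 59L,
                                    sd_low = 2.0, sd_high = 0.8, seed = NULL) {
  stopifnot(sd_low > 0, sd_high > 0, n_raters >= 1)
  if (!is.null(seed)) set.seed(seed)
  sds <- ifelse(gold >= 7, sd_high, sd_low)
  scores <- vapply(seq_along(gold), function(j) {
    as.integer(pmin(10, pmax(0, round(stats::rnorm(n_raters, gold[j], sds[j])))))
  }, integer(n_raters))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = n_raters)
  new_rating_matrix(scores, gold, site = rep("synthetic", n_raters))
}
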