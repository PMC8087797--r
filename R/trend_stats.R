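# Trend and regression toolkit: Theil-Sen slopes with Mann-Kendall
# significance, binned OLS, significance tiers, and weighted Gaussian KDE.

#' Theil-Sen trend estimate with Mann-Kendall significance
#'
#' Slope is the median of all pairwise slopes (robust to outliers, ~29%
#' breakdown); intercept is `median(y - slope * x)`. The p-value comes from
#' the two-sided Mann-Kendall test with tie correction and continuity
#' correction (normal approximation), the standard companion test for
#' Theil-Sen trend estimates.
#'
#' @param x Numeric predictor (e.g. years); at least two distinct values.
#' @param y Numeric response, same length.
#' @return List of class `trend_result`: slope, intercept, p_value, n.
#' @export
theil_sen <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stop("x values are all equal; slope undefined")
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  slopes <- (dy / dx)[dx != 0]
  slope <- stats::median(slopes)
  intercept <- stats::median(y - slope * x)
  structure(list(slope = slope, intercept = intercept,
                 p_value = mann_kendall_p(x, y), n = n),
            class = "trend_result")
}

#' Two-sided Mann-Kendall test p-value (tie-corrected)
#'
#' @param x Ordering variable (typically years).
#' @param y Values.
#' @return p-value in [0, 1]; exactly 1 when the S statistic is 0.
#' @export
mann_kendall_p <- function(x, y) {
  ord <- order(x)
  y <- y[ord]
  n <- length(y)
  ij <- utils::combn(n, 2)
  s <- sum(sign(y[ij[2, ]] - y[ij[1, ]]))
  ties <- table(y)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) return(1)
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  2 * stats::pnorm(-abs(z))
}

#' Binned ordinary least squares
#'
#' OLS with intercept for totals binned per year (or per year x ecoregion):
#' e.g. annual burned area versus annual SL_BA. Adjusted R^2 uses
#' `1 - (1 - R^2) (n - 1) / (n - 2)`.
#'
#' @param x,y Numeric binned totals; n >= 3 and x must vary.
#' @return List of class `regression_result`: slope, intercept, r2_adj,
#'   p_value (slope t-test), n.
#' @export
ols_binned <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("ols_binned needs n >= 3")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless fits trip a perfect-fit warning
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2_adj = sm$adj.r.squared,
                 p_value = p, n = length(x)),
            class = "regression_result")
}

#' Significance tier of a p-value
#'
#' Strict thresholds: highly significant p < 0.0001, moderately significant
#' p < 0.01, weakly significant p < 0.05, otherwise not significant.
#'
#' @param p p-value(s) in [0, 1]; vectorised.
#' @return Character vector of tier labels.
#' @export
significance_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.0001, "highly",
  ifelse(p < 0.01, "moderately",
  ifelse(p < 0.05, "weakly", "not significant")))
}

#' Weighted Gaussian kernel density estimate
#'
#' Direct (non-binned) evaluation of the weight-normalised Gaussian mixture,
#' used for SL_BA-weighted latitudinal/longitudinal density curves. The
#' default bandwidth is Silverman's rule computed on the weighted sample
#' with effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param x Coordinates (e.g. latitudes).
#' @param weights Non-negative weights (e.g. per-fire SL_BA), not all zero.
#' @param bandwidth Kernel bandwidth; NULL for weighted Silverman.
#' @param n_grid Number of evaluation points.
#' @param cut Grid extension beyond the data range, in bandwidths.
#' @return Data frame (grid, density); the trapezoid integral over the grid
#'   is 1 to high accuracy.
#' @export
weighted_kde <- function(x, weights = NULL, bandwidth = NULL, n_grid = 512,
                         cut = 5) {
  stopifnot(length(x) >= 1)
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), all(weights >= 0))
  if (sum(weights) <= 0) stop("weights must not all be zero")
  w <- weights / sum(weights)
  if (is.null(bandwidth)) {
    mu <- sum(w * x)
    sdw <- sqrt(sum(w * (x - mu)^2))
    n_eff <- 1 / sum(w^2)
    spread <- if (sdw > 0) sdw else 1
    bandwidth <- 0.9 * spread * n_eff^(-1 / 5)
  }
  stopifnot(bandwidth > 0)
  grid <- seq(min(x) - cut * bandwidth, max(x) + cut * bandwidth,
              length.out = n_grid)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm(g, mean = x, sd = bandwidth)), numeric(1))
  data.frame(grid = grid, density = dens)
}
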