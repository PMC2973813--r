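# Neutral-decay analysis: Ks density and modes, (partial) correlations of
# buffering strength with divergence, and the strength-vs-Ks regression.

#' Gaussian kernel density estimate with mode detection
#'
#' Standard Gaussian-window KDE on an even grid spanning
#' `\[min - 3h, max + 3h\]`. The default bandwidth is Silverman's
#' rule of thumb (`stats::bw.nrd0`). Modes are strict local maxima of the
#' gridded density whose topographic prominence exceeds
#' `min_prominence * max(density)`, suppressing noise wiggles.
#'
#' @param values numeric vector, at least 5 finite values.
#' @param bandwidth kernel standard deviation; default Silverman.
#' @param n_grid grid resolution (default 512).
#' @param min_prominence mode prominence threshold as a fraction of the
#'   density maximum (default 0.01).
#' @return a `density_estimate`: list with `grid`, `density`, `bandwidth`,
#'   `modes` (mode locations, ascending) and `n`.
#' @export
gaussian_kde <- function(values, bandwidth = NULL, n_grid = 512L,
                         min_prominence = 0.01) {
  x <- values[is.finite(values)]
  if (length(x) < 5L) pb_stop("kde_input_error", "need >= 5 finite values")
  if (stats::sd(x) == 0)
    pb_stop("degenerate_density_error", "all values identical; density degenerate")
  h <- bandwidth %||% stats::bw.nrd0(x)
  d <- stats::density(x, bw = h, kernel = "gaussian", n = n_grid, cut = 3)
  modes <- density_modes(d$x, d$y, min_prominence)
  structure(list(grid = d$x, density = d$y, bandwidth = h,
                 modes = modes, n = length(x)),
            class = "density_estimate")
}

# Local maxima of a gridded curve filtered by topographic prominence:
# a peak's prominence is its height minus the highest of the two lowest
# valleys separating it from higher ground (or from the grid edge).
density_modes <- function(grid, y, min_prominence) {
  n <- length(y)
  peak <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] & y[-c(1L, n)] > y[-(1:2)]) + 1L
  if (!length(peak)) return(numeric())
  thr <- min_prominence * max(y)
  keep <- vapply(peak, function(i) {
    left <- y[seq_len(i)]
    higher_l <- which(left > y[i])
    valley_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- y[i:n]
    higher_r <- which(right > y[i])
    valley_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    # prominence relative to the higher side's saddle
    min_side <- if (length(higher_l) && length(higher_r)) max(valley_l, valley_r)
                else if (length(higher_l)) valley_l
                else if (length(higher_r)) valley_r
                else min(valley_l, valley_r)
    (y[i] - min_side) >= thr
  }, TRUE)
  sort(grid[peak[keep]])
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> n = %d, bandwidth = %.4g, modes at %s\n",
              x$n, x$bandwidth, paste(signif(x$modes, 3), collapse = ", ")))
  invisible(x)
}

new_correlation_result <- function(r, p, n, controlled_for = NA_character_) {
  structure(list(r = r, p = p, n = n, controlled_for = controlled_for),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  ctl <- if (is.na(x$controlled_for)) "" else paste0(" | ", x$controlled_for)
  cat(sprintf("<correlation_result> r%s = %.3f, p = %.3g, n = %d\n",
              ctl, x$r, x$p, x$n))
  invisible(x)
}

#' Pearson correlation with a two-sided t test
#'
#' @param x,y equal-length finite numeric vectors, n >= 3.
#' @return a `correlation_result` with `r`, two-sided `p` (t transform,
#'   n - 2 df) and `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) pb_stop("input_error", "x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) pb_stop("input_error", "need n >= 3 finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    pb_stop("zero_variance_error", "zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_correlation_result(unname(ct$estimate), ct$p.value, n)
}

#' First-order partial correlation
#'
#' Correlation of `x` and `y` after removing the linear effect of `z`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' two-sided p-value from the t transform on n - 3 degrees of freedom.
#' Equivalent to correlating the residuals of the least-squares fits
#' `x ~ z` and `y ~ z`.
#'
#' @param x,y,z equal-length numeric vectors, n >= 4.
#' @param controlled_for label for the controlling variable (default "z").
#' @return a `correlation_result`.
#' @export
partial_correlation <- function(x, y, z, controlled_for = "z") {
  if (length(x) != length(y) || length(x) != length(z))
    pb_stop("input_error", "x, y, z differ in length")
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) pb_stop("input_error", "need n >= 4 finite observations")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (!is.finite(rxz) || !is.finite(ryz) ||
      abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    pb_stop("degenerate_partial_error",
            "a controlling correlation is +/-1; partial correlation undefined")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(max(r, -1), 1)
  df <- n - 3L
  tstat <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), df)
  new_correlation_result(r, p, n, controlled_for)
}

#' Regression of buffering strength on Ks
#'
#' Ordinary least squares of buffering strength (the negative interaction
#' score of buffering pairs) on synonymous divergence Ks, restricted to
#' pairs with `ks <= ks_max` because synonymous substitutions saturate
#' beyond that (default 2). The slope measures how much buffering strength
#' is lost per unit of Ks, the neutral-decay rate.
#'
#' @param pairs data.frame with columns `strength` (or `score`) and `ks`.
#' @param ks_max saturation filter threshold, default 2.
#' @return a `regression_fit`: list with `slope`, `intercept`, `r`, `p`,
#'   `n`, `ks_max`.
#' @export
strength_ks_regression <- function(pairs, ks_max = 2) {
  strength <- pairs$strength %||% pairs$score
  if (is.null(strength)) pb_stop("input_error", "pairs need a strength/score column")
  ks <- pairs$ks
  ok <- is.finite(strength) & is.finite(ks) & ks <= ks_max
  if (sum(ok) < 3L)
    pb_stop("saturation_filter_error", sprintf(
      "fewer than 3 pairs remain after the ks <= %g saturation filter", ks_max))
  x <- ks[ok]; y <- strength[ok]
  fit <- stats::lm(y ~ x)
  ct <- pearson_test(x, y)
  structure(list(slope = unname(stats::coef(fit)[[2L]]),
                 intercept = unname(stats::coef(fit)[[1L]]),
                 r = ct$r, p = ct$p, n = sum(ok), ks_max = ks_max),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> strength = %.3f * Ks %+.3f (r = %.3f, p = %.3g, n = %d, Ks <= %g)\n",
              x$slope, x$intercept, x$r, x$p, x$n, x$ks_max))
  invisible(x)
}

#' Neutral-mode report for a set of buffering pairs
#'
#' Bundles the neutral-decay diagnostics for buffering pairs carrying
#' strength, Ka and Ks: the partial correlation of Ks with strength
#' controlling for Ka (expected significant under neutral decay), the
#' partial correlation of Ka with strength controlling for Ks (expected
#' absent), the strength-vs-Ks regression under the saturation filter, and
#' the Ks kernel-density mode list (bimodality separates transient young
#' pairs from selectively stabilized ancient ones).
#'
#' @param pairs data.frame with columns `strength` (or `score`), `ka`, `ks`.
#' @param ks_max saturation threshold for the regression, default 2.
#' @param kde_bandwidth optional bandwidth for the Ks density.
#' @return list with `partial_ks_strength`, `partial_ka_strength`,
#'   `regression`, `ks_density` (or NULL when too few values), `n`.
#' @export
neutral_mode_report <- function(pairs, ks_max = 2, kde_bandwidth = NULL) {
  if (is.null(pairs) || !nrow(pairs))
    pb_stop("empty_input_error", "no pairs supplied")
  strength <- pairs$strength %||% pairs$score
  ok <- is.finite(strength) & is.finite(pairs$ka) & is.finite(pairs$ks)
  sub <- data.frame(strength = strength[ok], ka = pairs$ka[ok], ks = pairs$ks[ok])
  unsat <- sub[sub$ks <= ks_max, ]
  list(
    partial_ks_strength = partial_correlation(unsat$ks, unsat$strength,
                                              unsat$ka, controlled_for = "ka"),
    partial_ka_strength = partial_correlation(unsat$ka, unsat$strength,
                                              unsat$ks, controlled_for = "ks"),
    regression = strength_ks_regression(sub, ks_max = ks_max),
    ks_density = if (sum(is.finite(sub$ks)) >= 5L && stats::sd(sub$ks) > 0)
      gaussian_kde(sub$ks, bandwidth = kde_bandwidth) else NULL,
    n = nrow(sub)
  )
}
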