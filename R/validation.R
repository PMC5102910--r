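# Agreement statistics between two sets of paired parameter estimates
# (e.g. manual vs automated, or ground truth vs recovered).

#' Bland-Altman agreement analysis
#'
#' For each pair the average `x_i = (m_i + a_i)/2` gives a Z-score
#' `Z_i = (x_i - mean(x)) / sd(x)` and a percent difference
#' `Xi_i = (a_i - m_i) / x_i * 100`. The 95% interval of agreement is
#' `mean(Xi) +/- 1.96 sd(Xi)`. Negative `Xi` means the first (manual)
#' estimate exceeds the second (automated). Pairs with `x_i = 0` are
#' excluded and flagged. Sample (n-1) standard deviations throughout.
#'
#' @param manual,auto Paired numeric vectors of equal length.
#' @return Object of class `catrace_agreement`: per-pair tibble (`manual`,
#'   `auto`, `x`, `z_score`, `pct_diff`) plus `mean_pct_diff`, `loa_low`,
#'   `loa_high`, `slope`, `r2`, `n_used`, `flags`.
#' @export
#' @examples
#' ba <- bland_altman(c(10, 20), c(12, 18))
#' ba$pairs$pct_diff  # +18.18, -10.53
bland_altman <- function(manual, auto) {
  stopifnot(length(manual) == length(auto))
  ok <- is.finite(manual) & is.finite(auto)
  flags <- character(0)
  if (!all(ok)) flags <- c(flags, "nonfinite_pairs_dropped")
  m <- manual[ok]
  a <- auto[ok]
  x <- (m + a) / 2
  nz <- x != 0
  if (!all(nz)) flags <- c(flags, "zero_mean_pairs_dropped")
  m <- m[nz]; a <- a[nz]; x <- x[nz]

  z <- if (sd0(x) > 0) (x - mean(x)) / sd0(x) else rep(0, length(x))
  xi <- (a - m) / x * 100
  mean_xi <- mean(xi)
  s_xi <- sd0(xi)
  cs <- correlation_summary(m, a)

  structure(list(
    pairs = tibble::tibble(manual = m, auto = a, x = x, z_score = z,
                           pct_diff = xi),
    mean_pct_diff = mean_xi,
    loa_low = mean_xi - 1.96 * s_xi,
    loa_high = mean_xi + 1.96 * s_xi,
    slope = cs$slope, r2 = cs$r2,
    n_used = length(x), flags = flags
  ), class = "catrace_agreement")
}

#' Correlation summary of paired estimates
#'
#' Ordinary least-squares slope of the second input on the first and the
#' squared Pearson correlation; deviation of the slope from the line of
#' equality `y = x` measures proportional bias.
#'
#' @param manual,auto Paired numeric vectors.
#' @return List with `slope` and `r2` (`NaN` flagged for constant input).
#' @export
correlation_summary <- function(manual, auto) {
  stopifnot(length(manual) == length(auto))
  ok <- is.finite(manual) & is.finite(auto)
  m <- manual[ok]
  a <- auto[ok]
  if (length(m) < 2L || sd0(m) == 0) {
    return(list(slope = NA_real_, r2 = NaN))
  }
  slope <- coef(lm(a ~ m))[[2L]]
  r <- stats::cor(m, a)
  list(slope = slope, r2 = r^2)
}

#' @export
print.catrace_agreement <- function(x, ...) {
  cat("<catrace_agreement> n =", x$n_used, "\n")
  cat(sprintf("  mean %% difference: %.2f%%  [95%% LoA %.2f%%, %.2f%%]\n",
              x$mean_pct_diff, x$loa_low, x$loa_high))
  cat(sprintf("  slope: %.3f   r^2: %.3f\n", x$slope, x$r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `catrace_agreement`.
#' @param ... Unused.
#' @export
tidy.catrace_agreement <- function(x, ...) {
  x$pairs
}

#' @rdname bland_altman
#' @export
glance.catrace_agreement <- function(x, ...) {
  tibble::tibble(mean_pct_diff = x$mean_pct_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, slope = x$slope, r2 = x$r2,
                 n = x$n_used)
}

#' Bland-Altman plot
#'
#' Percent difference against the Z-score of the pair average, with the
#' mean difference and 95% limits of agreement.
#'
#' @param object A `catrace_agreement`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot catrace_agreement
#' @export
autoplot.catrace_agreement <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$z_score, y = .data$pct_diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_pct_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Z-score of pair average",
                  y = "Percent difference (auto - manual)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}
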