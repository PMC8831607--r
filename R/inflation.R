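#' Genomic inflation factor
#'
#' The median-based lambda: each p-value is converted to a 1-df chi-square
#' quantile, and lambda is the ratio of the median of those statistics to the
#' null chi-square median (0.4549364). Lambda near 1 indicates the bulk of
#' the test statistics behaves as under the null; lambda well above 1 flags
#' systematic inflation (stratification, coverage or genotyping bias), and
#' below 1 deflation.
#'
#' Note that two-sided exact-test p-values are discrete and conservative, so
#' lambda computed on them is biased downward at small carrier counts; for
#' calibration diagnostics of a `burden_result` use [inflation_diagnostics()]
#' which defaults to mid-p values.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return lambda (positive scalar), a pure function of the multiset of
#'   p-values.
#' @export
genomic_lambda <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' QQ coordinates with order-statistic bands
#'
#' Expected quantiles for rank i of n follow the uniform order-statistic
#' approximation i/(n+1); the 2.5th/97.5th percentile envelopes are
#' Beta(i, n - i + 1) quantiles. All coordinates are on the -log10 scale,
#' observed values sorted most-significant first.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return list of class `qq_result`: `lambda`, `n`, and `qq` (data.frame
#'   `expected`, `observed`, `band_lower`, `band_upper`).
#' @export
qq_with_bands <- function(pvals) {
  lam <- genomic_lambda(pvals)   # also validates input
  n <- length(pvals)
  i <- seq_len(n)
  qq <- data.frame(
    expected = -log10(i / (n + 1)),
    observed = -log10(sort(pvals)),
    band_lower = -log10(stats::qbeta(0.975, i, n - i + 1)),
    band_upper = -log10(stats::qbeta(0.025, i, n - i + 1)))
  structure(list(lambda = lam, n = n, qq = qq), class = "qq_result")
}

#' @export
print.qq_result <- function(x, ...) {
  cat(sprintf("<qq_result> %d p-values, lambda = %.3f\n", x$n, x$lambda))
  invisible(x)
}

#' QQ plot of a `qq_result`
#'
#' Observed versus expected -log10 p with the identity line and the
#' 2.5th/97.5th percentile order-statistic envelope. The computed
#' coordinates, not the figure, are the tested artifact.
#'
#' @param x a `qq_result`.
#' @param ... passed to [plot()].
#' @export
plot.qq_result <- function(x, ...) {
  q <- x$qq
  plot(q$expected, q$observed, pch = 20, cex = 0.6,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       main = sprintf("lambda = %.2f", x$lambda), ...)
  graphics::abline(0, 1, col = "blue")
  ord <- order(q$expected)
  graphics::lines(q$expected[ord], q$band_lower[ord], col = "goldenrod")
  graphics::lines(q$expected[ord], q$band_upper[ord], col = "darkgreen")
  invisible(x)
}

#' Inflation diagnostics for a burden scan
#'
#' Computes lambda and QQ coordinates from a [collapse_and_test()] result.
#' By default the mid-p values are used: the exact test's discreteness
#' otherwise deflates lambda well below 1 on a calibrated null, masking true
#' inflation (the mid-p correction restores a near-uniform null). Genes
#' without any qualifying variant (p exactly 1 with zero carriers) can be
#' dropped with `tested_only`, since their constant p-values carry no
#' calibration information; inclusion materially shifts lambda.
#'
#' @param result a `burden_result` data.frame.
#' @param use_midp use mid-p (default) rather than the raw two-sided p.
#' @param tested_only restrict to genes with at least one carrier (default
#'   TRUE).
#' @return A `qq_result` (see [qq_with_bands()]).
#' @export
inflation_diagnostics <- function(result, use_midp = TRUE,
                                  tested_only = TRUE) {
  stopifnot(inherits(result, "burden_result"))
  r <- result
  if (tested_only)
    r <- r[r$case_carriers + r$control_carriers > 0, , drop = FALSE]
  if (!nrow(r)) stop("no tested genes")
  p <- if (use_midp) r$p_mid else r$p_value
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  qq_with_bands(p)
}
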