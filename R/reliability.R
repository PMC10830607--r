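#' Single-score two-way agreement intraclass correlation, ICC(2,1)
#'
#' Inter-coder reliability of continuous measurements (durations, latencies)
#' under the two-way random-effects, absolute-agreement, single-score model:
#' both subjects (coded items) and raters (coders) are treated as random
#' samples, and systematic differences between coders count against
#' agreement. Computed from the two-way ANOVA mean squares
#' (subjects MSR, raters MSC, residual MSE):
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + k(MSC - MSE)/n}}
#' with `n` subjects and `k` raters. The significance test is
#' `F = MSR / MSE` on `(n - 1, (n - 1)(k - 1))` degrees of freedom, and the
#' confidence interval is the standard F-based interval for this estimator
#' (Satterthwaite degrees of freedom for the lower/upper bounds).
#'
#' Rows (subjects) with any missing cell are dropped listwise with a
#' message; a degenerate matrix (zero variance everywhere) yields an
#' undefined (`NA`) estimate.
#'
#' @param m numeric matrix or data.frame, subjects in rows, raters/coders in
#'   columns; at least 2 rows and 2 columns after dropping incomplete rows.
#' @param confidence confidence level for the interval, default 0.95.
#' @return list of class `"icc2"`: `icc`, `lower`, `upper`, `fvalue`, `df1`,
#'   `df2`, `pvalue`, `n`, `k`, `ms` (the three mean squares),
#'   `n_dropped`.
#' @examples
#' set.seed(1)
#' a <- rnorm(10); icc2Single(cbind(a, a))$icc  # identical coders: 1
#' @export
icc2Single <- function(m, confidence = 0.95) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " incomplete subject row(s) dropped before ICC")
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("ICC requires at least 2 complete subjects and 2 raters")

  ## two-way ANOVA mean squares, computed directly from the cell means
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (abs(denom) < .Machine$double.eps * max(1, abs(msr)))
    NA_real_ else (msr - mse) / denom

  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fvalue <- if (mse == 0 && msr == 0) NA_real_ else msr / mse  # Inf if mse = 0
  pvalue <- if (is.na(fvalue)) NA_real_ else
    stats::pf(fvalue, df1, df2, lower.tail = FALSE)

  alpha <- 1 - confidence
  lower <- upper <- NA_real_
  if (!is.na(icc) && !is.na(fvalue)) {
    ## F-based interval with Satterthwaite df for the between-rater term
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  structure(list(icc = icc, lower = lower, upper = upper, fvalue = fvalue,
                 df1 = df1, df2 = df2, pvalue = pvalue, n = n, k = k,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 n_dropped = n_dropped),
            class = "icc2")
}

#' @export
print.icc2 <- function(x, ...) {
  cat(sprintf("ICC(2,1), two-way random effects, absolute agreement, single score\n"))
  cat(sprintf("  %d subjects x %d raters (%d dropped incomplete)\n",
              x$n, x$k, x$n_dropped))
  if (is.na(x$icc)) {
    cat("  ICC undefined (degenerate ratings matrix)\n")
  } else {
    cat(sprintf("  ICC = %.3f, 95%% CI [%.3f, %.3f]\n", x$icc, x$lower, x$upper))
    cat(sprintf("  F(%d, %d) = %.2f, p = %.3g\n", x$df1, x$df2, x$fvalue,
                x$pvalue))
  }
  invisible(x)
}

#' Estimate and remove a systematic coder bias
#'
#' For paired measurements of the same items by a reference coder and a
#' second coder, the mean coding difference `d = mean(reference - other)` is
#' a systematic bias; adding it to the second coder's values aligns their
#' means exactly. Used to check whether an apparent group difference could be
#' explained by which coder coded which subset.
#'
#' @param reference numeric vector, the reference coder's values.
#' @param other numeric vector of equal length, the coder to adjust.
#' @param na.rm drop pairs with any missing value (default `TRUE`).
#' @return list: `mean_difference` (`d`), `adjusted` (`other + d`, same
#'   length as the input, missing pairs kept `NA`), `n_pairs`.
#' @examples
#' coderBiasAdjust(c(1, 2, 3), c(0.5, 1.5, 2.5))$mean_difference  # 0.5
#' @export
coderBiasAdjust <- function(reference, other, na.rm = TRUE) {
  if (length(reference) != length(other))
    stop("paired vectors must have equal length")
  if (length(reference) == 0L) stop("empty input")
  ok <- !(is.na(reference) | is.na(other))
  if (!na.rm && any(!ok)) stop("missing values in paired input")
  if (!any(ok)) stop("no complete pairs")
  d <- mean(reference[ok] - other[ok])
  list(mean_difference = d, adjusted = other + d, n_pairs = sum(ok))
}
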