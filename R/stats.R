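#' One-tailed unpaired (pooled-variance) t-test
#'
#' The classical two-sample Student t-test with pooled variance and a
#' one-sided alternative, as used for the spindle-length and MT-count
#' comparisons. Degenerate inputs (zero pooled variance) are flagged rather
#' than failing: equal means give p = 0.5, unequal means give p of 0 or 1
#' depending on the alternative.
#'
#' @param x,y numeric samples, each of length >= 2, finite.
#' @param alternative `"less"` (x shifted below y) or `"greater"`.
#' @param var_equal pool the variances (classical unpaired test, default);
#'   set `FALSE` for the Welch variant.
#' @return An object of class `ttest_result`: `t`, `df`, `p_one_tailed`,
#'   `alternative`, `n_x`, `n_y`, `degenerate`.
#' @export
one_tailed_unpaired_t <- function(x, y, alternative = c("less", "greater"),
                                  var_equal = TRUE) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 in each sample")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("samples must be finite")
  nx <- length(x); ny <- length(y)
  pooled_var <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (var_equal && pooled_var == 0) {
    dm <- mean(x) - mean(y)
    p <- if (dm == 0) 0.5
         else if (alternative == "less") as.numeric(dm < 0)
         else as.numeric(dm > 0)
    res <- list(t = if (dm == 0) 0 else sign(dm) * Inf, df = nx + ny - 2,
                p_one_tailed = p, alternative = alternative,
                n_x = nx, n_y = ny, degenerate = TRUE)
    return(structure(res, class = "ttest_result"))
  }
  tt <- stats::t.test(x, y, alternative = alternative, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_one_tailed = tt$p.value, alternative = alternative,
                 n_x = nx, n_y = ny, degenerate = FALSE),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("one-tailed unpaired t-test (alternative: x %s y)\n",
              if (x$alternative == "less") "<" else ">"))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g (n = %d vs %d)%s\n",
              x$t, x$df, x$p_one_tailed, x$n_x, x$n_y,
              if (x$degenerate) " [degenerate: zero pooled variance]" else ""))
  invisible(x)
}

#' Box-plot summary (median, quartiles, full-range whiskers)
#'
#' Matches the box-and-whisker convention used for the spindle-length plots:
#' the box spans the 25th-75th percentiles (linear-interpolation, type-7
#' quantiles), the median is marked, and the whiskers show the complete range.
#'
#' @param values numeric vector, length >= 1.
#' @return list of class `box_summary`: `median`, `q25`, `q75`, `min`, `max`, `n`.
#' @export
box_summary <- function(values) {
  if (length(values) < 1 || !all(is.finite(values))) stop("need >= 1 finite value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 min = min(values), max = max(values), n = length(values)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf("box summary (n = %d): min %.4g | q25 %.4g | median %.4g | q75 %.4g | max %.4g\n",
              x$n, x$min, x$q25, x$median, x$q75, x$max))
  invisible(x)
}
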