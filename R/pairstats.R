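#' Two-tailed paired t-test
#'
#' Baseline-vs-stimulation contrast on per-subject values:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `d = y - x` (sample sd, n-1
#' denominator), two-tailed p from the t distribution with n-1 df.
#' Pairs with a missing member are dropped (with a message), mirroring
#' the varying df across states when some subjects lack e.g. REM
#' epochs. Degenerate inputs: `sd(d) = 0` with non-zero mean yields an
#' infinite t with p = 0, flagged; `sd(d) = 0` with zero mean yields
#' t = 0, p = 1.
#'
#' @param x Per-subject values under condition A (baseline).
#' @param y Per-subject values under condition B (stimulation); same
#'   length.
#' @return A `paired_result`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_two_tailed`, `mean_difference`,
#'   `sem_difference`, `n_pairs`, `dropped`, `degenerate`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 4, 6))
#' @export
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  dropped <- sum(!ok)
  if (dropped > 0)
    message(dropped, " pair(s) with missing members dropped")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- y - x
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    degenerate <- TRUE
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- stats::t.test(y, x, paired = TRUE)
    tt <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(t_statistic = tt,
                 degrees_of_freedom = n - 1L,
                 p_two_tailed = p,
                 mean_difference = mean(d),
                 sem_difference = stats::sd(d) / sqrt(n),
                 n_pairs = n, dropped = dropped,
                 degenerate = degenerate),
            class = "paired_result")
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (two-tailed paired)%s\n",
              x$degrees_of_freedom, x$t_statistic, x$p_two_tailed,
              if (x$degenerate) "  [degenerate: sd(d) = 0]" else ""))
  cat(sprintf("  mean diff = %.4g +/- %.4g (SEM), n = %d\n",
              x$mean_difference, x$sem_difference, x$n_pairs))
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector (n >= 1).
#' @return List with `mean`, `sem` (`sd/sqrt(n)`; 0 when n = 1, with
#'   `sem_defined = FALSE`), `n`.
#' @examples
#' summarize_mean_sem(c(0, 2))  # mean 1, SEM 1
#' @export
summarize_mean_sem <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else 0,
       sem_defined = n > 1, n = n)
}

#' Benjamini-Hochberg adjustment of a results table
#'
#' Optional multiple-testing correction for a table of paired
#' contrasts; off by default in the pipeline, which mirrors the
#' uncorrected per-band reporting convention.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (`stats::p.adjust`, method "BH").
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
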