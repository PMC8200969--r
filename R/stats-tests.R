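# Statistical kernels implemented in-package so the fluctuation analytics do
# not silently depend on a library test's defaults; stats::wilcox.test and
# stats::t.test serve as independent references in the test suite only.

#' Comparison result container
#'
#' @param method `"wilcoxon_signed_rank"` or `"welch_t"`.
#' @param statistic test statistic (signed-rank V, or Welch t).
#' @param p_value two-sided p value (possibly multiplicity-adjusted).
#' @param n number of pairs (paired tests) or the two group sizes (unpaired).
#' @param adjusted whether `p_value` has been multiplicity-adjusted.
#' @param label free-text description of the contrast.
#' @return an object of class `comparison_result`; `significant` is
#'   `p_value < 0.05`.
#' @export
comparison_result <- function(method, statistic, p_value, n,
                              adjusted = FALSE, label = "") {
  method <- match.arg(method, c("wilcoxon_signed_rank", "welch_t"))
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_pairs_or_groups = n, significant = p_value < 0.05,
                 adjusted = isTRUE(adjusted), label = label),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s%s: stat %.4g, p %s%.4g (n %s)%s>\n", x$method,
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$statistic, if (x$adjusted) "adj " else "", x$p_value,
              paste(x$n_pairs_or_groups, collapse = "/"),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of the paired differences `x - y` (zeros dropped, average
#' ranks for ties). The null distribution is exact (via the signed-rank
#' distribution) for 25 or fewer nonzero pairs without ties, and a normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact null is used (default 25).
#' @return a [comparison_result()].
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  d <- (x - y)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(comparison_result("wilcoxon_signed_rank", 0, 1, 0L))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    mu <- n * (n + 1) / 4
    p <- if (V > mu)
      2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
    else
      2 * stats::psignrank(V, n)
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
  }
  comparison_result("wilcoxon_signed_rank", V, p, n)
}

#' Welch's two-sample t-test
#'
#' Unpaired, unequal-variance two-sided t-test with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param x,y numeric vectors (independent groups).
#' @return a [comparison_result()].
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("welch_t needs at least 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  tstat <- if (se2 == 0) 0 else (mean(x) - mean(y)) / sqrt(se2)
  df <- if (se2 == 0) nx + ny - 2 else
    se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  comparison_result("welch_t", tstat, p, c(nx, ny))
}

#' Holm step-down adjustment of a set of comparison results
#'
#' @param results list of [comparison_result()] objects.
#' @return the list with adjusted p values and `adjusted = TRUE`.
#' @export
holm_adjust <- function(results) {
  p <- vapply(results, function(r) r$p_value, numeric(1))
  padj <- stats::p.adjust(p, method = "holm")
  mapply(function(r, pa) {
    comparison_result(r$method, r$statistic, pa, r$n_pairs_or_groups,
                      adjusted = TRUE, label = r$label)
  }, results, padj, SIMPLIFY = FALSE)
}
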