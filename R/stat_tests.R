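#' Shared statistical-test primitive
#'
#' One entry point for the hypothesis tests used across the pipeline, all
#' returning the same light-weight result record. Tests are two-sided.
#'
#' \describe{
#'   \item{wilcoxon}{rank-sum test of \code{x} vs \code{y}
#'     (\code{\link[stats]{wilcox.test}}: exact for small tie-free samples,
#'     normal approximation with tie correction otherwise).}
#'   \item{chi2_yates}{Pearson chi-squared with Yates continuity correction on
#'     a 2x2 \code{table}; all margins must be positive.}
#'   \item{two_proportion_z}{pooled two-proportion z from successes
#'     \code{x = c(x1, x2)} and sizes \code{n = c(n1, n2)}; the signed z
#'     statistic is reported (positive when group 1's proportion is larger).}
#'   \item{pearson, spearman}{correlation tests on paired \code{x}, \code{y}.}
#' }
#'
#' @param kind test name, see Details.
#' @param x,y,table,n inputs as per \code{kind}.
#' @return A \code{test_result}: list with \code{statistic}, \code{p_value},
#'   \code{method}, \code{n}, and \code{estimate} where meaningful.
#' @export
stat_test <- function(kind = c("wilcoxon", "chi2_yates", "two_proportion_z",
                               "pearson", "spearman"),
                      x = NULL, y = NULL, table = NULL, n = NULL) {
  kind <- match.arg(kind)
  res <- switch(kind,
    wilcoxon = {
      if (length(unique(c(x, y))) == 1) {
        # fully tied samples carry no evidence of separation
        test_result(length(x) * length(y) / 2, 1, "wilcoxon",
                    c(length(x), length(y)))
      } else {
        ht <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
        test_result(unname(ht$statistic), ht$p.value, "wilcoxon",
                    c(length(x), length(y)))
      }
    },
    chi2_yates = {
      stopifnot(identical(dim(as.matrix(table)), c(2L, 2L)))
      tb <- as.matrix(table)
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
        stop("degenerate 2x2 table (zero margin): ",
             paste(tb, collapse = ","))
      ht <- suppressWarnings(stats::chisq.test(tb, correct = TRUE))
      test_result(unname(ht$statistic), ht$p.value, "chi2_yates", sum(tb))
    },
    two_proportion_z = {
      stopifnot(length(x) == 2, length(n) == 2, all(n > 0))
      p1 <- x[1] / n[1]; p2 <- x[2] / n[2]
      pbar <- sum(x) / sum(n)
      se <- sqrt(pbar * (1 - pbar) * (1 / n[1] + 1 / n[2]))
      z <- if (se == 0) 0 else (p1 - p2) / se
      test_result(z, 2 * stats::pnorm(-abs(z)), "two_proportion_z", n,
                  estimate = c(p1 = p1, p2 = p2))
    },
    pearson = ,
    spearman = {
      if (length(x) < 3) stop("need >= 3 pairs for a correlation test")
      ht <- suppressWarnings(stats::cor.test(x, y, method = kind))
      test_result(unname(ht$statistic), ht$p.value, kind, length(x),
                  estimate = unname(ht$estimate))
    })
  res
}

test_result <- function(statistic, p_value, method, n, estimate = NULL,
                        p_adjusted = NULL) {
  structure(list(statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, method = method, n = n,
                 estimate = estimate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g%s\n", x$method, x$statistic,
              x$p_value,
              if (!is.null(x$p_adjusted))
                sprintf(", p_adj = %.3g", x$p_adjusted) else ""))
  invisible(x)
}

#' Multiple-testing adjustment over a family of test results
#'
#' @param results list of \code{test_result}s.
#' @param method \code{"bonferroni"} or \code{"BH"}
#'   (Benjamini-Hochberg), via \code{\link[stats]{p.adjust}}.
#' @return the list with \code{p_adjusted} filled in.
#' @export
adjust_family <- function(results, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  p <- vapply(results, `[[`, 0, "p_value")
  padj <- stats::p.adjust(p, method = method)
  for (i in seq_along(results)) results[[i]]$p_adjusted <- padj[i]
  results
}
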