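#' Hypergeometric point probability
#'
#' Probability of drawing exactly `k` marked items in `n` draws without
#' replacement from a population of `N` items of which `K` are marked:
#' `choose(K, k) * choose(N - K, n - k) / choose(N, n)`. Computed in log
#' space via `lchoose()` so large tables do not overflow. Values of `k`
#' outside the support return 0 (not an error): this is the kernel of the
#' exact 2x2 test, where out-of-support cells simply have no mass.
#'
#' @param k Number of marked items drawn (vectorised).
#' @param N Population size.
#' @param K Number of marked items in the population.
#' @param n Number of draws.
#' @return Numeric vector of probabilities, same length as `k`.
#' @examples
#' hypergeom_point_prob(1, N = 20, K = 10, n = 10)  # 100 / choose(20, 10)
#' @export
hypergeom_point_prob <- function(k, N, K, n) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L) {
    abort_validation("N, K and n must be scalars")
  }
  if (K < 0 || K > N || n < 0 || n > N) {
    abort_validation("need 0 <= K <= N and 0 <= n <= N")
  }
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  out <- numeric(length(k))
  ok <- k >= lo & k <= hi & k == round(k)
  if (any(ok)) {
    kk <- k[ok]
    out[ok] <- exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
  }
  out
}

#' Exact test of association in a 2x2 table
#'
#' Fisher's exact test computed from hypergeometric point probabilities. The
#' two-sided p-value follows the minimum-likelihood rule: it sums the point
#' probabilities of every table with the observed margins whose probability
#' does not exceed that of the observed table (ties resolved with relative
#' tolerance `1e-7`), the convention used by the common exact-test
#' calculators. One-sided tail probabilities in both directions and the
#' sample odds ratio `ad/bc` are also returned (`Inf` when `bc = 0`).
#'
#' The table is laid out rows = group, columns = lesion / no lesion:
#' \preformatted{        lesion  no lesion
#'  group A    a        b
#'  group B    c        d }
#'
#' @param a,b,c,d Non-negative integer cell counts; alternatively `a` may be
#'   a 2x2 matrix and `b`, `c`, `d` omitted.
#' @return An object of class `cna_fisher`: a list with `p_two_sided`,
#'   `p_one_sided_greater` (upper tail on `a`), `p_one_sided_less`,
#'   `odds_ratio` and `table`. [generics::tidy()] converts it to a one-row
#'   tibble.
#' @examples
#' fisher_exact(10, 34, 14, 412)   # lesion enrichment in group A
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) abort_validation("table must be 2x2")
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (length(cells) != 4L || anyNA(cells) || any(cells < 0) ||
      any(cells != round(cells))) {
    abort_validation("cells a, b, c, d must be non-negative integers")
  }
  if (sum(cells) == 0) abort_validation("all-zero table")

  N <- a + b + c + d
  n1 <- a + b      # row-1 margin
  c1 <- a + c      # column-1 margin
  lo <- max(0, n1 + c1 - N)
  hi <- min(n1, c1)
  support <- lo:hi
  logp <- lchoose(c1, support) + lchoose(N - c1, n1 - support) - lchoose(N, n1)
  p <- exp(logp)
  p_obs <- p[support == a]
  p_two <- min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
  p_greater <- min(1, sum(p[support >= a]))
  p_less <- min(1, sum(p[support <= a]))
  odds_ratio <- if (b * c == 0) Inf else (a * d) / (b * c)

  structure(
    list(p_two_sided = p_two,
         p_one_sided_greater = p_greater,
         p_one_sided_less = p_less,
         odds_ratio = odds_ratio,
         table = matrix(c(a, c, b, d), nrow = 2,
                        dimnames = list(group = c("A", "B"),
                                        status = c("lesion", "no_lesion")))),
    class = "cna_fisher"
  )
}

#' @export
print.cna_fisher <- function(x, ...) {
  cat("Exact 2x2 association test (minimum-likelihood two-sided rule)\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g\n", x$odds_ratio))
  cat(sprintf("p (two-sided) = %.4g;  p (upper tail) = %.4g;  p (lower tail) = %.4g\n",
              x$p_two_sided, x$p_one_sided_greater, x$p_one_sided_less))
  invisible(x)
}

#' Tidy an exact-test result
#'
#' @param x A `cna_fisher` object from [fisher_exact()] or
#'   [associate_lesions()].
#' @param ... Unused.
#' @return One-row tibble with the cell counts, odds ratio and p-values.
#' @export
tidy.cna_fisher <- function(x, ...) {
  tibble(a = x$table[1, 1], b = x$table[1, 2],
         c = x$table[2, 1], d = x$table[2, 2],
         estimate = x$odds_ratio,
         p.value = x$p_two_sided,
         p.greater = x$p_one_sided_greater,
         p.less = x$p_one_sided_less)
}

#' @rdname tidy.cna_fisher
#' @export
glance.cna_fisher <- function(x, ...) tidy(x, ...)
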