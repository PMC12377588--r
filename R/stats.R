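#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Computes the two-sided p-value by the minimum-likelihood rule: with the
#' margins fixed, sum the hypergeometric probabilities of every admissible
#' table whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7). The odds ratio is the sample odds
#' ratio (a*d)/(b*c), reported as `Inf` when b*c = 0 and a*d > 0 (and 0 in
#' the mirror case). A table with a zero margin carries no information:
#' p = 1 and the odds ratio is undefined (`NA`, flagged).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Object of class `enrichment_result`: list with `table`,
#'   `odds_ratio`, `p_value`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("`tab` must be a 2x2 matrix", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    res <- list(table = tab, odds_ratio = NA_real_, p_value = 1, degenerate = TRUE)
    class(res) <- "enrichment_result"
    return(res)
  }
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  # a non-degenerate table cannot have both cross products zero
  ad <- a * d; bc <- b * c_
  odds <- if (bc == 0) Inf else if (ad == 0) 0 else ad / bc
  res <- list(table = tab, odds_ratio = odds, p_value = p, degenerate = FALSE)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> OR = %.4g, two-sided Fisher p = %.3g%s\n",
              x$odds_ratio, x$p_value, if (x$degenerate) " (degenerate margins)" else ""))
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Wilson score interval by default: good coverage at small counts and
#' never leaves [0, 1]. The Clopper-Pearson "exact" interval is available
#' via `method = "clopper-pearson"` (delegates to [stats::binom.test()]).
#' Vectorised over `k` (and `n` of matching length).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return Data frame with columns `k`, `n`, `point`, `lower`, `upper`,
#'   `level`, `method`.
#' @export
binomial_ci <- function(k, n, level = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (length(n) == 1L) n <- rep(n, length(k))
  stopifnot(length(k) == length(n))
  if (any(n < 1)) stop("`n` must be at least 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("`k` must satisfy 0 <= k <= n", call. = FALSE)
  check_scalar_number(level, "level", 0, 1)
  p <- k / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    lower <- pmax(0, centre - half)
    upper <- pmin(1, centre + half)
  } else {
    ci <- vapply(seq_along(k),
                 function(i) stats::binom.test(k[i], n[i], conf.level = level)$conf.int,
                 numeric(2))
    lower <- ci[1, ]
    upper <- ci[2, ]
  }
  data.frame(k = k, n = n, point = p, lower = lower, upper = upper,
             level = level, method = method, stringsAsFactors = FALSE)
}
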