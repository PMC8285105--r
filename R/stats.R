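## evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Wilcoxon--Mann--Whitney rank-sum test
#'
#' Exact enumeration (via the null distribution of the U statistic) when
#' `min(n, m) <= 8` and there are no ties; tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y numeric samples (both nonempty).
#' @param sides `"two"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (the U statistic for `x`) and `p`.
#' @export
rank_sum <- function(x, y, sides = c("two", "less", "greater")) {
  sides <- match.arg(sides)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (length(unique(c(x, y))) == 1)  # fully tied: no evidence either way
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  alternative <- switch(sides, two = "two.sided", less = "less",
                        greater = "greater")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 8
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Pearson correlation with t-distributed p-value
#'
#' @param x,y numeric vectors, `n >= 3`, finite, non-constant.
#' @return list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3 paired values")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p = res$p.value)
}

#' Benjamini--Hochberg false discovery rate adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (step-up BH).
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
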