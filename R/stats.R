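#' Nonparametric test toolkit
#'
#' Thin, tibble-returning wrappers around the classical nonparametric tests
#' used throughout the pipeline: Mann-Whitney U (exact enumeration for small
#' untied samples, tie-corrected normal approximation otherwise),
#' Kruskal-Wallis with tie correction, and Spearman rank correlation.
#' Results come back as one-row tibbles with a `method` label, group sizes
#' and an `exact` flag, so they can be row-bound into report tables.
#'
#' @param x,y Numeric vectors.
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"`.
#' @return A one-row tibble: `statistic`, `p_value`, `method`, `n1`, `n2`
#'   (or `n` / `df` where appropriate), `exact`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @name nonparam
NULL

#' @rdname nonparam
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1 || length(y) < 1) abort("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method = "Mann-Whitney U",
    n1 = length(x),
    n2 = length(y),
    exact = exact
  )
}

#' @rdname nonparam
#' @param groups A list of numeric vectors (one per group).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need a list of >= 2 groups")
  if (any(lengths(groups) < 1)) abort("every group must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  if (length(vals) < 3) abort("need at least 3 observations in total")
  if (length(unique(vals)) == 1) {
    # fully tied data: no rank variation, conventionally H = 0, p = 1
    return(tibble(
      statistic = 0, p_value = 1, method = "Kruskal-Wallis",
      n = length(vals), df = length(groups) - 1L, exact = FALSE
    ))
  }
  ht <- kruskal.test(groups)
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = "Kruskal-Wallis",
    n = length(vals),
    df = unname(ht$parameter),
    exact = FALSE
  )
}

#' @rdname nonparam
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("rank correlation undefined for constant input")
  exact <- length(x) <= 7 && !anyDuplicated(x) && !anyDuplicated(y)
  ht <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact)
  )
  tibble(
    r = unname(ht$estimate),
    p_value = ht$p.value,
    method = "Spearman rank correlation",
    n = length(x),
    exact = exact
  )
}
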