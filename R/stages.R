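#' The seven ordinal embryo-stage categories
#'
#' Freshly laid embryos are scored into seven ordered developmental
#' categories, from earliest cleavage to hatched larvae.
#'
#' @export
STAGE_CATEGORIES <- c("1-8 cell", "9-25 cell", ">26 cells pre-morphogenesis",
                      "comma", "two-fold", "three-fold", "hatched/L1")

#' Embryo-stage count distribution
#'
#' @param counts seven non-negative integer counts over the categories of
#'   [STAGE_CATEGORIES] in developmental order.
#' @return Object of class `"stage_distribution"`: named integer vector.
#' @export
stage_distribution <- function(counts) {
  if (length(counts) != 7L)
    stop("'counts' must have exactly 7 categories", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  structure(stats::setNames(as.integer(counts), STAGE_CATEGORIES),
            class = "stage_distribution")
}

#' @export
print.stage_distribution <- function(x, ...) {
  cat("Embryo stage distribution (n =", sum(x), "):\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Expand a stage distribution into per-embryo ordinal scores
#'
#' @param dist a [stage_distribution()].
#' @return Integer vector of ordinal codes 1..7 (1 = earliest), one per
#'   embryo; length equals the total count.
#' @examples
#' stage_scores(stage_distribution(c(2, 0, 0, 0, 0, 0, 1)))  # 1 1 7
#' @export
stage_scores <- function(dist) {
  stopifnot(inherits(dist, "stage_distribution"))
  rep(1:7, times = as.integer(dist))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison with midranks for ties. When both groups
#' have at most `exact_max` observations the p-value is exact, computed by
#' complete enumeration of all labelings of the pooled sample (the
#' permutation null conditional on the observed values, valid under ties);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric or ordinal vectors, each non-empty.
#' @param exact_max per-group size up to which the exact enumeration is
#'   used (default 10).
#' @return Object of class `c("rank_sum", "htest")` with the U statistic
#'   (for `x`), the two-sided p-value, the method used, and group sizes.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    method <- "exact"
    # distribution of U over all C(n1+n2, n1) labelings of the pooled ranks
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    method <- "normal-approximation"
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(
    statistic = c(U = u_obs),
    p.value = p,
    method = paste0("Wilcoxon-Mann-Whitney rank-sum test (", method, ")"),
    alternative = "two.sided",
    parameter = c(n1 = n1, n2 = n2),
    data.name = paste(deparse(substitute(x)), "and", deparse(substitute(y)))),
    class = c("rank_sum", "htest"))
}

#' Compare two embryo-stage distributions
#'
#' Expands both count distributions to per-embryo ordinal scores and
#' applies the rank-sum test (ties across the seven categories handled by
#' midranks).
#'
#' @param d1,d2 [stage_distribution()] objects, each with at least one
#'   embryo.
#' @inheritParams rank_sum_test
#' @return A [rank_sum_test()] result.
#' @export
compare_stage_distributions <- function(d1, d2, exact_max = 10) {
  s1 <- stage_scores(d1); s2 <- stage_scores(d2)
  if (length(s1) == 0 || length(s2) == 0)
    stop("both distributions must contain at least one embryo", call. = FALSE)
  rank_sum_test(s1, s2, exact_max = exact_max)
}
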