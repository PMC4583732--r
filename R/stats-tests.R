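#' Median and interquartile range
#'
#' Median, first and third quartile by the linear-interpolation quantile
#' convention (R type 7).
#'
#' @param x numeric vector (NAs removed).
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("median_iqr of an empty vector", call. = FALSE)
  q <- quantile(x, probs = c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

mto_test <- function(statistic, p_value, method, n) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n = n), class = "mto_test")
}

#' @export
print.mto_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), " n =", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

#' Two-group rank-sum test
#'
#' Wilcoxon–Mann–Whitney rank-sum test with mid-ranks for ties, two-sided.
#' The convention used for the skewed per-visit cost comparisons between
#' funding strata. For small samples (at most `exact_limit` distinct group
#' assignments) the p-value is the exact two-sided permutation probability
#' of the mid-rank U statistic, which is valid under ties; larger samples
#' use the normal approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param exact_limit enumerate the permutation distribution when
#'   `choose(n, n_a)` is at most this (default 40000).
#' @return `mto_test` with the Mann–Whitney U statistic and two-sided p.
#' @export
rank_sum_test <- function(group_a, group_b, exact_limit = 40000) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a)
  nb <- length(group_b)
  if (na == 0L || nb == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  r <- rank(c(group_a, group_b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (choose(na + nb, na) <= exact_limit) {
    u_all <- apply(utils::combn(na + nb, na), 2, function(ix) {
      sum(r[ix]) - na * (na + 1) / 2
    })
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "Wilcoxon rank-sum (exact permutation, mid-ranks)"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)
    )
    p <- wt$p.value
    method <- "Wilcoxon rank-sum (normal approximation, continuity corrected)"
  }
  mto_test(u_obs, p, method, c(na, nb))
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic on an r x c contingency table, df = (r-1)(c-1),
#' upper-tail p, without continuity correction.
#'
#' @param contingency matrix of counts.
#' @return `mto_test` with the Pearson statistic and p-value.
#' @export
chi_square_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  expected <- outer(rowSums(contingency), colSums(contingency)) /
    sum(contingency)
  if (any(expected == 0)) {
    stop("zero expected count; merge sparse categories before testing",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  mto_test(ct$statistic, ct$p.value,
           "Pearson chi-square (no continuity correction)",
           rowSums(contingency))
}

#' Cuzick non-parametric test for trend across ordered groups
#'
#' Rank-based trend test: with group scores l_1 < ... < l_k (default
#' 1..k in the given order) and S_j the sum of mid-ranks in group j, the
#' statistic is T = sum l_j S_j, standardised by its null mean
#' E(T) = (N+1)/2 * sum n_j l_j and variance
#' Var(T) = (N+1)/12 * (N sum n_j l_j^2 - (sum n_j l_j)^2), with the usual
#' tie correction factor 1 - sum(t^3 - t)/(N^3 - N). Two-sided normal p.
#'
#' @param values numeric vector.
#' @param groups ordered factor (or vector coercible to one) giving each
#'   value's group; the factor level order defines the trend direction.
#' @param scores optional numeric group scores (default 1..k).
#' @return `mto_test` with the z statistic (sign = trend direction) and
#'   two-sided p.
#' @export
trend_test <- function(values, groups, scores = NULL) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok],
                              levels = if (is.factor(groups)) levels(groups)
                                       else unique(groups)))
  k <- nlevels(groups)
  if (k < 2) stop("trend test needs at least two ordered groups", call. = FALSE)
  if (is.null(scores)) scores <- seq_len(k)
  stopifnot(length(scores) == k)

  N <- length(values)
  r <- rank(values)                      # mid-ranks for ties
  n_j <- as.numeric(table(groups))
  l_obs <- scores[as.integer(groups)]
  T_stat <- sum(l_obs * r)
  L1 <- sum(n_j * scores)
  L2 <- sum(n_j * scores^2)
  e_t <- (N + 1) / 2 * L1
  v_t <- (N + 1) / 12 * (N * L2 - L1^2)
  ties <- table(values)
  tie_adj <- 1 - sum(ties^3 - ties) / (N^3 - N)
  v_t <- v_t * tie_adj
  if (v_t <= 0) stop("degenerate trend test (no variance)", call. = FALSE)
  z <- (T_stat - e_t) / sqrt(v_t)
  mto_test(z, 2 * pnorm(-abs(z)), "Cuzick rank test for trend", n_j)
}
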