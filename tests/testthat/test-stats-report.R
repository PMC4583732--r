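test_that("median_iqr uses the linear-interpolation convention", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("rank-sum test agrees with exact permutation enumeration for small n", {
  perm_p <- function(a, b) {
    # enumerate all assignments of the pooled values to group sizes
    pooled <- c(a, b)
    n <- length(pooled)
    na <- length(a)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2 # Mann-Whitney U
    combs <- utils::combn(n, na)
    u_all <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    mu <- na * (n - na) / 2
    mean(abs(u_all - mu) >= abs(w_obs - mu) - 1e-12)
  }

  # separated groups: exact two-sided value 2/70
  got <- rank_sum_test(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(got$p_value, 2 / 70)

  # identical groups: two-sided p = 1
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # random small cases, combined n <= 10, ties included: exact agreement
  set.seed(15)
  for (trial in 1:25) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    vals <- sample(1:6, na + nb, replace = TRUE) # heavy ties
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    got <- rank_sum_test(a, b)
    expect_equal(got$p_value, perm_p(a, b),
                 label = paste("a:", paste(a, collapse = ","),
                               "b:", paste(b, collapse = ",")))
    # symmetry: swapping groups leaves p unchanged
    expect_equal(got$p_value, rank_sum_test(b, a)$p_value)
  }

  # beyond the enumeration limit the normal approximation with continuity
  # correction takes over and tracks the exact path closely
  set.seed(19)
  a <- rlnorm(40, 6, 1)
  b <- rlnorm(45, 6.3, 1)
  big <- rank_sum_test(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(big$p_value, ref$p.value)
  expect_match(big$method, "normal approximation")

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("chi-square test reproduces hand-computed Pearson statistics", {
  # perfect separation: every observed-vs-expected term contributes 5
  sep <- chi_square_test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(sep$statistic, 20)

  # proportional table: statistic 0, p = 1
  prop <- chi_square_test(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "merge")

  p <- chi_square_test(matrix(c(199, 145, 266, 205), 2, byrow = TRUE))$p_value
  expect_equal(round(p, 1), 0.7)
})

test_that("trend test matches its permutation distribution and reduces sanely", {
  groups <- factor(rep(1:5, each = 6), levels = 1:5)
  set.seed(16)
  values <- as.numeric(groups) + rnorm(30, sd = 0.5)
  got <- trend_test(values, groups)
  expect_lt(got$p_value, 0.01)
  expect_gt(got$statistic, 0)

  # permutation oracle: p of the normal approximation tracks the
  # permutation p of the same statistic
  t_stat <- function(v, g) {
    r <- rank(v)
    sum(as.integer(g) * r)
  }
  obs <- t_stat(values, groups)
  set.seed(17)
  perm <- replicate(10000, t_stat(values, sample(groups)))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_lt(abs(got$p_value - p_perm), 0.01)

  # two groups: direction agrees with the rank-sum comparison
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  two <- trend_test(c(a, b), rep(c("lo", "hi"), each = 4))
  expect_gt(two$statistic, 0) # second group larger, positive trend
  expect_error(trend_test(1:5, rep("only", 5)), "two ordered groups")
})

test_that("p-values are valid and the null is calibrated for the trend test", {
  set.seed(18)
  groups <- factor(rep(1:4, each = 10))
  p <- replicate(200, trend_test(rnorm(40), groups)$p_value)
  expect_true(all(p >= 0 & p <= 1))
  # null rejection near 5%: binomial 3-sigma band around 0.05 at 200 reps
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("build_report emits the full deterministic bundle", {
  rec <- generate_survey(tiny_config(n_sub = 120, n_priv = 150, seed = 8))
  out <- withr::local_tempdir()
  rep1 <- suppressMessages(suppressWarnings(
    build_report(rec, B = 50, seed = 2, out_dir = out)))
  expect_true(all(c("demographics", "disease_profile", "visit_costs", "payer_breakdown", "catastrophic_by_group",
                    "economic_costs", "metadata", "summary_json") %in% names(rep1)))
  expect_true(all(file.exists(file.path(out, c(
    "demographics.csv", "disease_profile.csv", "visit_costs.csv", "payer_breakdown.csv", "catastrophic_by_group.csv",
    "economic_costs.csv", "summary.json", "report.log")))))

  # re-run with the same seed/config: byte-identical JSON summary
  rep2 <- suppressMessages(suppressWarnings(
    build_report(rec, B = 50, seed = 2)))
  expect_identical(as.character(rep1$summary_json),
                   as.character(rep2$summary_json))

  # disease-profile table excludes Z-chapter and reports the omitted count
  n_z <- sum(substr(rec$icd_code, 1, 1) == "Z")
  expect_identical(attr(rep1$disease_profile, "n_omitted"), n_z)
  expect_false(any(grepl("Z00", rep1$disease_profile$chapter)))

  # percentages within each categorical block sum to 100 (up to rounding)
  sex_block <- rep1$demographics[rep1$demographics$variable == "sex", ]
  expect_equal(sum(sex_block$pct_total), 100, tolerance = 0.2)
})
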