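#' Household health budget share
#'
#' The proportion of the monthly household budget spent out of pocket on
#' health: `health / (health + food + other)`. The denominator is the
#' household's routine monthly expenditure; episode costs of the overseas
#' visit are not amortized into it (see the methods vignette for the
#' optional amortization mode discussion).
#'
#' @param records survey tibble with `hh_health_month`, `hh_food_month`,
#'   `hh_other_month` (or pass the three vectors directly).
#' @param health,food,other monthly USD amounts, used when `records` is
#'   missing.
#' @return numeric vector of shares in `[0, 1]`.
#' @export
health_share <- function(records = NULL, health = NULL, food = NULL,
                         other = NULL) {
  if (!is.null(records)) {
    health <- records$hh_health_month
    food <- records$hh_food_month
    other <- records$hh_other_month
    ids <- records$id
  } else {
    ids <- seq_along(health)
  }
  total <- health + food + other
  zero <- !is.na(total) & total == 0
  if (any(zero)) {
    stop("total monthly expenditure is zero for household(s): ",
         paste(head(ids[zero], 5), collapse = ", "), call. = FALSE)
  }
  health / total
}

#' Catastrophic health expenditure statistics
#'
#' Computes, at threshold budget share `z`, the three standard measures:
#' * headcount `H`: fraction of households whose health budget share
#'   exceeds `z` (strict `>` by default; "in excess of" the threshold);
#' * overshoot `O`: mean over all households of `max(share - z, 0)`;
#' * mean positive overshoot `MPO = O / H`: the average excess among the
#'   exceeders, so `z + MPO` is the exceeders' mean budget share.
#'
#' `MPO` is undefined when no household exceeds the threshold; it is then
#' `NA` with `mpo_defined = FALSE`.
#'
#' @param shares numeric vector of household health budget shares.
#' @param z threshold budget share, in (0, 1); default 0.10.
#' @param strict logical; `TRUE` (default) counts shares strictly greater
#'   than `z`, `FALSE` uses `>=` for sensitivity analysis.
#' @return object of class `catastrophic_result`: a list with `n`, `z`,
#'   `H`, `O`, `MPO`, `mpo_defined`, and `exceeders` (indices).
#' @examples
#' catastrophic_stats(c(0.05, 0.15, 0.30, 0.08), z = 0.10)
#' @export
catastrophic_stats <- function(shares, z = 0.10, strict = TRUE) {
  stopifnot(z > 0, z < 1, length(shares) >= 1)
  exceed <- if (strict) shares > z else shares >= z
  n <- length(shares)
  H <- sum(exceed) / n
  O <- sum(pmax(shares - z, 0) * exceed) / n
  structure(list(
    n = n, z = z, H = H, O = O,
    MPO = if (H > 0) O / H else NA_real_,
    mpo_defined = H > 0,
    exceeders = which(exceed)
  ), class = "catastrophic_result")
}

#' @export
print.catastrophic_result <- function(x, ...) {
  cat(sprintf("Catastrophic health expenditure (z = %.0f%%, n = %d)\n",
              100 * x$z, x$n))
  cat(sprintf("  headcount H   : %.1f%%\n", 100 * x$H))
  cat(sprintf("  overshoot O   : %.1f points\n", 100 * x$O))
  if (x$mpo_defined) {
    cat(sprintf("  MPO (O/H)     : %.1f points (exceeder mean share %.1f%%)\n",
                100 * x$MPO, 100 * (x$z + x$MPO)))
  } else {
    cat("  MPO           : undefined (no exceeders)\n")
  }
  invisible(x)
}

#' Catastrophic incidence by subgroup
#'
#' Cross-tabulates households below/above the catastrophic threshold by a
#' grouping variable (funding stratum, region, household-size class or
#' income quintile), with row percentages and a chi-square test of
#' independence.
#'
#' @param records survey tibble (quintiles/size classes are derived on the
#'   fly when absent).
#' @param by one of `"stratum"`, `"region"`, `"hh_size_class"`,
#'   `"income_quintile"`.
#' @param z,strict threshold as in [catastrophic_stats()].
#' @return tibble with columns `group`, `n_below`, `n_above`, `pct_below`,
#'   `pct_above`, `n`; chi-square p-value in `attr(, "p_value")` (NA for a
#'   single group).
#' @export
catastrophic_subgroups <- function(records,
                                   by = c("stratum", "region",
                                          "hh_size_class", "income_quintile"),
                                   z = 0.10, strict = TRUE) {
  by <- match.arg(by)
  if (by == "hh_size_class" && is.null(records$hh_size_class)) {
    records <- categorize(records)
  }
  if (by == "income_quintile" && is.null(records$income_quintile)) {
    records <- bin_income_quintiles(records)
  }
  shares <- health_share(records)
  exceed <- if (strict) shares > z else shares >= z
  g <- as.character(records[[by]])
  keep <- !is.na(g)
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with missing group dropped", call. = FALSE)
  }
  tab <- table(g[keep], factor(exceed[keep], levels = c(FALSE, TRUE)))
  out <- tibble::tibble(
    group = rownames(tab),
    n_below = as.integer(tab[, 1]),
    n_above = as.integer(tab[, 2]),
    n = as.integer(rowSums(tab))
  )
  out$pct_below <- 100 * out$n_below / out$n
  out$pct_above <- 100 * out$n_above / out$n
  out <- out[, c("group", "n_below", "pct_below", "n_above", "pct_above", "n")]
  p <- if (nrow(out) >= 2 && all(colSums(tab) > 0)) {
    chi_square_test(unclass(as.matrix(tab)))$p_value
  } else NA_real_
  attr(out, "p_value") <- p
  out
}
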