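#' Annual caretaker visits from the mean party size
#'
#' Caretakers do not appear in the visit registers, so their annual visit
#' count is derived as mean caretakers per patient times the annual patient
#' visits, rounded half up to a whole count.
#'
#' @param mean_caretakers mean accompanying persons per patient.
#' @param patient_visits annual patient visits for the stratum.
#' @return integer-valued numeric count.
#' @examples
#' caretaker_visits(2.3, 3546) # 8156
#' @export
caretaker_visits <- function(mean_caretakers, patient_visits) {
  stopifnot(mean_caretakers >= 0, patient_visits >= 0)
  round_half_up(mean_caretakers * patient_visits)
}

#' Annual cost of a stratum
#'
#' `annual cost = median per-capita cost x annual visits`, computed exactly
#' in integer cents.
#'
#' @param median_pc median per-capita cost per visit, USD.
#' @param visits annual visit count.
#' @return annual cost, USD (exact to the cent).
#' @examples
#' stratum_annual_cost(965.25, 8156) # 7872579
#' @export
stratum_annual_cost <- function(median_pc, visits) {
  stopifnot(median_pc >= 0, visits >= 0)
  as_usd(as_cents(median_pc) * visits)
}

#' National totals over the four extrapolation strata
#'
#' Sums visits and annual costs over the four strata (patients and
#' caretakers in each funding group) and expresses the total against the
#' economy: share of GDP and cost per head of population.
#'
#' @param strata tibble with columns `label`, `visits`, `annual_cost`
#'   containing exactly the four strata
#'   `subsidized-patients`, `subsidized-caretakers`, `private-patients`,
#'   `private-caretakers` (any order).
#' @param gdp GDP, USD (default 1,431,000,000).
#' @param population persons (default 336,224).
#' @return list with `total_visits`, `total_cost`, `gdp_share_pct`,
#'   `per_capita_usd`.
#' @export
national_totals <- function(strata, gdp = 1431e6, population = 336224) {
  stopifnot(gdp > 0, population > 0)
  wanted <- c("subsidized-patients", "subsidized-caretakers",
              "private-patients", "private-caretakers")
  missing_strata <- setdiff(wanted, strata$label)
  if (length(missing_strata) > 0) {
    stop("missing stratum estimate(s): ",
         paste(missing_strata, collapse = ", "), call. = FALSE)
  }
  strata <- strata[strata$label %in% wanted, ]
  total_cost <- as_usd(sum(as_cents(strata$annual_cost)))
  list(
    total_visits = sum(strata$visits),
    total_cost = total_cost,
    gdp_share_pct = 100 * total_cost / gdp,
    per_capita_usd = total_cost / population
  )
}

#' Bootstrap standard error of an extrapolated annual cost
#'
#' Draws `B` resamples of size `n` with replacement from the per-capita
#' cost sample; each replicate's annual cost is its median times the
#' (fixed) visit count; the SE is the standard deviation across
#' replicates. Seeded and reproducible.
#'
#' @param per_capita_costs numeric sample of per-capita costs (n >= 2).
#' @param visits annual visit count the median is scaled by (use 1 for the
#'   SE of the median itself).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return standard error, USD.
#' @export
bootstrap_se <- function(per_capita_costs, visits, B = 1000, seed = 1) {
  n <- length(per_capita_costs)
  if (n < 2) stop("need at least 2 observations to bootstrap", call. = FALSE)
  stopifnot(B >= 2)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    median(per_capita_costs[sample.int(n, n, replace = TRUE)]) * visits
  }, numeric(1))
  sd(reps)
}

#' Median productivity loss with bootstrap SE
#'
#' Median over all travelers of the per-visit productivity loss, with a
#' bootstrap SE. Productivity loss is a loss rather than an expenditure:
#' it is reported alongside the annual cost table but never added into the
#' totals.
#'
#' @param records survey tibble.
#' @param B,seed bootstrap parameters as in [bootstrap_se()].
#' @return list with `median`, `q1`, `q3`, `se`.
#' @export
productivity_loss_summary <- function(records, B = 1000, seed = 1) {
  loss <- record_productivity_loss(records)
  mi <- median_iqr(loss)
  se <- if (length(loss) >= 2) bootstrap_se(loss, visits = 1, B = B,
                                            seed = seed) else 0
  list(median = unname(mi["median"]), q1 = unname(mi["q1"]),
       q3 = unname(mi["q3"]), se = se)
}

#' Economic cost extrapolation table
#'
#' Builds the four-stratum national extrapolation from survey records and
#' external annual patient-visit counts: per stratum the median per-capita
#' cost per visit (patients and caretakers separately, caretakers bearing
#' no medical costs), the annual visit count (caretaker visits derived from
#' the stratum's mean party size), the annual cost `a x b`, its bootstrap
#' SE (visits treated as fixed), and the share of GDP. Patient visit
#' counts come from administrative registers and are inputs, never
#' estimated here.
#'
#' @param records survey tibble with both strata present.
#' @param visits_subsidized,visits_private annual patient visits per
#'   stratum (external inputs).
#' @param caretaker_means optional named numeric (mean caretakers per
#'   stratum); defaults to the sample means in `records`.
#' @param gdp,population economy context as in [national_totals()].
#' @param B,seed bootstrap parameters.
#' @return list with `strata` (tibble: label, n, median_pc, q1, q3, visits,
#'   annual_cost, se, gdp_share_pct), `totals` (from [national_totals()],
#'   plus a summed bootstrap SE), and `productivity`
#'   (from [productivity_loss_summary()]).
#' @export
economic_cost_table <- function(records, visits_subsidized, visits_private,
                                caretaker_means = NULL,
                                gdp = 1431e6, population = 336224,
                                B = 1000, seed = 1) {
  stopifnot(all(c("subsidized", "private") %in% records$stratum))
  pc <- per_capita_costs(records)
  patient_visits <- c(subsidized = visits_subsidized,
                      private = visits_private)
  rows <- list()
  total_var_c <- 0
  for (str in c("subsidized", "private")) {
    in_str <- records$stratum == str
    n_str <- sum(in_str)
    k_mean <- if (!is.null(caretaker_means)) caretaker_means[[str]] else
      mean(records$n_caretakers[in_str])
    for (who in c("patients", "caretakers")) {
      x <- if (who == "patients") pc$patient_pc[in_str] else
        pc$caretaker_pc[in_str]
      visits <- if (who == "patients") patient_visits[[str]] else
        caretaker_visits(k_mean, patient_visits[[str]])
      mi <- median_iqr(x)
      se <- bootstrap_se(x, visits, B = B,
                         seed = stream_seed(seed, paste0("boot/", str, "/", who)))
      rows[[paste(str, who, sep = "-")]] <- tibble::tibble(
        label = paste(str, who, sep = "-"), n = n_str,
        median_pc = unname(mi["median"]), q1 = unname(mi["q1"]),
        q3 = unname(mi["q3"]), visits = visits,
        annual_cost = stratum_annual_cost(round_money(unname(mi["median"])),
                                          visits),
        se = se
      )
      total_var_c <- total_var_c + se^2
    }
  }
  strata <- dplyr::bind_rows(rows)
  strata$gdp_share_pct <- 100 * strata$annual_cost / gdp
  totals <- national_totals(strata, gdp = gdp, population = population)
  totals$se <- sqrt(total_var_c)
  list(strata = strata, totals = totals,
       productivity = productivity_loss_summary(records, B = B,
                                                seed = stream_seed(seed, "boot/productivity")))
}
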