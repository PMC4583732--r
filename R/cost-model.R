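#' Cost component columns
#'
#' The itemized per-episode cost columns of the survey schema. Only direct
#' medical care and the airfare can carry a government subsidy; every other
#' component is paid out of pocket by the household.
#'
#' @return character vector of the twelve cost column names.
#' @export
cost_columns <- function() {
  c("cost_medical_subsidy", "cost_medical_oop",
    "cost_travel_home_oop",
    "cost_airfare_subsidy", "cost_airfare_oop",
    "cost_travel_dest_oop",
    "cost_entertainment_oop", "cost_lodging_oop", "cost_food_oop",
    "cost_visa_oop", "cost_fx_oop", "cost_other_oop")
}

subsidy_columns <- function() c("cost_medical_subsidy", "cost_airfare_subsidy")
oop_columns <- function() setdiff(cost_columns(), subsidy_columns())

# component -> columns, with travel optionally collapsed into one group
component_map <- function(collapse_travel = TRUE) {
  base <- list(
    direct_medical = c("cost_medical_subsidy", "cost_medical_oop"),
    travel_home = "cost_travel_home_oop",
    airfare = c("cost_airfare_subsidy", "cost_airfare_oop"),
    travel_destination = "cost_travel_dest_oop",
    entertainment = "cost_entertainment_oop",
    lodging = "cost_lodging_oop",
    food = "cost_food_oop",
    visa = "cost_visa_oop",
    foreign_exchange = "cost_fx_oop",
    other = "cost_other_oop"
  )
  if (!collapse_travel) return(base)
  c(base["direct_medical"],
    list(travel = c("cost_travel_home_oop", "cost_airfare_subsidy",
                    "cost_airfare_oop", "cost_travel_dest_oop")),
    base[c("entertainment", "lodging", "food", "visa", "foreign_exchange",
           "other")])
}

sum_cents <- function(records, cols) {
  m <- as.matrix(records[, cols, drop = FALSE])
  rowSums(as_cents(m))
}

#' Total cost of a visit
#'
#' Sum of every itemized cost component over both payers (subsidy and
#' out-of-pocket), computed in integer cents. Productivity loss is a loss,
#' not an expenditure, and is never part of the total.
#'
#' @param records survey tibble (or any data frame with the [cost_columns()]).
#' @return numeric vector of per-traveler totals, USD.
#' @export
visit_total_cost <- function(records) {
  as_usd(sum_cents(records, cost_columns()))
}

#' Split a visit's cost by payer
#'
#' @param records survey tibble.
#' @return tibble with `subsidy_total`, `oop_total`, `subsidy_share`
#'   (subsidy / grand total; 0 with `share_defined = FALSE` when the grand
#'   total is 0). Totals are conserved: `subsidy_total + oop_total` equals
#'   [visit_total_cost()] exactly in cents.
#' @export
payer_split <- function(records) {
  sub_c <- sum_cents(records, subsidy_columns())
  oop_c <- sum_cents(records, oop_columns())
  tot_c <- sub_c + oop_c
  tibble::tibble(
    subsidy_total = as_usd(sub_c),
    oop_total = as_usd(oop_c),
    subsidy_share = ifelse(tot_c == 0, 0, sub_c / tot_c),
    share_defined = tot_c > 0
  )
}

#' Per-capita cost of the travel party
#'
#' Allocates the episode cost over the travel party (patient plus
#' caretakers). Caretakers bear no medical costs, so the direct medical
#' cost M goes entirely to the patient; the remaining non-medical cost G is
#' shared equally across the `n_caretakers + 1` party members:
#' `caretaker_pc = G / (k + 1)`, `patient_pc = M + G / (k + 1)`. The
#' identity `M + (k + 1) * caretaker_pc = total` holds for every k >= 0.
#'
#' @param records survey tibble with cost columns and `n_caretakers`.
#' @return tibble with `patient_pc` and `caretaker_pc`, USD.
#' @export
per_capita_costs <- function(records) {
  m_c <- sum_cents(records, c("cost_medical_subsidy", "cost_medical_oop"))
  g_c <- sum_cents(records, cost_columns()) - m_c
  share <- g_c / (records$n_caretakers + 1)
  tibble::tibble(
    patient_pc = as_usd(m_c) + as_usd(share),
    caretaker_pc = as_usd(share)
  )
}

#' Productivity loss of a visit
#'
#' Values the work time lost while abroad as
#' `(hours lost per day / working-day hours) * days abroad * daily income`,
#' i.e. hours are converted to a fraction of a working day (default 8 h)
#' and multiplied by days overseas and the self-reported daily wage.
#'
#' @param hours_per_day hours of work lost per day abroad, in 0–24.
#' @param days_abroad days spent overseas.
#' @param income_per_day self-reported income per day, USD.
#' @param workday_hours hours in a full working day (default 8).
#' @return numeric vector of losses, USD.
#' @examples
#' productivity_loss(8, 10, 20) # a full working day lost for 10 days: 200
#' @export
productivity_loss <- function(hours_per_day, days_abroad, income_per_day,
                              workday_hours = 8) {
  stopifnot(all(hours_per_day >= 0 & hours_per_day <= 24, na.rm = TRUE),
            all(days_abroad >= 0, na.rm = TRUE),
            all(income_per_day >= 0, na.rm = TRUE))
  round_money((hours_per_day / workday_hours) * days_abroad * income_per_day)
}

# convenience: loss per record from the survey columns
record_productivity_loss <- function(records, workday_hours = 8) {
  productivity_loss(records$prod_hours_per_day, records$los_days,
                    records$prod_income_per_day, workday_hours)
}

#' Mean cost-component shares
#'
#' For each component, the mean over travelers of that traveler's spend on
#' the component divided by the traveler's total (mean of per-traveler
#' ratios, which is scale-free, rather than ratio of means). Shares sum to
#' 1 over the full component set. Travelers with zero total have no defined
#' shares and are excluded with a warning.
#'
#' @param records survey tibble.
#' @param collapse_travel collapse home-country travel, airfare and
#'   destination travel into a single "travel" component (default TRUE).
#' @return tibble with `component` and `mean_share` (fractions summing to 1).
#' @export
component_shares <- function(records, collapse_travel = TRUE) {
  tot_c <- sum_cents(records, cost_columns())
  if (all(tot_c == 0)) stop("all travelers have zero total cost; shares undefined",
                            call. = FALSE)
  if (any(tot_c == 0)) {
    warning(sum(tot_c == 0), " traveler(s) with zero total excluded from shares",
            call. = FALSE)
    records <- records[tot_c > 0, , drop = FALSE]
    tot_c <- tot_c[tot_c > 0]
  }
  cmap <- component_map(collapse_travel)
  shares <- vapply(cmap, function(cols) {
    mean(sum_cents(records, cols) / tot_c)
  }, numeric(1))
  tibble::tibble(component = names(cmap), mean_share = unname(shares))
}

#' Per-traveler cost table
#'
#' One row per traveler with derived totals: total episode cost, payer
#' split, per-capita allocation, and productivity loss (reported alongside,
#' never inside, the total).
#'
#' @param records survey tibble.
#' @return tibble with columns `id`, `total`, `subsidy_total`, `oop_total`,
#'   `patient_pc`, `caretaker_pc`, `productivity_loss`.
#' @export
costs_table <- function(records) {
  split <- payer_split(records)
  pc <- per_capita_costs(records)
  tibble::tibble(
    id = records$id,
    total = visit_total_cost(records),
    subsidy_total = split$subsidy_total,
    oop_total = split$oop_total,
    patient_pc = pc$patient_pc,
    caretaker_pc = pc$caretaker_pc,
    productivity_loss = record_productivity_loss(records)
  )
}
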