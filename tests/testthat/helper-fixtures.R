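# Minimal valid survey rows built in code; override any field by name.
make_records <- function(n = 1, ...) {
  base <- tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    stratum = "private", sex = "female", age = 40,
    region = "Central", occupation = "other",
    household_size = 4, household_income_month = 1000,
    icd_code = "I25", destination = "India",
    los_days = 10, n_caretakers = 2, visits_per_year = 1,
    cost_medical_subsidy = 0, cost_medical_oop = 500,
    cost_travel_home_oop = 100, cost_airfare_subsidy = 0,
    cost_airfare_oop = 700, cost_travel_dest_oop = 100,
    cost_entertainment_oop = 100, cost_lodging_oop = 140,
    cost_food_oop = 105, cost_visa_oop = 0, cost_fx_oop = 0,
    cost_other_oop = 0,
    prod_hours_per_day = 0, prod_income_per_day = 30,
    hh_health_month = 100, hh_food_month = 500, hh_other_month = 400
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

tiny_config <- function(n_sub = 30, n_priv = 40, seed = 11, ...) {
  survey_config(n_subsidized = n_sub, n_private = n_priv, seed = seed, ...)
}

# brute-force catastrophic statistics, kept deliberately naive and separate
# from the implementation
brute_catastrophic <- function(shares, z, strict = TRUE) {
  n <- length(shares)
  exceed_count <- 0
  excess_sum <- 0
  for (s in shares) {
    over <- if (strict) s > z else s >= z
    if (over) {
      exceed_count <- exceed_count + 1
      excess_sum <- excess_sum + (s - z)
    }
  }
  H <- exceed_count / n
  O <- excess_sum / n
  list(H = H, O = O, MPO = if (exceed_count > 0) O / H else NA_real_)
}
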