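#' Survey CSV schema
#'
#' Column names and roles of the traveler-level survey CSV. One row is one
#' surveyed medical traveler; money columns are USD per episode except the
#' `hh_*_month` household budget columns (USD per month) and
#' `prod_income_per_day` (USD per day).
#'
#' @return character vector of the mandatory column names, in order.
#' @export
survey_columns <- function() {
  c("id", "stratum", "sex", "age", "region", "occupation",
    "household_size", "household_income_month", "icd_code", "destination",
    "los_days", "n_caretakers", "visits_per_year",
    cost_columns(),
    "prod_hours_per_day", "prod_income_per_day",
    "hh_health_month", "hh_food_month", "hh_other_month")
}

# closed vocabularies
stratum_levels <- function() c("subsidized", "private")
sex_levels <- function() c("female", "male")
region_levels <- function() c("North", "Central", "South")
occupation_levels <- function() {
  c("civil_servant", "private_sector", "own_business", "not_employed", "other")
}

survey_col_types <- function() {
  chr <- c("id", "stratum", "sex", "region", "occupation", "icd_code",
           "destination")
  types <- lapply(survey_columns(), function(nm) {
    if (nm %in% chr) readr::col_character() else readr::col_double()
  })
  do.call(readr::cols, setNames(types, survey_columns()))
}

# Validate one loaded tibble; returns character vector of reasons (one string
# per offending row, "" when valid).
validate_rows <- function(df) {
  money_cols <- c("household_income_month", cost_columns(),
                  "prod_income_per_day",
                  "hh_health_month", "hh_food_month", "hh_other_month")
  reason <- character(nrow(df))
  add <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    reason[bad] <<- ifelse(reason[bad] == "", msg, paste(reason[bad], msg, sep = "; "))
  }
  add(!df$stratum %in% stratum_levels(), "invalid stratum")
  add(!df$sex %in% sex_levels(), "invalid sex")
  add(!df$region %in% region_levels(), "invalid region")
  add(!df$occupation %in% occupation_levels(), "invalid occupation")
  add(df$age < 0, "negative age")
  add(df$household_size < 1, "household_size < 1")
  add(df$los_days < 0, "negative los_days")
  add(df$n_caretakers < 0, "negative n_caretakers")
  add(df$visits_per_year < 1, "visits_per_year < 1")
  add(df$prod_hours_per_day < 0 | df$prod_hours_per_day > 24,
      "prod_hours_per_day outside [0,24]")
  for (mc in money_cols) add(df[[mc]] < 0, paste("negative", mc))
  reason
}

#' Load a traveler survey from CSV
#'
#' Reads and validates a UTF-8 comma-separated survey file with the
#' mandatory header of [survey_columns()]. Rows violating an invariant
#' (unknown category, negative money, hours outside 0–24, ...) are not
#' silently dropped: they are collected with their reasons in the
#' `"rejected"` attribute of the result, and counts are reported via
#' `message()`.
#'
#' @param path path to the CSV file.
#' @return tibble of valid records (one per surviving row), with attribute
#'   `rejected`: a tibble of invalid rows plus a `reason` column.
#' @export
load_survey <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(survey_columns(), header)
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = survey_col_types())
  df <- df[, survey_columns()]
  if (nrow(df) == 0L) {
    message("loaded 0 records (header-only file)")
    attr(df, "rejected") <- dplyr::mutate(df, reason = character(0))
    return(df)
  }
  reason <- validate_rows(df)
  bad <- reason != ""
  out <- df[!bad, , drop = FALSE]
  rejected <- df[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  message("loaded ", nrow(out), " valid record(s); rejected ", nrow(rejected))
  attr(out, "rejected") <- rejected
  out
}

#' Collapse continuous variables to the analysis categories
#'
#' Adds the categorical labels used throughout the descriptive tables:
#' age group, household-size class, and length-of-stay class. Missing
#' numeric values map to the label `"missing"`, never an error.
#'
#' Length of stay is classed by whole weeks counted so that any started
#' week belongs to that week's class (day 8 already counts as "2 weeks");
#' 22–30 days is "1 month" and anything longer is ">1 month". This
#' day-to-class convention is the package's own and is documented in the
#' methods vignette.
#'
#' @param records survey tibble.
#' @return `records` with `age_group`, `hh_size_class` and `los_class`
#'   character columns appended.
#' @export
categorize <- function(records) {
  records$age_group <- age_class(records$age)
  records$hh_size_class <- household_size_class(records$household_size)
  records$los_class <- los_class(records$los_days)
  records
}

#' @rdname categorize
#' @param age,household_size,los_days numeric vectors.
#' @export
age_class <- function(age) {
  out <- rep("missing", length(age))
  out[!is.na(age) & age <= 9] <- "Children <=9 yrs"
  out[!is.na(age) & age >= 10 & age <= 19] <- "Adolescents 10-19 yrs"
  out[!is.na(age) & age >= 20 & age <= 29] <- "Youth 20-29 yrs"
  out[!is.na(age) & age >= 30 & age <= 59] <- "Adult 30-59 yrs"
  out[!is.na(age) & age >= 60] <- "Elderly >=60 yrs"
  out
}

#' @rdname categorize
#' @export
household_size_class <- function(household_size) {
  # small is <=5 so the three classes partition all sizes >= 1
  out <- rep("missing", length(household_size))
  ok <- !is.na(household_size)
  out[ok & household_size <= 5] <- "Small (<=5 members)"
  out[ok & household_size >= 6 & household_size <= 10] <- "Medium (6-10 members)"
  out[ok & household_size > 10] <- "Large (>10 members)"
  out
}

#' @rdname categorize
#' @export
los_class <- function(los_days) {
  out <- rep("missing", length(los_days))
  ok <- !is.na(los_days)
  out[ok & los_days <= 7] <- "<=1 week"
  out[ok & los_days > 7 & los_days <= 14] <- "2 weeks"
  out[ok & los_days > 14 & los_days <= 21] <- "3 weeks"
  out[ok & los_days > 21 & los_days <= 30] <- "1 month"
  out[ok & los_days > 30] <- ">1 month"
  out
}

#' Sample-based household income quintiles
#'
#' Annotates each record with its income quintile (1 = poorest 20%,
#' 5 = richest 20%), using cut points at the 20/40/60/80% sample quantiles
#' of `household_income_month`. A value exactly equal to a cut point is
#' assigned the lower quintile, so ties at boundaries never promote a
#' record; assignment is therefore monotone in income and order-independent.
#'
#' @param records survey tibble with `household_income_month`.
#' @return `records` with an integer `income_quintile` column (NA for
#'   missing income).
#' @export
bin_income_quintiles <- function(records) {
  x <- records$household_income_month
  ok <- !is.na(x)
  if (sum(ok) < 5) stop("need at least 5 records with non-missing income",
                        call. = FALSE)
  cuts <- quantile(x[ok], probs = c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  if (length(unique(x[ok])) == 1L) {
    warning("all incomes identical; every record assigned quintile 1",
            call. = FALSE)
    q <- ifelse(ok, 1L, NA_integer_)
  } else {
    q <- rep(NA_integer_, length(x))
    # strictly-greater comparison assigns boundary ties to the lower quintile
    q[ok] <- as.integer(1L + rowSums(outer(x[ok], cuts, ">")))
  }
  records$income_quintile <- q
  records
}
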