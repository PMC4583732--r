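#' Log-normal parameters from a median and IQR
#'
#' Calibrates a log-normal distribution to a printed summary
#' `median (q1–q3)`: `mu = log(median)` and
#' `sigma = log(q3/q1) / (2 * 0.67449)`, 0.67449 being the standard normal
#' upper quartile. For a log-normal the quartiles are symmetric around the
#' median on the log scale, so the fitted distribution reproduces the
#' median exactly and the quartiles exactly when `q1*q3 = median^2`
#' (approximately otherwise).
#'
#' @param median,q1,q3 money targets with `0 < q1 <= median <= q3`.
#' @return list with `mu` and `sigma`.
#' @examples
#' lognormal_from_median_iqr(500, 181.5, 1150)
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (q1 <= 0) {
    stop("q1 = 0: a plain log-normal cannot be calibrated; ",
         "use the zero-inflated path (p_zero > 0)", call. = FALSE)
  }
  stopifnot(q1 <= median, median <= q3)
  list(mu = log(median), sigma = log(q3 / q1) / (2 * 0.67449))
}

# Per-component sampling parameters from (median, q1, q3, p_zero).
# Three regimes:
#  * q1 > 0: plain log-normal via lognormal_from_median_iqr (p_zero = 0).
#  * median > 0, q1 = 0: zero-inflated log-normal; p_zero (default 0.3,
#    must be < 0.5) and the positive part solved so the OVERALL median and
#    q3 hit the targets exactly.
#  * median = 0: mostly-zero component; p_zero default 0.6 when q3 > 0
#    (positive part solved to hit overall q3), else 0.9 with a nominal
#    positive part (median $40).
component_params <- function(median, q1, q3, p_zero = NA_real_) {
  if (!is.na(p_zero) && p_zero >= 1) {
    return(list(p_zero = 1, mu = 0, sigma = 0))
  }
  if (median > 0 && q1 > 0) {
    p <- lognormal_from_median_iqr(median, q1, q3)
    return(list(p_zero = if (is.na(p_zero)) 0 else p_zero,
                mu = p$mu, sigma = p$sigma))
  }
  if (median > 0) { # q1 == 0
    p0 <- if (is.na(p_zero)) 0.3 else p_zero
    stopifnot(p0 >= 0.25, p0 < 0.5, q3 >= median)
    pq50 <- (0.5 - p0) / (1 - p0)
    pq75 <- (0.75 - p0) / (1 - p0)
    if (q3 > median) {
      sigma <- (log(q3) - log(median)) /
        (stats::qnorm(pq75) - stats::qnorm(pq50))
    } else {
      sigma <- 0
    }
    mu <- log(median) - sigma * stats::qnorm(pq50)
    return(list(p_zero = p0, mu = mu, sigma = sigma))
  }
  if (q3 > 0) { # median 0, q3 > 0
    p0 <- if (is.na(p_zero)) 0.6 else p_zero
    stopifnot(p0 >= 0.5, p0 < 0.75)
    pq75 <- (0.75 - p0) / (1 - p0)
    sigma <- 1
    mu <- log(q3) - sigma * stats::qnorm(pq75)
    return(list(p_zero = p0, mu = mu, sigma = sigma))
  }
  # 0 (0-0): rare component with a nominal positive tail
  p0 <- if (is.na(p_zero)) 0.9 else p_zero
  stopifnot(p0 >= 0.75, p0 < 1)
  list(p_zero = p0, mu = log(40), sigma = 0.8)
}

# default per-stratum per-column cost targets: median (q1-q3) in USD, with
# NA p_zero meaning "by regime rule above"; p_zero = 1 pins a column at 0.
default_component_dists <- function() {
  tribble_row <- function(stratum, column, median, q1, q3, p_zero = NA_real_) {
    tibble::tibble(stratum = stratum, column = column, median = median,
                   q1 = q1, q3 = q3, p_zero = p_zero)
  }
  dplyr::bind_rows(
    # subsidized stratum: itemized by payer
    tribble_row("subsidized", "cost_medical_subsidy", 500, 106.25, 1462.5),
    tribble_row("subsidized", "cost_medical_oop", 56.5, 0, 500),
    tribble_row("subsidized", "cost_travel_home_oop", 81.5, 8, 437.25),
    tribble_row("subsidized", "cost_airfare_subsidy", 336, 200, 419.25),
    tribble_row("subsidized", "cost_airfare_oop", 400, 336, 672),
    tribble_row("subsidized", "cost_travel_dest_oop", 91, 35, 200),
    tribble_row("subsidized", "cost_entertainment_oop", 34.5, 0, 200),
    tribble_row("subsidized", "cost_lodging_oop", 150, 67, 300),
    tribble_row("subsidized", "cost_food_oop", 140, 56, 300),
    tribble_row("subsidized", "cost_visa_oop", 0, 0, 0),
    tribble_row("subsidized", "cost_fx_oop", 0, 0, 0),
    tribble_row("subsidized", "cost_other_oop", 0, 0, 0),
    # private stratum: no subsidy; only a combined travel summary is
    # available as a target, split here into home-country travel / airfare /
    # destination travel medians summing near it
    tribble_row("private", "cost_medical_subsidy", 0, 0, 0, p_zero = 1),
    tribble_row("private", "cost_airfare_subsidy", 0, 0, 0, p_zero = 1),
    tribble_row("private", "cost_medical_oop", 300, 147.5, 720.5),
    tribble_row("private", "cost_travel_home_oop", 180, 60, 450),
    tribble_row("private", "cost_airfare_oop", 750, 520, 1100),
    tribble_row("private", "cost_travel_dest_oop", 120, 45, 250),
    tribble_row("private", "cost_entertainment_oop", 142, 0, 400),
    tribble_row("private", "cost_lodging_oop", 127, 47, 300),
    tribble_row("private", "cost_food_oop", 100, 46, 210),
    tribble_row("private", "cost_visa_oop", 0, 0, 0),
    tribble_row("private", "cost_fx_oop", 0, 0, 0),
    tribble_row("private", "cost_other_oop", 0, 0, 0)
  )
}

default_categoricals <- function() {
  list(
    sex_probs = list(subsidized = c(female = 169, male = 175) / 344,
                     private = c(female = 313, male = 158) / 471),
    age_probs = list(
      subsidized = c("0-9" = 53, "10-19" = 24, "20-29" = 30,
                     "30-59" = 163, "60-85" = 74) / 344,
      private = c("0-9" = 46, "10-19" = 34, "20-29" = 64,
                  "30-59" = 266, "60-85" = 61) / 471),
    region_probs = list(
      subsidized = c(North = 86, Central = 190, South = 68) / 344,
      private = c(North = 159, Central = 176, South = 136) / 471),
    occupation_probs = list(
      subsidized = c(civil_servant = 52, private_sector = 35,
                     own_business = 77, not_employed = 136, other = 44) / 344,
      private = c(civil_servant = 119, private_sector = 42,
                  own_business = 88, not_employed = 156, other = 66) / 471),
    hh_size_probs = list(
      subsidized = c(small = 201, medium = 100, large = 43) / 344,
      private = c(small = 277, medium = 149, large = 45) / 471),
    destination_probs = list(
      subsidized = c(India = 239, `Sri Lanka` = 105, Thailand = 0, Italy = 0) / 344,
      private = c(India = 305, `Sri Lanka` = 160, Thailand = 5, Italy = 1) / 471),
    # chapter weights over the 22 blocks, keyed by block start code
    chapter_probs = c(I00 = 82, G00 = 69, M00 = 65, N00 = 62, H00 = 51,
                      C00 = 51, R00 = 49, S00 = 43, K00 = 35, E00 = 35,
                      Z00 = 169, J00 = 25, F00 = 20, L00 = 10, O00 = 10,
                      Q00 = 9, H60 = 8, A00 = 8, D50 = 7, P00 = 4,
                      V01 = 3, U00 = 0) / 815
  )
}

#' Synthetic survey configuration
#'
#' Full parameterization of the synthetic traveler-survey generator. The
#' defaults emulate the study conditions of a two-stratum household survey
#' of medical travelers: 344 government-subsidized and 471 privately funded
#' travelers; per-stratum skewed cost components calibrated to printed
#' median/IQR targets; caretaker party sizes with means 2.3 (subsidized)
#' and 3.3 (private); and household budget shares drawn from a Beta mixture
#' whose exceedance probability at the threshold `z` is solved numerically
#' so that the expected catastrophic incidence equals `catastrophic_target`
#' (default 43% at z = 10%).
#'
#' @param n_subsidized,n_private stratum sample sizes.
#' @param caretaker_mean named numeric: mean caretakers per stratum.
#' @param z threshold budget share.
#' @param catastrophic_target expected fraction of households with health
#'   budget share above `z`; must be strictly between the exceedance
#'   probabilities of the two mixture components.
#' @param component_dists tibble of per-stratum cost targets
#'   (`stratum`, `column`, `median`, `q1`, `q3`, `p_zero`).
#' @param budget Beta-mixture and scale parameters of the household budget
#'   generator.
#' @param income,los,productivity auxiliary distribution parameters.
#' @param visits_rate Poisson rate of extra annual visits beyond the first.
#' @param categoricals per-stratum categorical weights (sex, age group,
#'   region, occupation, household-size class, destination) and the ICD
#'   chapter weights.
#' @param seed root seed; every draw flows from it through named
#'   independent streams, so regenerating with the same config is
#'   bit-identical and adding a component never perturbs the others.
#' @return object of class `survey_config` (a list).
#' @export
survey_config <- function(n_subsidized = 344,
                          n_private = 471,
                          caretaker_mean = c(subsidized = 2.3, private = 3.3),
                          z = 0.10,
                          catastrophic_target = 0.43,
                          component_dists = default_component_dists(),
                          budget = list(share_lo = c(1.2, 25),
                                        share_hi = c(3.5, 8.5),
                                        total_median = 1000,
                                        total_q1 = 600, total_q3 = 1700,
                                        food_frac_shape = c(8, 5)),
                          income = list(median = 1000, q1 = 600, q3 = 1800),
                          los = list(median = 15, q1 = 9, q3 = 24),
                          productivity = list(p_zero_hours = 0.6,
                                              hours_min = 2, hours_max = 8,
                                              income_day = list(median = 33,
                                                                q1 = 16,
                                                                q3 = 66)),
                          visits_rate = 0.3,
                          categoricals = default_categoricals(),
                          seed = 20130601) {
  stopifnot(n_subsidized >= 1, n_private >= 1, z > 0, z < 1,
            all(caretaker_mean >= 0),
            all(component_dists$q1 <= component_dists$median),
            all(component_dists$median <= component_dists$q3))
  for (p in categoricals[setdiff(names(categoricals), "chapter_probs")]) {
    stopifnot(abs(sum(p$subsidized) - 1) < 1e-9, abs(sum(p$private) - 1) < 1e-9)
  }
  stopifnot(abs(sum(categoricals$chapter_probs) - 1) < 1e-9)
  structure(list(
    n_subsidized = n_subsidized, n_private = n_private,
    caretaker_mean = caretaker_mean, z = z,
    catastrophic_target = catastrophic_target,
    component_dists = component_dists, budget = budget, income = income,
    los = los, productivity = productivity, visits_rate = visits_rate,
    categoricals = categoricals, seed = seed
  ), class = "survey_config")
}

# deterministic per-stream sub-seed derived from the root seed and a name
stream_seed <- function(root, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (root %% 2147483647) * 7919) %% 2147483646 + 1)
}

with_stream <- function(root, name, expr) {
  set.seed(stream_seed(root, name))
  force(expr)
}

# zero-inflated lognormal draw, rounded to cents
draw_component <- function(n, params) {
  if (params$p_zero >= 1) return(numeric(n))
  pos <- rlnorm(n, params$mu, params$sigma)
  zero <- runif(n) < params$p_zero
  round_money(ifelse(zero, 0, pos))
}

# Solve the Beta-mixture weight so P(share > z) = target.
budget_mixture_weight <- function(budget, z, target) {
  p_lo <- 1 - pbeta(z, budget$share_lo[1], budget$share_lo[2])
  p_hi <- 1 - pbeta(z, budget$share_hi[1], budget$share_hi[2])
  if (target <= 0 || target >= 1 ||
      target <= min(p_lo, p_hi) || target >= max(p_lo, p_hi)) {
    stop("catastrophic_target ", target, " is not attainable by the ",
         "configured Beta mixture (component exceedance probabilities ",
         signif(p_lo, 3), " and ", signif(p_hi, 3), ")", call. = FALSE)
  }
  uniroot(function(w) w * p_lo + (1 - w) * p_hi - target,
          c(0, 1), tol = 1e-12)$root
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# draw one stratum's worth of records
generate_stratum <- function(config, stratum, n, id_offset) {
  cats <- config$categoricals
  seed <- config$seed
  s <- function(name) paste0(name, "/", stratum)

  sex <- with_stream(seed, s("sex"), sample_cat(n, cats$sex_probs[[stratum]]))
  age <- with_stream(seed, s("age"), {
    grp <- sample_cat(n, cats$age_probs[[stratum]])
    lims <- list("0-9" = c(0, 9), "10-19" = c(10, 19), "20-29" = c(20, 29),
                 "30-59" = c(30, 59), "60-85" = c(60, 85))
    vapply(grp, function(g) sample(lims[[g]][1]:lims[[g]][2], 1L), numeric(1))
  })
  region <- with_stream(seed, s("region"),
                        sample_cat(n, cats$region_probs[[stratum]]))
  occupation <- with_stream(seed, s("occupation"),
                            sample_cat(n, cats$occupation_probs[[stratum]]))
  household_size <- with_stream(seed, s("hh_size"), {
    cls <- sample_cat(n, cats$hh_size_probs[[stratum]])
    lims <- list(small = 1:5, medium = 6:10, large = 11:15)
    vapply(cls, function(g) sample(lims[[g]], 1L), integer(1))
  })
  destination <- with_stream(seed, s("destination"),
                             sample_cat(n, cats$destination_probs[[stratum]]))
  icd_code <- with_stream(seed, s("icd"), {
    chapters <- icd10_chapters()
    start <- sample_cat(n, cats$chapter_probs)
    row <- match(start, chapters$start)
    lo <- icd_index(chapters$start[row])
    hi <- icd_index(chapters$end[row])
    # uniform block inside the chapter range; indices are contiguous by
    # construction of icd_index
    idx <- floor(lo + runif(n) * (hi - lo + 1))
    icd_code_from_index(pmin(idx, hi))
  })
  los_days <- with_stream(seed, s("los"), {
    p <- lognormal_from_median_iqr(config$los$median, config$los$q1,
                                   config$los$q3)
    pmax(1, round(rlnorm(n, p$mu, p$sigma)))
  })
  n_caretakers <- with_stream(seed, s("caretakers"),
    1 + rpois(n, config$caretaker_mean[[stratum]] - 1))
  visits_per_year <- with_stream(seed, s("visits"),
                                 1 + rpois(n, config$visits_rate))
  household_income_month <- with_stream(seed, s("income"), {
    p <- lognormal_from_median_iqr(config$income$median, config$income$q1,
                                   config$income$q3)
    round_money(rlnorm(n, p$mu, p$sigma))
  })

  dists <- config$component_dists[config$component_dists$stratum == stratum, ]
  costs <- lapply(seq_len(nrow(dists)), function(i) {
    row <- dists[i, ]
    params <- component_params(row$median, row$q1, row$q3, row$p_zero)
    with_stream(seed, s(paste0("cost/", row$column)), draw_component(n, params))
  })
  names(costs) <- dists$column

  prod <- config$productivity
  prod_hours_per_day <- with_stream(seed, s("prod_hours"), {
    zero <- runif(n) < prod$p_zero_hours
    ifelse(zero, 0, round(runif(n, prod$hours_min, prod$hours_max), 1))
  })
  prod_income_per_day <- with_stream(seed, s("prod_income"), {
    p <- lognormal_from_median_iqr(prod$income_day$median, prod$income_day$q1,
                                   prod$income_day$q3)
    round_money(rlnorm(n, p$mu, p$sigma))
  })

  bud <- config$budget
  w <- budget_mixture_weight(bud, config$z, config$catastrophic_target)
  budget <- with_stream(seed, s("budget"), {
    lo <- runif(n) < w
    share <- ifelse(lo, rbeta(n, bud$share_lo[1], bud$share_lo[2]),
                    rbeta(n, bud$share_hi[1], bud$share_hi[2]))
    p <- lognormal_from_median_iqr(bud$total_median, bud$total_q1, bud$total_q3)
    total <- rlnorm(n, p$mu, p$sigma)
    ff <- rbeta(n, bud$food_frac_shape[1], bud$food_frac_shape[2])
    health <- round_money(share * total)
    food <- round_money(ff * (1 - share) * total)
    other <- round_money((1 - ff) * (1 - share) * total)
    list(health = health, food = food, other = other)
  })

  out <- tibble::tibble(
    id = sprintf("MT%05d", id_offset + seq_len(n)),
    stratum = stratum, sex = sex, age = age, region = region,
    occupation = occupation, household_size = household_size,
    household_income_month = household_income_month,
    icd_code = icd_code, destination = destination,
    los_days = los_days, n_caretakers = n_caretakers,
    visits_per_year = visits_per_year
  )
  for (col in cost_columns()) out[[col]] <- costs[[col]]
  out$prod_hours_per_day <- prod_hours_per_day
  out$prod_income_per_day <- prod_income_per_day
  out$hh_health_month <- budget$health
  out$hh_food_month <- budget$food
  out$hh_other_month <- budget$other
  out
}

#' Generate a synthetic traveler survey
#'
#' Draws `n_subsidized + n_private` traveler records with the statistical
#' structure described in [survey_config()]. A pure function of the config
#' (including its seed): the same config always yields a bit-identical
#' table, and every component uses its own named random stream derived from
#' the root seed.
#'
#' @param config a [survey_config()].
#' @return tibble conforming to [survey_columns()].
#' @examples
#' records <- generate_survey(survey_config(n_subsidized = 20, n_private = 30))
#' nrow(records)
#' @export
generate_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  out <- dplyr::bind_rows(
    generate_stratum(config, "subsidized", config$n_subsidized, 0L),
    generate_stratum(config, "private", config$n_private, config$n_subsidized)
  )
  out[, survey_columns()]
}

#' Write a survey table to CSV
#'
#' Writes the schema columns of [survey_columns()] as UTF-8 comma-separated
#' text with a header. Money values are stored to the cent, so a
#' write–load round-trip through [load_survey()] reproduces every field
#' exactly.
#'
#' @param records survey tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path) {
  readr::write_csv(records[, survey_columns()], path)
  invisible(path)
}

#' Read / write a survey configuration as YAML
#'
#' The YAML mirrors [survey_config()] field for field (the component
#' distribution table becomes a list of rows). `read_survey_config()`
#' validates through `survey_config()`, so a hand-edited file is checked
#' against the same invariants as the in-code defaults.
#'
#' @param path YAML file path.
#' @param config a `survey_config` object.
#' @return `read_survey_config()`: a `survey_config`;
#'   `write_survey_config()`: `path`, invisibly.
#' @export
read_survey_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$component_dists <- dplyr::bind_rows(lapply(y$component_dists, function(r) {
    r$p_zero <- if (is.null(r$p_zero)) NA_real_ else r$p_zero
    tibble::as_tibble(r)
  }))
  y$caretaker_mean <- unlist(y$caretaker_mean)
  y$categoricals <- lapply(y$categoricals, function(x) {
    if (is.list(x) && all(c("subsidized", "private") %in% names(x))) {
      lapply(x, unlist)
    } else unlist(x)
  })
  y$budget <- lapply(y$budget, unlist)
  do.call(survey_config, y)
}

#' @rdname read_survey_config
#' @export
write_survey_config <- function(config, path) {
  stopifnot(inherits(config, "survey_config"))
  y <- unclass(config)
  y$component_dists <- lapply(seq_len(nrow(config$component_dists)),
                              function(i) as.list(config$component_dists[i, ]))
  # named numerics must become YAML maps, not bare sequences
  y$caretaker_mean <- as.list(config$caretaker_mean)
  y$categoricals <- lapply(config$categoricals, function(x) {
    if (is.list(x)) lapply(x, as.list) else as.list(x)
  })
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Default configuration shipped with the package
#'
#' @return path to the installed default YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "survey_config.yaml", package = "mtoburden",
              mustWork = TRUE)
}
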