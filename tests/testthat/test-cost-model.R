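test_that("visit totals sum all components and never include productivity loss", {
  rec <- make_records(1, cost_medical_oop = 500, cost_travel_home_oop = 157,
                      cost_airfare_oop = 800, cost_travel_dest_oop = 200,
                      cost_entertainment_oop = 100, cost_lodging_oop = 140,
                      cost_food_oop = 105)
  expect_equal(visit_total_cost(rec), 2002)

  zero <- make_records(1)
  zero[cost_columns()] <- 0
  expect_equal(visit_total_cost(zero), 0)

  # a recorded productivity loss leaves the total unchanged
  with_loss <- rec
  with_loss$prod_hours_per_day <- 8
  with_loss$prod_income_per_day <- 20.2
  expect_equal(visit_total_cost(with_loss), visit_total_cost(rec))
  expect_gt(record_productivity_loss(with_loss), 0)
})

test_that("payer split conserves the total exactly and handles degenerate shares", {
  rec <- make_records(1, cost_medical_subsidy = 500, cost_airfare_subsidy = 336,
                      cost_medical_oop = 0, cost_travel_home_oop = 0,
                      cost_airfare_oop = 0, cost_travel_dest_oop = 0,
                      cost_entertainment_oop = 0, cost_lodging_oop = 0,
                      cost_food_oop = 1797)
  got <- payer_split(rec)
  expect_equal(got$subsidy_total, 836)
  expect_equal(got$oop_total, 1797)
  expect_equal(got$subsidy_share, 836 / 2633)

  zero <- make_records(1)
  zero[cost_columns()] <- 0
  z <- payer_split(zero)
  expect_equal(z$subsidy_share, 0)
  expect_false(z$share_defined)

  only_sub <- make_records(1)
  only_sub[cost_columns()] <- 0
  only_sub$cost_medical_subsidy <- 250
  expect_equal(payer_split(only_sub)$subsidy_share, 1)

  # conservation property on random cent-valued breakdowns
  set.seed(1)
  for (i in 1:20) {
    r <- make_records(1)
    for (col in cost_columns()) r[[col]] <- round(runif(1, 0, 2000), 2)
    ps <- payer_split(r)
    expect_identical(as_cents(ps$subsidy_total) + as_cents(ps$oop_total),
                     as_cents(visit_total_cost(r)))
  }
})

test_that("per-capita allocation gives medical cost to the patient only", {
  rec <- make_records(1, n_caretakers = 2)
  rec[cost_columns()] <- 0
  rec$cost_medical_oop <- 500
  rec$cost_food_oop <- 1500
  pc <- per_capita_costs(rec)
  expect_equal(pc$patient_pc, 1000)
  expect_equal(pc$caretaker_pc, 500)

  solo <- rec
  solo$n_caretakers <- 0
  pcs <- per_capita_costs(solo)
  expect_equal(pcs$patient_pc, 2000)
  expect_equal(pcs$caretaker_pc, 1500)

  # no medical cost: patient and caretaker shares coincide
  nomed <- rec
  nomed$cost_medical_oop <- 0
  pcn <- per_capita_costs(nomed)
  expect_equal(pcn$patient_pc, pcn$caretaker_pc)

  # identity M + (k+1)*caretaker_pc = total, for k = 0..6 on random costs
  set.seed(2)
  for (k in 0:6) {
    r <- make_records(1, n_caretakers = k)
    for (col in cost_columns()) r[[col]] <- round(runif(1, 0, 3000), 2)
    p <- per_capita_costs(r)
    m <- r$cost_medical_subsidy + r$cost_medical_oop
    expect_equal(m + (k + 1) * p$caretaker_pc, visit_total_cost(r))
    expect_gte(p$patient_pc, p$caretaker_pc)
  }
})

test_that("productivity loss follows the working-day convention", {
  expect_equal(productivity_loss(0, 10, 20), 0)
  expect_equal(productivity_loss(8, 10, 20), 200)   # full working day
  expect_equal(productivity_loss(4, 10, 20), 100)   # half working day
  expect_equal(productivity_loss(12, 5, 40, workday_hours = 12), 200)
  expect_error(productivity_loss(25, 1, 1))
})

test_that("component shares are means of per-traveler ratios and sum to one", {
  one <- make_records(1)
  one[cost_columns()] <- 0
  one$cost_airfare_oop <- 48
  one$cost_food_oop <- 52
  sh <- component_shares(one)
  expect_equal(sh$mean_share[sh$component == "travel"], 0.48)
  expect_equal(sum(sh$mean_share), 1)

  # two travelers with component shares 0.4 and 0.6 -> mean 0.5 (not the
  # pooled ratio, which would differ because totals differ)
  two <- make_records(2)
  two[cost_columns()] <- 0
  two$cost_lodging_oop <- c(40, 600)
  two$cost_food_oop <- c(60, 400)
  sh2 <- component_shares(two)
  expect_equal(sh2$mean_share[sh2$component == "lodging"], 0.5)

  all_zero <- make_records(2)
  all_zero[cost_columns()] <- 0
  expect_error(component_shares(all_zero), "undefined")

  # shares sum to 1 within 1e-9 on generated data
  rec <- generate_survey(tiny_config())
  expect_equal(sum(component_shares(rec)$mean_share), 1, tolerance = 1e-9)
  expect_equal(sum(component_shares(rec, collapse_travel = FALSE)$mean_share),
               1, tolerance = 1e-9)
})

test_that("the per-traveler cost table has the documented columns", {
  rec <- generate_survey(tiny_config())
  ct <- costs_table(rec)
  expect_identical(names(ct), c("id", "total", "subsidy_total", "oop_total",
                                "patient_pc", "caretaker_pc",
                                "productivity_loss"))
  expect_equal(ct$total, visit_total_cost(rec))
  expect_equal(ct$subsidy_total + ct$oop_total, ct$total)
})
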