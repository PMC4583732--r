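test_that("load_survey validates rows and round-trips generated data exactly", {
  rec <- generate_survey(tiny_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(rec, path)
  expect_identical(length(readLines(path)), nrow(rec) + 1L)

  back <- suppressMessages(load_survey(path))
  attr(back, "rejected") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(rec))
  expect_identical(back$cost_medical_oop, rec$cost_medical_oop)

  # invalid rows are collected with reasons, not silently dropped
  bad <- make_records(3)
  bad$household_income_month[2] <- -5
  bad$stratum[3] <- "charity"
  write_survey(bad, path)
  got <- suppressMessages(load_survey(path))
  expect_identical(nrow(got), 1L)
  rej <- attr(got, "rejected")
  expect_identical(nrow(rej), 2L)
  expect_match(rej$reason[rej$id == "T002"], "negative household_income_month")
  expect_match(rej$reason[rej$id == "T003"], "invalid stratum")
})

test_that("header-only files load as empty; missing columns are schema errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(make_records(0), path)
  got <- suppressMessages(load_survey(path))
  expect_identical(nrow(got), 0L)
  expect_identical(nrow(attr(got, "rejected")), 0L)

  df <- make_records(2)
  df$icd_code <- NULL
  readr::write_csv(df, path)
  expect_error(load_survey(path), "icd_code")
  expect_error(load_survey("no/such/file.csv"), "no such file")
})

test_that("ICD chapter assignment is correct, total and partitioning", {
  got <- assign_icd_chapter(c("I25", "Z34", "M17"))
  expect_identical(got$code_range, c("I00-I99", "Z00-Z99", "M00-M99"))
  expect_identical(got$profile_eligible, c(TRUE, FALSE, TRUE))
  expect_match(got$label[1], "circulatory", ignore.case = TRUE)
  expect_match(got$label[3], "musculoskeletal", ignore.case = TRUE)

  # missing is a first-class sentinel, never an error
  miss <- assign_icd_chapter(c(NA, ""))
  expect_identical(miss$label, c("missing", "missing"))
  expect_false(any(miss$profile_eligible))

  # unparseable and out-of-chapter codes are errors
  expect_error(assign_icd_chapter("25X"), "unparseable")
  expect_error(assign_icd_chapter("D49"), "outside every chapter")

  # exactly 22 chapters, exactly one profile-ineligible, no overlaps,
  # one probe code per letter block lands in a unique chapter
  ch <- icd10_chapters()
  expect_identical(nrow(ch), 22L)
  expect_identical(sum(!ch$profile_eligible), 1L)
  probes <- c("A15", "B20", "C50", "D10", "D70", "E11", "F32", "G40", "H25",
              "H65", "I10", "J45", "K35", "L40", "M54", "N18", "O80", "P07",
              "Q90", "R50", "S72", "T40", "U07", "V40", "W10", "X60", "Y60",
              "Z34")
  assigned <- assign_icd_chapter(probes)
  expect_false(any(is.na(assigned$code_range)))
  # every chapter is hit by at least one probe
  expect_identical(sort(unique(assigned$code_range)),
                   sort(paste0(ch$start, "-", ch$end)))
})

test_that("disease-profile filter drops Z-chapter and missing with a count", {
  rec <- make_records(10)
  rec$icd_code[1:3] <- c("Z00", "Z34", "Z99")
  out <- suppressMessages(filter_disease_profile(rec))
  expect_identical(nrow(out), 7L)
  expect_identical(attr(out, "n_omitted"), 3L)

  # no Z-chapter records -> identity
  clean <- make_records(4)
  out2 <- suppressMessages(filter_disease_profile(clean))
  expect_identical(nrow(out2), 4L)
  expect_identical(attr(out2, "n_omitted"), 0L)

  # all-Z input -> empty with warning
  allz <- make_records(3, icd_code = "Z50")
  expect_warning(suppressMessages(filter_disease_profile(allz)),
                 "no profile-eligible")
})

test_that("categorical collapsing matches the documented class tables", {
  expect_identical(age_class(c(0, 9, 10, 19, 20, 29, 30, 45, 59, 60, 90)),
                   c("Children <=9 yrs", "Children <=9 yrs",
                     "Adolescents 10-19 yrs", "Adolescents 10-19 yrs",
                     "Youth 20-29 yrs", "Youth 20-29 yrs",
                     "Adult 30-59 yrs", "Adult 30-59 yrs", "Adult 30-59 yrs",
                     "Elderly >=60 yrs", "Elderly >=60 yrs"))
  expect_identical(household_size_class(c(1, 5, 6, 7, 10, 11)),
                   c("Small (<=5 members)", "Small (<=5 members)",
                     "Medium (6-10 members)", "Medium (6-10 members)",
                     "Medium (6-10 members)", "Large (>10 members)"))

  # hand-written day-to-class oracle for days 0..45
  oracle <- c(rep("<=1 week", 8),      # 0..7
              rep("2 weeks", 7),       # 8..14
              rep("3 weeks", 7),       # 15..21
              rep("1 month", 9),       # 22..30
              rep(">1 month", 15))     # 31..45
  expect_identical(los_class(0:45), oracle)
  expect_identical(los_class(10), "2 weeks")

  rec <- categorize(make_records(1, age = NA))
  expect_identical(rec$age_group, "missing")
})

test_that("income quintiles: forced small case, degenerate ties, sort-slice oracle", {
  rec <- make_records(10, household_income_month = c(1:10))
  got <- bin_income_quintiles(rec)$income_quintile
  expect_identical(got, as.integer(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)))

  same <- make_records(6, household_income_month = 500)
  expect_warning(q <- bin_income_quintiles(same)$income_quintile,
                 "identical")
  expect_true(all(q == 1L))

  expect_error(bin_income_quintiles(make_records(4)), "at least 5")

  # 1000 continuous draws: groups of 200 each, and monotone in income
  set.seed(42)
  x <- rlnorm(1000, 7, 1)
  big <- bin_income_quintiles(make_records(1000, household_income_month = x))
  expect_identical(as.vector(table(big$income_quintile)),
                   rep(200L, 5))
  ord <- order(x)
  expect_true(all(diff(big$income_quintile[ord]) >= 0))
})
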