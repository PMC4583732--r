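# Descriptive table helpers -------------------------------------------------

pct1 <- function(n, total) round(100 * n / total, 1)

# counts and column percentages of `var` by stratum, plus chi-square p
demographic_block <- function(records, var) {
  g <- records[[var]]
  tab <- table(g, records$stratum)
  tab <- tab[, c("subsidized", "private"), drop = FALSE]
  p <- tryCatch(chi_square_test(unclass(tab))$p_value, error = function(e) NA_real_)
  tibble::tibble(
    variable = var,
    label = rownames(tab),
    n_subsidized = as.integer(tab[, "subsidized"]),
    pct_subsidized = pct1(as.integer(tab[, "subsidized"]), sum(tab[, "subsidized"])),
    n_private = as.integer(tab[, "private"]),
    pct_private = pct1(as.integer(tab[, "private"]), sum(tab[, "private"])),
    n_total = as.integer(rowSums(tab)),
    pct_total = pct1(as.integer(rowSums(tab)), sum(tab)),
    p_value = c(p, rep(NA_real_, nrow(tab) - 1))
  )
}

fmt_median_iqr <- function(x) {
  mi <- median_iqr(x)
  sprintf("%.1f (%.1f-%.1f)", mi["median"], mi["q1"], mi["q3"])
}

#' Build the full analysis report
#'
#' Runs the whole pipeline on a validated survey table and returns the
#' standard table bundle: demographics and utilization by funding stratum
#' (with chi-square p-values), the disease profile over ICD-10 chapters
#' (Z-chapter and missing diagnoses omitted, with the omitted count
#' reported), per-visit cost summaries with mean component shares and
#' rank-sum p-values, the subsidized-stratum payer breakdown, catastrophic
#' health expenditure overall and by subgroup, and the national economic
#' cost extrapolation. A deterministic JSON summary and run metadata
#' (seed, config hash, package version) are included; with `out_dir` set,
#' every table is written as CSV next to `summary.json` and a plain-text
#' log.
#'
#' @param records survey tibble (e.g. from [load_survey()] or
#'   [generate_survey()]).
#' @param z catastrophic threshold budget share.
#' @param visits_subsidized,visits_private annual patient visit counts used
#'   by the extrapolation.
#' @param gdp,population economy context.
#' @param B,seed bootstrap parameters.
#' @param out_dir optional output directory.
#' @return list with elements `demographics`, `disease_profile`, `visit_costs`, `payer_breakdown`,
#'   `catastrophic_by_group`, `economic_costs`, `catastrophic`, `metadata`, `summary_json`.
#' @export
build_report <- function(records, z = 0.10,
                         visits_subsidized = 3546, visits_private = 15462,
                         gdp = 1431e6, population = 336224,
                         B = 1000, seed = 1, out_dir = NULL) {
  records <- categorize(records)
  records <- bin_income_quintiles(records)

  # demographics and utilization by stratum
  demographics <- dplyr::bind_rows(lapply(
    c("sex", "age_group", "region", "occupation", "hh_size_class",
      "income_quintile", "destination", "los_class"),
    function(v) demographic_block(records, v)))

  # disease profile over ICD-10 chapters (Z-chapter and missing omitted)
  profile <- suppressMessages(filter_disease_profile(records))
  chap <- assign_icd_chapter(profile$icd_code)
  chap_tab <- table(paste0(chap$label, " (", chap$code_range, ")"),
                profile$stratum)
  disease_profile <- tibble::tibble(
    chapter = rownames(chap_tab),
    n = as.integer(rowSums(chap_tab)),
    pct_subsidized = pct1(as.integer(chap_tab[, "subsidized"]), rowSums(chap_tab)),
    pct_private = pct1(as.integer(chap_tab[, "private"]), rowSums(chap_tab))
  )
  disease_profile <- disease_profile[order(-disease_profile$n), ]
  attr(disease_profile, "n_omitted") <- attr(profile, "n_omitted")

  # per-visit cost summaries by stratum
  shares <- component_shares(records, collapse_travel = TRUE)
  sub <- records[records$stratum == "subsidized", ]
  priv <- records[records$stratum == "private", ]
  pc <- per_capita_costs(records)
  comp_rows <- lapply(names(component_map(TRUE)), function(comp) {
    cols <- component_map(TRUE)[[comp]]
    all_v <- as_usd(sum_cents(records, cols))
    sub_v <- as_usd(sum_cents(sub, cols))
    priv_v <- as_usd(sum_cents(priv, cols))
    tibble::tibble(
      item = comp,
      mean_share_pct = round(100 * shares$mean_share[shares$component == comp], 1),
      total = fmt_median_iqr(all_v),
      subsidized = fmt_median_iqr(sub_v),
      private = fmt_median_iqr(priv_v),
      p_value = rank_sum_test(sub_v, priv_v)$p_value
    )
  })
  totals_row <- tibble::tibble(
    item = "total_cost",
    mean_share_pct = 100,
    total = fmt_median_iqr(visit_total_cost(records)),
    subsidized = fmt_median_iqr(visit_total_cost(sub)),
    private = fmt_median_iqr(visit_total_cost(priv)),
    p_value = rank_sum_test(visit_total_cost(sub), visit_total_cost(priv))$p_value
  )
  pc_row <- tibble::tibble(
    item = "total_cost_per_capita_patient",
    mean_share_pct = NA_real_,
    total = fmt_median_iqr(pc$patient_pc),
    subsidized = fmt_median_iqr(pc$patient_pc[records$stratum == "subsidized"]),
    private = fmt_median_iqr(pc$patient_pc[records$stratum == "private"]),
    p_value = rank_sum_test(pc$patient_pc[records$stratum == "subsidized"],
                            pc$patient_pc[records$stratum == "private"])$p_value
  )
  visit_costs <- dplyr::bind_rows(c(comp_rows, list(totals_row, pc_row)))

  # payer breakdown within the subsidized stratum
  split_sub <- payer_split(sub)
  by_payer <- function(cols) {
    if (length(cols) == 0) return("-")
    fmt_median_iqr(as_usd(sum_cents(sub, cols)))
  }
  cmap <- component_map(FALSE)
  payer_breakdown <- tibble::tibble(
    item = names(cmap),
    subsidy = vapply(names(cmap), function(comp) {
      by_payer(intersect(cmap[[comp]], subsidy_columns()))
    }, character(1)),
    out_of_pocket = vapply(names(cmap), function(comp) {
      by_payer(intersect(cmap[[comp]], oop_columns()))
    }, character(1))
  )
  payer_breakdown <- dplyr::bind_rows(payer_breakdown, tibble::tibble(
    item = "productivity_loss", subsidy = "-",
    out_of_pocket = fmt_median_iqr(record_productivity_loss(sub))
  ), tibble::tibble(
    item = "total_cost",
    subsidy = fmt_median_iqr(split_sub$subsidy_total),
    out_of_pocket = fmt_median_iqr(split_sub$oop_total)
  ))
  attr(payer_breakdown, "mean_subsidy_share_pct") <-
    round(100 * mean(split_sub$subsidy_share[split_sub$share_defined]), 1)

  # catastrophic statistics overall and by subgroup
  cat_res <- catastrophic_stats(health_share(records), z = z)
  catastrophic_by_group <- dplyr::bind_rows(lapply(
    c("stratum", "region", "hh_size_class", "income_quintile"),
    function(by) {
      t <- catastrophic_subgroups(records, by = by, z = z)
      t$grouping <- by
      t$p_value <- c(attr(t, "p_value"), rep(NA_real_, nrow(t) - 1))
      t
    }))

  # national extrapolation
  econ <- economic_cost_table(records, visits_subsidized, visits_private,
                              gdp = gdp, population = population,
                              B = B, seed = seed)
  economic_costs <- econ$strata

  metadata <- list(
    package_version = as.character(utils::packageVersion("mtoburden")),
    seed = seed, z = z, bootstrap_replicates = B,
    visits_subsidized = visits_subsidized, visits_private = visits_private,
    gdp = gdp, population = population,
    n_records = nrow(records),
    n_profile_omitted = attr(disease_profile, "n_omitted"),
    config_hash = rlang::hash(list(z, visits_subsidized, visits_private,
                                   gdp, population, B, seed)),
    trend_test = "Cuzick rank test",
    quantile_convention = "linear interpolation (type 7)"
  )

  summary <- list(
    metadata = metadata,
    catastrophic = list(n = cat_res$n, H = cat_res$H, O = cat_res$O,
                        MPO = cat_res$MPO),
    mean_component_shares = as.list(setNames(shares$mean_share,
                                             shares$component)),
    totals = econ$totals,
    productivity = econ$productivity
  )
  summary_json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                   pretty = TRUE, na = "null")

  bundle <- list(demographics = demographics, disease_profile = disease_profile, visit_costs = visit_costs,
                 payer_breakdown = payer_breakdown, catastrophic_by_group = catastrophic_by_group, economic_costs = economic_costs,
                 catastrophic = cat_res, metadata = metadata,
                 summary_json = summary_json)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("demographics", "disease_profile", "visit_costs", "payer_breakdown", "catastrophic_by_group", "economic_costs")) {
      readr::write_csv(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    writeLines(summary_json, file.path(out_dir, "summary.json"))
    writeLines(c(paste("mtoburden report", Sys.time()),
                 paste("records:", nrow(records)),
                 paste("config hash:", metadata$config_hash)),
               file.path(out_dir, "report.log"))
  }
  bundle
}
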