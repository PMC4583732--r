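#' The 22 major ICD-10 chapter blocks
#'
#' Returns the chapter table shipped with the package: 22 inclusive
#' letter+digit block ranges (e.g. I00–I99) with chapter labels and a
#' `profile_eligible` flag. The single ineligible chapter is Z00–Z99
#' ("Factors influencing health status and contact with health services"),
#' which by convention is excluded from disease-profile tables because the
#' codes describe contact circumstances rather than morbidity.
#'
#' @return A tibble with columns `start`, `end`, `label`, `profile_eligible`.
#' @export
icd10_chapters <- function() {
  path <- system.file("extdata", "icd10_chapters.csv", package = "mtoburden",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    start = readr::col_character(),
    end = readr::col_character(),
    label = readr::col_character(),
    profile_eligible = readr::col_logical()
  ))
}

# map "I25" -> comparable integer: letter index * 100 + numeric part.
# Codes may carry a subcategory suffix ("I25.1", "I251"); only the first
# three characters determine the chapter.
icd_index <- function(code) {
  stub <- toupper(substr(trimws(code), 1L, 3L))
  ok <- grepl("^[A-Z][0-9]{2}$", stub)
  idx <- rep(NA_real_, length(code))
  idx[ok] <- (match(substr(stub[ok], 1L, 1L), LETTERS) - 1L) * 100 +
    as.integer(substr(stub[ok], 2L, 3L))
  idx
}

# inverse of icd_index for generating codes inside a range
icd_code_from_index <- function(idx) {
  paste0(LETTERS[idx %/% 100 + 1L], sprintf("%02d", idx %% 100))
}

#' Assign ICD-10 chapters to diagnosis codes
#'
#' Maps each code to the unique chapter block whose range contains it.
#' Missing codes (`NA` or `""`) are first-class: they get the label
#' `"missing"` with `profile_eligible = FALSE`, never an error. A
#' non-missing code that does not parse as letter + two digits, or that
#' falls in a gap between chapter blocks (e.g. `"D49"`), is a
#' classification error.
#'
#' @param icd_code character vector of ICD-10 codes (block level; a
#'   subcategory suffix is ignored).
#' @return A tibble with one row per input code: `icd_code`, `code_range`
#'   (e.g. `"I00-I99"`), `label`, `profile_eligible`.
#' @examples
#' assign_icd_chapter(c("I25", "Z34", "M17", NA))
#' @export
assign_icd_chapter <- function(icd_code) {
  chapters <- icd10_chapters()
  lo <- icd_index(chapters$start)
  hi <- icd_index(chapters$end)

  idx <- icd_index(icd_code)
  missing <- is.na(icd_code) | trimws(as.character(icd_code)) == ""
  bad <- !missing & is.na(idx)
  if (any(bad)) {
    stop("unparseable ICD-10 code(s): ",
         paste(unique(icd_code[bad]), collapse = ", "),
         " (expected letter + two digits, e.g. 'I25')", call. = FALSE)
  }

  row <- rep(NA_integer_, length(icd_code))
  for (j in seq_along(lo)) {
    inside <- !is.na(idx) & idx >= lo[j] & idx <= hi[j]
    row[inside] <- j
  }
  unmapped <- !missing & is.na(row)
  if (any(unmapped)) {
    stop("ICD-10 code(s) outside every chapter block: ",
         paste(unique(icd_code[unmapped]), collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(
    icd_code = as.character(icd_code),
    code_range = ifelse(is.na(row), NA_character_,
                        paste0(chapters$start[row], "-", chapters$end[row])),
    label = ifelse(is.na(row), "missing", chapters$label[row]),
    profile_eligible = ifelse(is.na(row), FALSE, chapters$profile_eligible[row])
  )
  out
}

#' Add chapter columns to a survey table
#'
#' @param records survey tibble with an `icd_code` column.
#' @return `records` with `code_range`, `chapter` and `profile_eligible`
#'   columns appended.
#' @export
add_icd_chapter <- function(records) {
  ch <- assign_icd_chapter(records$icd_code)
  records$code_range <- ch$code_range
  records$chapter <- ch$label
  records$profile_eligible <- ch$profile_eligible
  records
}

#' Restrict records to the disease-profile subset
#'
#' Drops travelers whose diagnosis falls in the Z00–Z99 chapter (contact
#' with health services rather than morbidity) or is missing, the subset
#' used for disease-profile tables. The number of omitted records is
#' reported via `message()` and attached as `attr(, "n_omitted")`.
#'
#' @param records survey tibble with an `icd_code` column.
#' @return the profile-eligible subset, with attribute `n_omitted`.
#' @export
filter_disease_profile <- function(records) {
  eligible <- assign_icd_chapter(records$icd_code)$profile_eligible
  out <- records[eligible, , drop = FALSE]
  n_omitted <- sum(!eligible)
  message(n_omitted, " record(s) omitted from the disease profile ",
          "(Z-chapter or missing diagnosis)")
  if (nrow(out) == 0L) {
    warning("no profile-eligible records remain", call. = FALSE)
  }
  attr(out, "n_omitted") <- n_omitted
  out
}
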