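#' Cohort CSV schema
#'
#' One row per implant; comma-separated, UTF-8, header required, `.`
#' decimal separator, booleans as true/false. Units are fixed: mm for
#' widths, depths and bone loss; mg/dl for glucose; cigarettes/day for
#' smoking intensity.
#'
#' @return Named character vector mapping column names to their readr
#'   type shorthand.
#' @export
cohort_schema <- function() {
  c(patient_id = "c", implant_id = "c", sex = "c",
    periodontal_history = "l", compliant = "l", mpi = "i", mgi = "i",
    random_glucose_mg_dl = "d", smoking_status = "c",
    cigarettes_per_day = "i", residual_cement = "l",
    occlusal_overload = "l", keratinized_width_mm = "d", alcohol = "l",
    suppuration = "l",
    pd_mesiobuccal_mm = "d", pd_midbuccal_mm = "d",
    pd_distobuccal_mm = "d", pd_distolingual_mm = "d",
    pd_midlingual_mm = "d", pd_mesiolingual_mm = "d",
    crestal_bone_loss_mm = "d")
}

#' Validate implant records
#'
#' Checks every row of a cohort tibble against the record invariants
#' (score ranges, allowed categories, non-negative measurements,
#' cigarettes/day present for current smokers) and reports all
#' violations at once, each with its row number and field.
#'
#' @param records A tibble in the [cohort_schema()] layout.
#' @return `records`, invisibly, if valid; otherwise an error listing
#'   every offending row and field.
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(names(cohort_schema()), names(records))
  if (length(missing_cols)) {
    abort(sprintf("Cohort is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  problems <- list()
  note <- function(rows, field, msg) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<- tibble(
        row = rows, field = field, message = msg)
    }
  }
  bad_id <- which(is.na(records$patient_id) | is.na(records$implant_id))
  note(bad_id, "patient_id/implant_id", "identifier is missing")
  if (anyDuplicated(records$implant_id[!is.na(records$implant_id)])) {
    dup <- which(duplicated(records$implant_id))
    note(dup, "implant_id", "duplicated implant identifier")
  }
  note(which(!records$sex %in% c("F", "M")), "sex", "must be F or M")
  for (fld in c("periodontal_history", "compliant", "residual_cement",
                "occlusal_overload", "alcohol", "suppuration")) {
    note(which(is.na(records[[fld]])), fld, "must be true/false")
  }
  for (fld in c("mpi", "mgi")) {
    bad <- which(is.na(records[[fld]]) | !records[[fld]] %in% 0:3)
    note(bad, fld, "must be an integer in the allowed range 0-3")
  }
  for (fld in c("random_glucose_mg_dl", "keratinized_width_mm",
                "crestal_bone_loss_mm", pd_site_columns())) {
    bad <- which(is.na(records[[fld]]) | records[[fld]] < 0)
    note(bad, fld, "must be a non-negative number")
  }
  bad_status <- which(!records$smoking_status %in%
                        c("nonsmoker", "former", "current"))
  note(bad_status, "smoking_status",
       "must be nonsmoker, former or current")
  cur <- records$smoking_status == "current"
  note(which(cur & is.na(records$cigarettes_per_day)),
       "cigarettes_per_day", "required for current smokers")
  note(which(cur & records$cigarettes_per_day < 0),
       "cigarettes_per_day", "must be non-negative")

  if (length(problems)) {
    prob <- dplyr::arrange(dplyr::bind_rows(problems), .data$row)
    lines <- sprintf("row %d, %s: %s", prob$row, prob$field, prob$message)
    abort(paste0(c(sprintf("Invalid cohort (%d problem(s)):", nrow(prob)),
                   head(lines, 20L)), collapse = "\n"))
  }
  invisible(records)
}

#' Read and write cohort CSV files
#'
#' `read_cohort_csv()` reads a cohort file, checks that every schema
#' column is present, and validates all rows, reporting row-level
#' problems with line numbers. `write_cohort_csv()` writes a cohort back
#' out; a write-then-read round trip preserves every field exactly.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort_csv(study_fixture(), path)
#' cohort <- read_cohort_csv(path)
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  schema <- cohort_schema()
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing_cols <- setdiff(names(schema), hdr)
  if (length(missing_cols)) {
    abort(sprintf("Schema error: column(s) %s missing from '%s'.",
                  paste(missing_cols, collapse = ", "), path))
  }
  col_of <- list(c = readr::col_character(), l = readr::col_logical(),
                 i = readr::col_integer(), d = readr::col_double())
  records <- readr::read_csv(
    path, col_types = do.call(readr::cols_only, lapply(schema, function(t) col_of[[t]])),
    show_col_types = FALSE)
  parse_problems <- readr::problems(records)
  if (nrow(parse_problems)) {
    lines <- sprintf("row %d, column %s: expected %s, got '%s'",
                     parse_problems$row, hdr[parse_problems$col],
                     parse_problems$expected, parse_problems$actual)
    abort(paste0(c("Unparseable cell(s):", head(lines, 20L)),
                 collapse = "\n"))
  }
  records <- records[names(schema)]
  validate_records(records)
  ir_log("info", "Read %d implant record(s) from %s", nrow(records), path)
  records
}

#' @rdname read_cohort_csv
#' @param records A cohort tibble.
#' @export
write_cohort_csv <- function(records, path) {
  validate_records(records)
  readr::write_csv(records, path)
  invisible(path)
}
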