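#' Per-parameter risk scoring
#'
#' Each scorer maps a raw clinical measurement to its ordinal rubric score
#' and the associated risk-percentage contribution. All scorers are
#' vectorized and return a tibble with columns `score` and `percentage`.
#'
#' @param history_present Logical; previous history of periodontal disease.
#' @param compliant Logical; compliance with (supportive) periodontal
#'   therapy.
#' @param rubric A `risk_rubric`; defaults to the shipped rubric.
#'
#' @return A tibble with one row per input and columns `score` (integer)
#'   and `percentage` (risk contribution, percent).
#'
#' @examples
#' score_periodontal_history(TRUE, FALSE)
#' score_diabetes(c(95, 130))
#' score_smoking("current", cigarettes_per_day = 20)
#' @export
score_periodontal_history <- function(history_present, compliant,
                                      rubric = default_rubric()) {
  check_flag_vec(history_present, "history_present")
  check_flag_vec(compliant, "compliant")
  score <- as.integer(2L * history_present + !compliant)
  tibble(score = score,
         percentage = rubric_percentage(rubric,
                                        "periodontal_history_compliance",
                                        score))
}

#' @rdname score_periodontal_history
#' @param index_score Integer 0-3, a modified plaque index (MPI) or
#'   modified gingival index (MGI) grade. Both indices share the same
#'   score-to-percentage mapping.
#' @param parameter Which rubric block to read the percentage from:
#'   `"plaque_status"` or `"gingival_status"` (identical mappings in the
#'   default rubric).
#' @export
score_index <- function(index_score,
                        parameter = c("plaque_status", "gingival_status"),
                        rubric = default_rubric()) {
  parameter <- match.arg(parameter)
  if (!is.numeric(index_score) || anyNA(index_score) ||
      any(index_score != as.integer(index_score)) ||
      any(index_score < 0 | index_score > 3)) {
    abort(sprintf("Parameter '%s': index score must be an integer in 0-3.",
                  parameter))
  }
  score <- as.integer(index_score)
  tibble(score = score,
         percentage = rubric_percentage(rubric, parameter, score))
}

#' @rdname score_periodontal_history
#' @param random_glucose_mg_dl Random (non-fasting) blood glucose in mg/dl.
#'   Banded as below 102, [102, 110), [110, 118), [118, 126), [126, 134),
#'   and 134 or above.
#' @export
score_diabetes <- function(random_glucose_mg_dl, rubric = default_rubric()) {
  check_number(random_glucose_mg_dl, "random_glucose_mg_dl", min = 0)
  score <- findInterval(random_glucose_mg_dl, c(102, 110, 118, 126, 134))
  tibble(score = as.integer(score),
         percentage = rubric_percentage(rubric, "diabetes", score))
}

#' @rdname score_periodontal_history
#' @param status Smoking status: `"nonsmoker"`, `"former"` or `"current"`.
#' @param cigarettes_per_day Cigarettes smoked per day; required for
#'   current smokers, ignored otherwise. Bands: under 10, 10-19, exactly
#'   20, over 20.
#' @export
score_smoking <- function(status, cigarettes_per_day = NA_real_,
                          rubric = default_rubric()) {
  allowed <- c("nonsmoker", "former", "current")
  if (!all(status %in% allowed)) {
    abort(sprintf("Parameter 'smoking': status must be one of %s.",
                  paste(allowed, collapse = ", ")))
  }
  cigarettes_per_day <- rep_len(as.numeric(cigarettes_per_day),
                                length(status))
  cur <- status == "current"
  if (any(cur & is.na(cigarettes_per_day))) {
    abort("Parameter 'smoking': `cigarettes_per_day` is required for current smokers.")
  }
  if (any(cur & cigarettes_per_day < 0)) {
    abort("Parameter 'smoking': `cigarettes_per_day` must be non-negative.")
  }
  score <- integer(length(status))
  score[status == "former"] <- 1L
  cig <- cigarettes_per_day[cur]
  score[cur] <- ifelse(cig < 10, 2L, ifelse(cig < 20, 3L,
                ifelse(cig == 20, 4L, 5L)))
  tibble(score = score,
         percentage = rubric_percentage(rubric, "smoking", score))
}

#' @rdname score_periodontal_history
#' @param factor One of `"residual_cement"`, `"occlusal_overload"`,
#'   `"other_alcohol"`.
#' @param present Logical; whether the factor is present.
#' @export
score_binary_factor <- function(factor, present, rubric = default_rubric()) {
  allowed <- c("residual_cement", "occlusal_overload", "other_alcohol")
  if (length(factor) != 1L || !factor %in% allowed) {
    abort(sprintf("`factor` must be one of %s.",
                  paste(allowed, collapse = ", ")))
  }
  check_flag_vec(present, "present")
  score <- as.integer(present)
  tibble(score = score,
         percentage = rubric_percentage(rubric, factor, score))
}

#' @rdname score_periodontal_history
#' @param width_mm Keratinized-mucosa width in mm. Widths of 2 mm or more
#'   count as sufficient (score 0); below 2 mm as insufficient.
#' @export
score_keratinized_width <- function(width_mm, rubric = default_rubric()) {
  check_number(width_mm, "width_mm", min = 0)
  score <- as.integer(width_mm < 2)
  tibble(score = score,
         percentage = rubric_percentage(rubric, "keratinized_width", score))
}

#' Risk category from a total risk percentage
#'
#' Totals below 25 percent are low risk, 25 to 50 percent (inclusive)
#' moderate, and above 50 percent high.
#'
#' @param total_percentage Total risk percentage in \[0, 100\] (the nine
#'   rubric maxima sum to 100).
#' @return A factor with levels `low`, `moderate`, `high`.
#' @examples
#' categorize_risk(c(0, 24.9, 25, 50, 50.1, 95))
#' @export
categorize_risk <- function(total_percentage) {
  check_number(total_percentage, "total_percentage", min = 0)
  if (any(total_percentage > 100)) {
    abort("`total_percentage` must lie in [0, 100].")
  }
  lab <- ifelse(total_percentage < 25, "low",
         ifelse(total_percentage <= 50, "moderate", "high"))
  factor(lab, levels = c("low", "moderate", "high"))
}

# per-record long score table: one row per implant x parameter
score_records <- function(records, rubric) {
  score_of <- list(
    periodontal_history_compliance = function(r)
      score_periodontal_history(r$periodontal_history, r$compliant, rubric),
    plaque_status = function(r)
      score_index(r$mpi, "plaque_status", rubric),
    gingival_status = function(r)
      score_index(r$mgi, "gingival_status", rubric),
    diabetes = function(r)
      score_diabetes(r$random_glucose_mg_dl, rubric),
    smoking = function(r)
      score_smoking(r$smoking_status, r$cigarettes_per_day, rubric),
    residual_cement = function(r)
      score_binary_factor("residual_cement", r$residual_cement, rubric),
    occlusal_overload = function(r)
      score_binary_factor("occlusal_overload", r$occlusal_overload, rubric),
    keratinized_width = function(r)
      score_keratinized_width(r$keratinized_width_mm, rubric),
    other_alcohol = function(r)
      score_binary_factor("other_alcohol", r$alcohol, rubric)
  )
  purrr::imap_dfr(score_of, function(f, nm) {
    dplyr::bind_cols(
      tibble(patient_id = records$patient_id,
             implant_id = records$implant_id,
             parameter = nm),
      f(records)
    )
  })
}

#' Assess per-implant risk
#'
#' Scores each of the nine rubric parameters for every implant record,
#' sums the per-parameter risk percentages into a total, and attaches the
#' low/moderate/high category. Suppuration, while recorded per implant,
#' carries no rubric weight: it informs diagnosis only.
#'
#' @param records A tibble of implant records (see [read_cohort_csv()] for
#'   the column schema, or [study_fixture()] for an example cohort).
#' @param rubric A `risk_rubric`; defaults to the shipped rubric.
#'
#' @return A tibble of class `risk_profiles`: one row per implant with
#'   `<parameter>_score` and `<parameter>_pct` columns, `total_percentage`
#'   and `category`. [tidy()] returns the long per-parameter form;
#'   [glance()] a one-row category summary; [autoplot()] a bar chart of
#'   totals.
#'
#' @examples
#' cohort <- study_fixture()
#' profiles <- assess_risk(cohort)
#' dplyr::count(profiles, category)
#' @export
assess_risk <- function(records, rubric = default_rubric()) {
  validate_records(records)
  validate_rubric(rubric)
  long <- score_records(records, rubric)
  wide <- tidyr::pivot_wider(long,
                             id_cols = c("patient_id", "implant_id"),
                             names_from = "parameter",
                             values_from = c("score", "percentage"),
                             names_glue = "{parameter}_{.value}")
  names(wide) <- sub("_percentage$", "_pct", names(wide))
  totals <- dplyr::summarise(
    dplyr::group_by(long, .data$patient_id, .data$implant_id),
    total_percentage = sum(.data$percentage), .groups = "drop")
  out <- dplyr::left_join(wide, totals, by = c("patient_id", "implant_id"))
  out$category <- categorize_risk(out$total_percentage)
  out <- out[match(records$implant_id, out$implant_id), ]
  structure(as_tibble(out), class = c("risk_profiles", class(as_tibble(out))))
}

#' @method tidy risk_profiles
#' @export
tidy.risk_profiles <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x)[c("patient_id", "implant_id",
                   grep("_(score|pct)$", names(x), value = TRUE))],
    cols = -c("patient_id", "implant_id"),
    names_to = c("parameter", ".value"),
    names_pattern = "(.*)_(score|pct)$")
  dplyr::rename(long, percentage = "pct")
}

#' @method glance risk_profiles
#' @export
glance.risk_profiles <- function(x, ...) {
  tibble(n_implants = nrow(x),
         n_low = sum(x$category == "low"),
         n_moderate = sum(x$category == "moderate"),
         n_high = sum(x$category == "high"),
         mean_total = mean(x$total_percentage))
}

#' @method autoplot risk_profiles
#' @export
autoplot.risk_profiles <- function(object, ...) {
  df <- as_tibble(object)
  df$implant_id <- factor(df$implant_id,
                          levels = df$implant_id[order(df$total_percentage)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$implant_id,
                                   y = .data$total_percentage,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(25, 50), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Total risk (%)", fill = "Category") +
    ggplot2::theme_minimal()
}
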