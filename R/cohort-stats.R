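#' Pearson chi-square on a contingency table
#'
#' Computes the uncorrected Pearson statistic (no Yates continuity
#' correction) on the observed counts after removing rows and columns
#' whose counts are all zero; degrees of freedom are
#' `(rows - 1) * (cols - 1)` of the reduced table. A warning is issued
#' when any expected count falls below 5 — the test is still computed, as
#' is conventional in small clinical series.
#'
#' @param observed A matrix of non-negative integer counts, or a
#'   `contingency_table` from [build_contingency()].
#' @return An object of class `contingency_result` with elements
#'   `observed`, `expected`, `statistic`, `df`, `p_value`,
#'   `dropped_rows`, `dropped_cols`. [tidy()]/[glance()] return a
#'   one-row tibble.
#' @examples
#' pearson_chi_square(matrix(c(0, 4, 7, 10), nrow = 2))
#' @export
pearson_chi_square <- function(observed) {
  meta <- list(factor = NULL, outcome = NULL)
  if (inherits(observed, "contingency_table")) {
    meta <- observed[c("factor", "outcome")]
    observed <- observed$observed
  }
  if (!is.matrix(observed) || !is.numeric(observed)) {
    abort("`observed` must be a numeric count matrix.")
  }
  if (anyNA(observed) || any(observed < 0) ||
      any(observed != round(observed))) {
    abort("`observed` must contain non-negative integer counts.")
  }
  keep_r <- rowSums(observed) > 0
  keep_c <- colSums(observed) > 0
  dropped_rows <- rownames(observed)[!keep_r]
  dropped_cols <- colnames(observed)[!keep_c]
  obs <- observed[keep_r, keep_c, drop = FALSE]
  if (nrow(obs) < 2L || ncol(obs) < 2L) {
    abort("Degenerate margins: need at least 2 non-zero rows and 2 non-zero columns.")
  }
  ct <- suppressWarnings(chisq.test(obs, correct = FALSE))
  if (any(ct$expected < 5)) {
    warn(sprintf("Expected count below 5 in %d of %d cells; chi-square approximation may be poor.",
                 sum(ct$expected < 5), length(ct$expected)))
  }
  structure(
    list(factor = meta$factor, outcome = meta$outcome,
         observed = obs, expected = ct$expected,
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value),
         dropped_rows = dropped_rows %||% character(),
         dropped_cols = dropped_cols %||% character()),
    class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, digits = 3, ...) {
  cat("Pearson chi-square (no continuity correction)\n")
  if (!is.null(x$factor)) cat("Factor:", x$factor, "\n")
  print(x$observed)
  dropped <- c(x$dropped_rows, x$dropped_cols)
  if (length(dropped)) {
    cat("Dropped all-zero categories:", paste(dropped, collapse = ", "), "\n")
  }
  cat(sprintf("X-squared = %.*f, df = %d, p-value = %.*f\n",
              digits, x$statistic, x$df, digits, x$p_value))
  invisible(x)
}

#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble(factor = x$factor %||% NA_character_,
         statistic = x$statistic, df = x$df, p_value = x$p_value,
         min_expected = min(x$expected),
         n = sum(x$observed))
}

#' @method glance contingency_result
#' @export
glance.contingency_result <- function(x, ...) tidy(x)

#' Upper-tail chi-square probability
#'
#' @param statistic Non-negative chi-square statistic.
#' @param df Degrees of freedom (positive integer).
#' @return The upper-tail probability `P(X >= statistic)`.
#' @examples
#' chi_square_p(5.219, 1)
#' @export
chi_square_p <- function(statistic, df) {
  check_number(statistic, "statistic", min = 0)
  if (!is.numeric(df) || anyNA(df) || any(df < 1) || any(df != round(df))) {
    abort("`df` must be a positive integer.")
  }
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Two-sample test of proportions
#'
#' Two-sided z-test for equality of two binomial proportions with pooled
#' variance and no continuity correction.
#'
#' @param successes_a,n_a Successes and trials in group A.
#' @param successes_b,n_b Successes and trials in group B.
#' @return A one-row tibble: `estimate_a`, `estimate_b`, `z`, `p_value`.
#' @examples
#' two_proportion_test(10, 10, 0, 10)
#' @export
two_proportion_test <- function(successes_a, n_a, successes_b, n_b) {
  for (nm in c("successes_a", "n_a", "successes_b", "n_b")) {
    check_number(get(nm), nm, min = 0)
  }
  if (n_a < 1 || n_b < 1) abort("Both groups must have at least one trial.")
  if (successes_a > n_a || successes_b > n_b) {
    abort("Successes cannot exceed trials.")
  }
  p_a <- successes_a / n_a
  p_b <- successes_b / n_b
  p_pool <- (successes_a + successes_b) / (n_a + n_b)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n_a + 1 / n_b))
  z <- if (se == 0) 0 else (p_a - p_b) / se
  tibble(estimate_a = p_a, estimate_b = p_b, z = z,
         p_value = 2 * pnorm(-abs(z)))
}

#' Build a factor-by-diagnosis contingency table
#'
#' Cross-tabulates a derived cohort factor against the diagnosis label.
#' Factor levels with zero counts in every diagnosis group are retained
#' in the table but recorded so [pearson_chi_square()] can exclude them.
#'
#' @param records A tibble of implant records.
#' @param factor Name of a derived cohort factor; see
#'   [evaluation_factors()] for the available names.
#' @param rubric Rubric used for the `result` (risk category) factor.
#' @param mode Diagnosis mode passed to [classify_implants()].
#' @return A `contingency_table`: list with `factor`, `outcome`,
#'   `observed` (levels x diagnosis count matrix) and `n`.
#' @examples
#' build_contingency(study_fixture(), "sex")
#' @export
build_contingency <- function(records, factor, rubric = default_rubric(),
                              mode = c("pragmatic", "strict")) {
  mode <- match.arg(mode)
  derived <- cohort_factor_table(records, rubric, mode)
  if (!factor %in% names(derived)) {
    abort(sprintf("Unknown cohort factor '%s'. Available: %s.", factor,
                  paste(evaluation_factors(), collapse = ", ")))
  }
  contingency_from_derived(derived, factor)
}

contingency_from_derived <- function(derived, factor) {
  f <- derived[[factor]]
  d <- derived$diagnosis
  miss <- which(is.na(f) | is.na(d))
  if (length(miss)) {
    abort(sprintf("Missing %s or diagnosis for implant(s): %s.", factor,
                  paste(derived$implant_id[miss], collapse = ", ")))
  }
  observed <- unclass(table(f, d))
  dimnames(observed) <- list(levels(f), levels(d))
  structure(list(factor = factor, outcome = "diagnosis",
                 observed = observed, n = nrow(derived)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table: %s x %s (n = %d)\n",
              x$factor, x$outcome, x$n))
  print(x$observed)
  invisible(x)
}

#' Per-level cohort proportions
#'
#' @param records A tibble of implant records.
#' @param factor A derived cohort factor name (see [build_contingency()]).
#' @param rubric,mode Passed through to the factor derivation.
#' @return A tibble with `level`, `n` and `pct` (percent of the cohort,
#'   rounded to one decimal).
#' @examples
#' cohort_proportions(study_fixture(), "plaque_status")
#' @export
cohort_proportions <- function(records, factor, rubric = default_rubric(),
                               mode = c("pragmatic", "strict")) {
  mode <- match.arg(mode)
  derived <- cohort_factor_table(records, rubric, mode)
  if (!factor %in% names(derived)) {
    abort(sprintf("Unknown cohort factor '%s'.", factor))
  }
  counts <- table(derived[[factor]])
  tibble(level = names(counts),
         n = as.integer(counts),
         pct = round(100 * as.integer(counts) / nrow(derived), 1))
}

#' Factors evaluated against the diagnosis
#'
#' @return Character vector of the derived cohort factor names.
#' @export
evaluation_factors <- function() {
  c("sex", "suppuration", "pdl_history", "plaque_status", "gingival_status",
    "diabetes", "smoking", "residual_cement", "occlusal_overload",
    "keratinized_width", "others", "result")
}

# derive the categorical evaluation factors from raw records.
# "present" for keratinized_width means the RISK is present, i.e. the
# width is insufficient (< 2 mm); diabetes present means random glucose
# >= 126 mg/dl; smoking present covers former and current smokers.
cohort_factor_table <- function(records, rubric, mode) {
  validate_records(records)
  if (nrow(records) == 0L) abort("Empty cohort.")
  profiles <- assess_risk(records, rubric)
  diag <- withCallingHandlers(
    classify_implants(records, mode),
    warning = function(w) {
      ir_log("warn", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pa <- function(x) factor(ifelse(x, "present", "absent"),
                           levels = c("absent", "present"))
  score_f <- function(s) factor(paste("Score", s),
                                levels = paste("Score", 0:3))
  tibble(
    patient_id = records$patient_id,
    implant_id = records$implant_id,
    sex = factor(records$sex, levels = c("F", "M")),
    suppuration = pa(records$suppuration),
    pdl_history = score_f(profiles$periodontal_history_compliance_score),
    plaque_status = score_f(records$mpi),
    gingival_status = score_f(records$mgi),
    diabetes = pa(records$random_glucose_mg_dl >= 126),
    smoking = pa(records$smoking_status != "nonsmoker"),
    residual_cement = pa(records$residual_cement),
    occlusal_overload = pa(records$occlusal_overload),
    keratinized_width = pa(records$keratinized_width_mm < 2),
    others = pa(records$alcohol),
    result = profiles$category,
    total_percentage = profiles$total_percentage,
    diagnosis = droplevels(diag$diagnosis)
  )
}

#' Cohort-level evaluation of risk factors against diagnosis
#'
#' Builds every factor-by-diagnosis contingency table, computes the
#' uncorrected Pearson chi-square where the table is non-degenerate
#' (at least two non-zero factor levels and two diagnosis groups), and
#' reports per-level counts with within-diagnosis percentages.
#'
#' @param records A tibble of implant records.
#' @param rubric Risk rubric for the `result` factor.
#' @param mode Diagnosis mode (default pragmatic).
#' @param factors Factors to evaluate; defaults to all of
#'   [evaluation_factors()].
#' @return An object of class `cohort_evaluation`: list with `counts`
#'   (long per-level tibble), `tests` (per-factor statistic, df,
#'   p-value), `n_implants`, `n_patients`, `mode`. [tidy()] returns the
#'   tests, [glance()] a one-row summary, [autoplot()] a p-value chart.
#' @examples
#' ev <- evaluate_cohort(study_fixture())
#' tidy(ev)
#' @export
evaluate_cohort <- function(records, rubric = default_rubric(),
                            mode = c("pragmatic", "strict"),
                            factors = evaluation_factors()) {
  mode <- match.arg(mode)
  derived <- cohort_factor_table(records, rubric, mode)
  diag_levels <- levels(derived$diagnosis)

  counts <- purrr::map_dfr(factors, function(fct) {
    tab <- table(derived[[fct]], derived$diagnosis)
    lev <- rownames(tab)
    out <- tibble(factor = fct, level = lev,
                  n = as.integer(rowSums(tab)))
    for (dg in diag_levels) {
      cnt <- as.integer(tab[, dg])
      out[[paste0(dg, "_n")]] <- cnt
      tot <- sum(cnt)
      out[[paste0(dg, "_pct")]] <- round(100 * cnt / max(tot, 1L), 1)
    }
    out
  })

  tests <- purrr::map_dfr(factors, function(fct) {
    ct <- contingency_from_derived(derived, fct)
    keep_r <- rowSums(ct$observed) > 0
    keep_c <- colSums(ct$observed) > 0
    degenerate <- sum(keep_r) < 2 || sum(keep_c) < 2
    if (degenerate) {
      return(tibble(factor = fct, statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, min_expected = NA_real_,
                    dropped = paste(rownames(ct$observed)[!keep_r],
                                    collapse = ";"),
                    note = "degenerate (single non-zero category)"))
    }
    res <- withCallingHandlers(
      pearson_chi_square(ct),
      warning = function(w) {
        ir_log("warn", "Factor '%s': %s", fct, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tibble(factor = fct, statistic = res$statistic,
           df = as.integer(res$df), p_value = res$p_value,
           min_expected = min(res$expected),
           dropped = paste(c(res$dropped_rows, res$dropped_cols),
                           collapse = ";"),
           note = "")
  })

  structure(list(counts = counts, tests = tests,
                 n_implants = nrow(derived),
                 n_patients = length(unique(derived$patient_id)),
                 mode = mode),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort evaluation: %d implants in %d patients (%s mode)\n\n",
              x$n_implants, x$n_patients, x$mode))
  tests <- x$tests
  tests$statistic <- round(tests$statistic, digits)
  tests$p_value <- round(tests$p_value, digits)
  print(as.data.frame(tests[c("factor", "statistic", "df", "p_value")]),
        row.names = FALSE)
  invisible(x)
}

#' @method tidy cohort_evaluation
#' @export
tidy.cohort_evaluation <- function(x, ...) x$tests

#' @method glance cohort_evaluation
#' @export
glance.cohort_evaluation <- function(x, ...) {
  tibble(n_implants = x$n_implants, n_patients = x$n_patients,
         n_factors = nrow(x$tests),
         n_tested = sum(!is.na(x$tests$statistic)),
         n_significant = sum(x$tests$p_value < 0.05, na.rm = TRUE),
         mode = x$mode)
}

#' @method autoplot cohort_evaluation
#' @export
autoplot.cohort_evaluation <- function(object, alpha = 0.05, ...) {
  df <- object$tests[!is.na(object$tests$statistic), ]
  df$factor <- factor(df$factor, levels = df$factor[order(df$p_value,
                                                          decreasing = TRUE)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$p_value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Chi-square p-value") +
    ggplot2::theme_minimal()
}
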