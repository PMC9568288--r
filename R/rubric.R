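#' Risk rubrics
#'
#' A risk rubric maps, for each scored clinical parameter, an ordinal score
#' to a risk-percentage contribution. The shipped default carries nine
#' parameters (periodontal history/compliance, plaque status, gingival
#' status, diabetes, smoking, residual cement, occlusal overload,
#' keratinized-mucosa width, alcohol) whose maximum contributions sum to
#' 100 percent. Rubrics are plain tibbles (one row per parameter level) so
#' alternative weightings can be loaded from a YAML file and passed to
#' [assess_risk()].
#'
#' @param path Path to a rubric YAML file.
#'
#' @return A tibble of class `risk_rubric` with columns `parameter`,
#'   `label`, `score`, `descriptor`, `percentage`.
#'
#' @examples
#' rub <- default_rubric()
#' dplyr::summarise(dplyr::group_by(rub, parameter),
#'                  max_pct = max(percentage))
#' @export
default_rubric <- function() {
  read_rubric(system.file("extdata", "risk_rubric.yaml",
                          package = "implantrisk", mustWork = TRUE))
}

#' @rdname default_rubric
#' @export
read_rubric <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Rubric file not found: '%s'.", path))
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) {
    abort("Rubric YAML must have a top-level `parameters` list.")
  }
  rubric <- purrr::map_dfr(doc$parameters, function(par) {
    purrr::map_dfr(par$levels, function(lv) {
      tibble(parameter = par$name,
             label = par$label %||% par$name,
             score = as.integer(lv$score),
             descriptor = as.character(lv$descriptor),
             percentage = as.numeric(lv$percentage))
    })
  })
  rubric <- structure(rubric, class = c("risk_rubric", class(rubric)))
  validate_rubric(rubric)
}

#' @rdname default_rubric
#' @param rubric A `risk_rubric` tibble.
#' @export
write_rubric <- function(rubric, path) {
  validate_rubric(rubric)
  doc <- list(parameters = purrr::map(
    split(rubric, factor(rubric$parameter, unique(rubric$parameter))),
    function(p) list(
      name = p$parameter[[1]],
      label = p$label[[1]],
      levels = purrr::pmap(p[c("score", "descriptor", "percentage")],
                           function(score, descriptor, percentage) {
                             list(score = score, descriptor = descriptor,
                                  percentage = percentage)
                           })
    )
  ))
  names(doc$parameters) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname default_rubric
#' @export
validate_rubric <- function(rubric) {
  need <- c("parameter", "score", "descriptor", "percentage")
  missing_cols <- setdiff(need, names(rubric))
  if (length(missing_cols)) {
    abort(sprintf("Rubric is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(rubric$percentage) || any(rubric$percentage < 0)) {
    abort("Rubric percentages must be non-negative and non-missing.")
  }
  by_par <- split(rubric, rubric$parameter)
  for (p in by_par) {
    ord <- order(p$score)
    if (any(duplicated(p$score))) {
      abort(sprintf("Rubric parameter '%s' has duplicated scores.",
                    p$parameter[[1]]))
    }
    if (is.unsorted(p$percentage[ord])) {
      abort(sprintf(
        "Rubric parameter '%s': percentages must be non-decreasing in score.",
        p$parameter[[1]]))
    }
  }
  invisible(rubric)
}

# percentage lookup for (parameter, score) pairs; errors name the parameter
rubric_percentage <- function(rubric, parameter, score) {
  rows <- rubric[rubric$parameter == parameter, ]
  if (nrow(rows) == 0L) {
    abort(sprintf("Unknown rubric parameter '%s'.", parameter))
  }
  idx <- match(score, rows$score)
  if (anyNA(idx)) {
    abort(sprintf(
      "Parameter '%s': score %s is not a rubric level (allowed: %s).",
      parameter, paste(unique(score[is.na(idx)]), collapse = ", "),
      paste(sort(rows$score), collapse = ", ")))
  }
  rows$percentage[idx]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
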