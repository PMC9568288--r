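# internal helpers: argument checks and leveled logging

check_number <- function(x, what, min = -Inf, allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", what))
  }
  bad <- !is.na(x) & x < min
  if (any(bad)) {
    abort(sprintf("`%s` must be >= %s (got %s).", what, min,
                  paste(unique(x[bad]), collapse = ", ")))
  }
  if (!allow_na && anyNA(x)) {
    abort(sprintf("`%s` contains missing values.", what))
  }
  invisible(x)
}

check_flag_vec <- function(x, what) {
  if (!is.logical(x) || anyNA(x)) {
    abort(sprintf("`%s` must be TRUE/FALSE with no missing values.", what))
  }
  invisible(x)
}

#' @noRd
log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L, quiet = 5L)

ir_log <- function(level, ..., .envir = parent.frame()) {
  threshold <- getOption("implantrisk.log_level", "info")
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), sprintf(...)))
  }
  invisible(NULL)
}
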