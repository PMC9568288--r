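# builders for implant records at chosen factor levels

make_record <- function(...) {
  rec <- tibble::tibble(
    patient_id = "P1", implant_id = "I1", sex = "M",
    periodontal_history = FALSE, compliant = TRUE, mpi = 0L, mgi = 0L,
    random_glucose_mg_dl = 90, smoking_status = "nonsmoker",
    cigarettes_per_day = NA_integer_, residual_cement = FALSE,
    occlusal_overload = FALSE, keratinized_width_mm = 3, alcohol = FALSE,
    suppuration = FALSE,
    pd_mesiobuccal_mm = 3, pd_midbuccal_mm = 3, pd_distobuccal_mm = 3,
    pd_distolingual_mm = 3, pd_midlingual_mm = 3, pd_mesiolingual_mm = 3,
    crestal_bone_loss_mm = 0)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# every rubric parameter at its maximum level
make_max_record <- function() {
  make_record(periodontal_history = TRUE, compliant = FALSE,
              mpi = 3L, mgi = 3L, random_glucose_mg_dl = 140,
              smoking_status = "current", cigarettes_per_day = 25L,
              residual_cement = TRUE, occlusal_overload = TRUE,
              keratinized_width_mm = 1, alcohol = TRUE)
}

# per-parameter level setters used by the monotonicity property: each
# entry maps a level index (1-based) to record field values
parameter_levels <- function() {
  list(
    periodontal_history_compliance = list(
      function(r) make_record_fields(r, periodontal_history = FALSE, compliant = TRUE),
      function(r) make_record_fields(r, periodontal_history = FALSE, compliant = FALSE),
      function(r) make_record_fields(r, periodontal_history = TRUE, compliant = TRUE),
      function(r) make_record_fields(r, periodontal_history = TRUE, compliant = FALSE)),
    plaque_status = lapply(0:3, function(s) function(r) make_record_fields(r, mpi = s)),
    gingival_status = lapply(0:3, function(s) function(r) make_record_fields(r, mgi = s)),
    diabetes = lapply(c(95, 105, 112, 120, 130, 140),
                      function(g) function(r) make_record_fields(r, random_glucose_mg_dl = g)),
    smoking = list(
      function(r) make_record_fields(r, smoking_status = "nonsmoker", cigarettes_per_day = NA_integer_),
      function(r) make_record_fields(r, smoking_status = "former", cigarettes_per_day = NA_integer_),
      function(r) make_record_fields(r, smoking_status = "current", cigarettes_per_day = 5L),
      function(r) make_record_fields(r, smoking_status = "current", cigarettes_per_day = 15L),
      function(r) make_record_fields(r, smoking_status = "current", cigarettes_per_day = 20L),
      function(r) make_record_fields(r, smoking_status = "current", cigarettes_per_day = 30L)),
    residual_cement = lapply(c(FALSE, TRUE), function(p) function(r) make_record_fields(r, residual_cement = p)),
    occlusal_overload = lapply(c(FALSE, TRUE), function(p) function(r) make_record_fields(r, occlusal_overload = p)),
    keratinized_width = lapply(c(3, 1), function(w) function(r) make_record_fields(r, keratinized_width_mm = w)),
    other_alcohol = lapply(c(FALSE, TRUE), function(p) function(r) make_record_fields(r, alcohol = p))
  )
}

make_record_fields <- function(rec, ...) {
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# independent chi-square oracle: explicit double loop over cells
chisq_loop <- function(O) {
  n <- sum(O)
  s <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      E <- sum(O[i, ]) * sum(O[, j]) / n
      s <- s + (O[i, j] - E)^2 / E
    }
  }
  s
}

# independent upper-tail probability: numeric integration of the
# chi-square density written out explicitly
chisq_upper_num <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-10)$value
}
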