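#' Deterministic 21-implant study cohort
#'
#' Reconstructs a small clinical implant cohort — 21 implants in 13
#' patients (5 female, 8 male), 17 with peri-implant mucositis and 4 with
#' peri-implantitis — whose per-factor by diagnosis margins match the
#' published cross-tabulations exactly: sex, periodontal-history score,
#' plaque score, gingival score, smoking, residual cement, occlusal
#' overload, keratinized-width sufficiency, alcohol, and the resulting
#' risk category (15 low / 6 moderate). Suppuration and diabetes are
#' absent throughout.
#'
#' Only the margins are identified by the published tables; the joint
#' assignment of factor levels to individual implants is a fixed,
#' hand-designed configuration chosen so that all margins (including the
#' risk-category margin) hold simultaneously and patient-level attributes
#' (sex, smoking, periodontal history, alcohol) are constant within each
#' patient. Continuous measurements are fixed representative values
#' consistent with the categorical levels: glucose 92 mg/dl (non-diabetic
#' band), keratinized width 3.0 mm when sufficient and 1.0 mm when not,
#' crestal bone loss 1.0 mm for mucositis and 3.0 mm for peri-implantitis
#' implants, and six-site probing depths averaging 4.0 mm (mucositis) or
#' 6.0 mm (peri-implantitis).
#'
#' @return A tibble of 21 implant records (one row per implant) in the
#'   shared cohort CSV schema. Bit-identical across calls: the fixture
#'   contains no randomness.
#' @examples
#' fx <- study_fixture()
#' table(classify_implants(fx)$diagnosis)
#' @export
study_fixture <- function() {
  # per-implant design: pdl score (0/1/3), mpi, mgi, smoking, overload,
  # width sufficiency, alcohol; first 17 mucositis, last 4 peri-implantitis
  design <- tibble(
    implant = sprintf("IMP%02d", 1:21),
    patient = c("P01", "P01", "P02", "P02", "P03", "P04", "P05",
                "P06", "P06", "P07", "P07", "P08", "P08", "P09", "P09",
                "P10", "P10", "P11", "P12", "P12", "P13"),
    sex = c(rep("F", 7), rep("M", 14)),
    pdl = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0, 0, 0, 0, 3, 3, 3, 3,
            0, 3, 3, 3),
    mpi = c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 2, 0, 2, 0, 2, 3, 3,
            1, 2, 2, 2),
    mgi = c(0, 0, 0, 0, 0, 0, 0, 1, 0, 1, 0, 2, 0, 0, 2, 2, 2,
            1, 1, 2, 2),
    smoking = c(rep("nonsmoker", 7), "former", "former",
                rep("nonsmoker", 8), "nonsmoker", "current", "current",
                "nonsmoker"),
    overload = c(rep(FALSE, 16), TRUE, FALSE, FALSE, FALSE, TRUE),
    sufficient_width = c(rep(TRUE, 11), FALSE, FALSE, TRUE, FALSE,
                         TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    alcohol = c(rep(FALSE, 6), TRUE, FALSE, FALSE, TRUE, TRUE,
                FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, TRUE, TRUE, TRUE),
    diseased_bone = c(rep(FALSE, 17), rep(TRUE, 4))
  )
  pd <- t(vapply(design$diseased_bone,
                 function(d) if (d) c(5, 6, 7, 7, 6, 5) else c(3, 4, 5, 5, 4, 3),
                 numeric(6)))
  colnames(pd) <- pd_site_columns()

  dplyr::bind_cols(
    tibble(
      patient_id = design$patient,
      implant_id = design$implant,
      sex = design$sex,
      periodontal_history = design$pdl >= 2,
      compliant = design$pdl %in% c(0, 2),
      mpi = as.integer(design$mpi),
      mgi = as.integer(design$mgi),
      random_glucose_mg_dl = 92,
      smoking_status = design$smoking,
      cigarettes_per_day = ifelse(design$smoking == "current", 5L,
                                  NA_integer_),
      residual_cement = FALSE,
      occlusal_overload = design$overload,
      keratinized_width_mm = ifelse(design$sufficient_width, 3, 1),
      alcohol = design$alcohol,
      suppuration = FALSE
    ),
    as_tibble(pd),
    tibble(crestal_bone_loss_mm = ifelse(design$diseased_bone, 3, 1))
  )
}

#' Specify a synthetic implant cohort
#'
#' Describes a stochastic cohort generator: number of patients, implants
#' per patient, diagnosis prevalence, and per-factor level probabilities
#' conditional on diagnosis. The defaults emulate the study cohort: 13
#' patients carrying 1-2 implants each, a 5/13 chance of a female
#' patient, diagnosis prevalence (0, 17/21, 4/21) over (healthy,
#' mucositis, peri-implantitis), and conditional factor probabilities
#' equal to the study margins.
#'
#' @param n_patients Number of patients.
#' @param implants_per_patient Either a single count or a length-2
#'   integer range sampled uniformly per patient.
#' @param diagnosis_prevalence Named probabilities over `healthy`,
#'   `mucositis`, `peri_implantitis`; must sum to 1.
#' @param p_female Probability that a patient is female.
#' @param factor_probs Per-diagnosis factor probabilities; see
#'   [default_factor_probs()].
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   through it.
#' @return A validated list of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_patients = 50, seed = 7)
#' nrow(generate_cohort(spec))
#' @export
cohort_spec <- function(n_patients = 13,
                        implants_per_patient = c(1, 2),
                        diagnosis_prevalence = c(healthy = 0,
                                                 mucositis = 17 / 21,
                                                 peri_implantitis = 4 / 21),
                        p_female = 5 / 13,
                        factor_probs = default_factor_probs(),
                        seed = 1L) {
  check_number(n_patients, "n_patients", min = 1)
  if (!length(implants_per_patient) %in% 1:2 ||
      any(implants_per_patient < 1)) {
    abort("`implants_per_patient` must be a positive count or range.")
  }
  need <- c("healthy", "mucositis", "peri_implantitis")
  if (!setequal(names(diagnosis_prevalence), need)) {
    abort("`diagnosis_prevalence` must be named healthy/mucositis/peri_implantitis.")
  }
  diagnosis_prevalence <- diagnosis_prevalence[need]
  check_prob_vector(diagnosis_prevalence, "diagnosis_prevalence")
  check_prob_scalar(p_female, "p_female")
  for (dg in names(factor_probs)) {
    fp <- factor_probs[[dg]]
    for (nm in c("pdl_history", "mpi", "mgi")) {
      check_prob_vector(fp[[nm]], paste0(dg, "$", nm))
    }
    for (nm in c("smoking_present", "p_current_given_smoker",
                 "occlusal_overload", "residual_cement",
                 "width_insufficient", "alcohol", "suppuration",
                 "diabetes")) {
      check_prob_scalar(fp[[nm]], paste0(dg, "$", nm))
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 implants_per_patient = as.integer(implants_per_patient),
                 diagnosis_prevalence = diagnosis_prevalence,
                 p_female = p_female,
                 factor_probs = factor_probs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

check_prob_vector <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` must be non-negative probabilities summing to 1.",
                  what))
  }
  invisible(p)
}

check_prob_scalar <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1].", what))
  }
  invisible(p)
}

#' Default per-diagnosis factor probabilities
#'
#' Level probabilities for each risk factor, conditional on diagnosis,
#' taken from the study cohort margins (healthy implants default to the
#' zero level of every factor).
#'
#' @return A named list with elements `healthy`, `mucositis`,
#'   `peri_implantitis`.
#' @export
default_factor_probs <- function() {
  zero4 <- c(`0` = 1, `1` = 0, `2` = 0, `3` = 0)
  healthy <- list(pdl_history = zero4, mpi = zero4, mgi = zero4,
                  smoking_present = 0, p_current_given_smoker = 0,
                  occlusal_overload = 0, residual_cement = 0,
                  width_insufficient = 0, alcohol = 0, suppuration = 0,
                  diabetes = 0)
  mucositis <- list(
    pdl_history = c(`0` = 8, `1` = 5, `2` = 0, `3` = 4) / 17,
    mpi = c(`0` = 4, `1` = 8, `2` = 3, `3` = 2) / 17,
    mgi = c(`0` = 11, `1` = 2, `2` = 4, `3` = 0) / 17,
    smoking_present = 2 / 17, p_current_given_smoker = 0,
    occlusal_overload = 1 / 17, residual_cement = 0,
    width_insufficient = 3 / 17, alcohol = 3 / 17, suppuration = 0,
    diabetes = 0)
  peri_implantitis <- list(
    pdl_history = c(`0` = 1, `1` = 0, `2` = 0, `3` = 3) / 4,
    mpi = c(`0` = 0, `1` = 1, `2` = 3, `3` = 0) / 4,
    mgi = c(`0` = 0, `1` = 2, `2` = 2, `3` = 0) / 4,
    smoking_present = 2 / 4, p_current_given_smoker = 1,
    occlusal_overload = 1 / 4, residual_cement = 0,
    width_insufficient = 2 / 4, alcohol = 3 / 4, suppuration = 0,
    diabetes = 0)
  list(healthy = healthy, mucositis = mucositis,
       peri_implantitis = peri_implantitis)
}

#' Generate a synthetic implant cohort
#'
#' Samples patients, their implants and per-implant factor levels from a
#' [cohort_spec()], then synthesizes raw clinical measurements consistent
#' with the sampled levels (representative glucose per diabetes band,
#' widths of 3.0/1.0 mm, diagnosis-specific bone loss and probing
#' depths). Records are constructed so the pragmatic classifier recovers
#' the sampled diagnosis: healthy implants carry no inflammation sign and
#' zero bone loss; peri-implantitis implants always show at least an MGI
#' of 1 and bone loss above 2 mm.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of implant records in the shared cohort schema;
#'   reproducible for a given `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a `cohort_spec`.")
  }
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  ipp <- spec$implants_per_patient
  n_pat <- spec$n_patients
  n_imp_per <- if (length(ipp) == 1L) {
    rep(ipp, n_pat)
  } else {
    sample(seq(ipp[1], ipp[2]), n_pat, replace = TRUE)
  }
  sex_pat <- ifelse(stats::runif(n_pat) < spec$p_female, "F", "M")
  pat_idx <- rep(seq_len(n_pat), n_imp_per)
  n <- length(pat_idx)
  dg <- sample(names(spec$diagnosis_prevalence), n, replace = TRUE,
               prob = spec$diagnosis_prevalence)

  # per-diagnosis conditional draws, vectorized over implants
  fp_of <- function(field) {
    vapply(dg, function(d) spec$factor_probs[[d]][[field]], numeric(1),
           USE.NAMES = FALSE)
  }
  draw_level <- function(field) {
    out <- integer(n)
    for (d in unique(dg)) {
      idx <- dg == d
      p <- spec$factor_probs[[d]][[field]]
      out[idx] <- as.integer(sample(names(p), sum(idx), replace = TRUE,
                                    prob = p))
    }
    out
  }
  pdl <- draw_level("pdl_history")
  mpi <- draw_level("mpi")
  mgi <- draw_level("mgi")
  supp <- stats::runif(n) < fp_of("suppuration")

  healthy_i <- dg == "healthy"
  mpi[healthy_i] <- 0L
  mgi[healthy_i] <- 0L
  supp[healthy_i] <- FALSE
  # guarantee an inflammation sign wherever the bone is diseased
  need_sign <- dg == "peri_implantitis" & mgi == 0L & mpi < 2L & !supp
  mgi[need_sign] <- 1L

  smoker <- stats::runif(n) < fp_of("smoking_present")
  current <- smoker & stats::runif(n) < fp_of("p_current_given_smoker")
  status <- ifelse(!smoker, "nonsmoker",
                   ifelse(current, "current", "former"))
  diabetic <- stats::runif(n) < fp_of("diabetes")
  insuff <- stats::runif(n) < fp_of("width_insufficient")

  pd_profiles <- rbind(healthy = c(2, 3, 4, 4, 3, 2),
                       mucositis = c(3, 4, 5, 5, 4, 3),
                       peri_implantitis = c(5, 6, 7, 7, 6, 5))
  pd <- pd_profiles[dg, , drop = FALSE]
  colnames(pd) <- pd_site_columns()
  loss <- c(healthy = 0, mucositis = 1, peri_implantitis = 3)[dg]

  dplyr::bind_cols(
    tibble(
      patient_id = sprintf("P%04d", pat_idx),
      implant_id = sprintf("IMP%04d", seq_len(n)),
      sex = sex_pat[pat_idx],
      periodontal_history = pdl >= 2L,
      compliant = pdl %in% c(0L, 2L),
      mpi = mpi, mgi = mgi,
      random_glucose_mg_dl = ifelse(diabetic, 140, 92),
      smoking_status = status,
      cigarettes_per_day = ifelse(current, 5L, NA_integer_),
      residual_cement = stats::runif(n) < fp_of("residual_cement"),
      occlusal_overload = stats::runif(n) < fp_of("occlusal_overload"),
      keratinized_width_mm = ifelse(insuff, 1, 3),
      alcohol = stats::runif(n) < fp_of("alcohol"),
      suppuration = supp
    ),
    as_tibble(pd),
    tibble(crestal_bone_loss_mm = unname(loss))
  )
}
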