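#' Measurement helpers
#'
#' `mean_probing_depth()` averages the six per-site probing depths
#' (mesiobuccal, midbuccal, distobuccal, distolingual, midlingual,
#' mesiolingual) recorded around an implant. `crestal_bone_loss()` is a
#' validated pass-through for the radiographic bone-loss measurement: the
#' vertical distance, in mm, from the line joining the cemento-enamel
#' junctions of the two adjacent teeth to the deepest point of the
#' residual ridge crest.
#'
#' @param depths_mm Either a numeric vector of exactly six site depths
#'   (one implant) or a numeric matrix/data frame with six columns (one
#'   row per implant). All values in mm, non-negative.
#' @return `mean_probing_depth()`: the arithmetic mean depth(s) in mm.
#' @examples
#' mean_probing_depth(c(2, 3, 4, 4, 3, 2))
#' crestal_bone_loss(2.5)
#' @export
mean_probing_depth <- function(depths_mm) {
  if (is.data.frame(depths_mm)) depths_mm <- as.matrix(depths_mm)
  if (is.matrix(depths_mm)) {
    if (ncol(depths_mm) != 6L) {
      abort("`depths_mm` must have exactly 6 site columns.")
    }
    check_number(c(depths_mm), "depths_mm", min = 0)
    return(rowMeans(depths_mm))
  }
  if (length(depths_mm) != 6L) {
    abort("`depths_mm` must contain exactly 6 site depths.")
  }
  check_number(depths_mm, "depths_mm", min = 0)
  mean(depths_mm)
}

#' @rdname mean_probing_depth
#' @param loss_mm Crestal bone loss in mm (non-negative).
#' @return `crestal_bone_loss()`: `loss_mm`, validated.
#' @export
crestal_bone_loss <- function(loss_mm) {
  check_number(loss_mm, "loss_mm", min = 0)
  loss_mm
}

# vectorized three-way classification from clinical findings.
#
# strict mode applies each diagnostic column as a literal conjunction of
# all five criteria and returns "indeterminate" when none holds; the
# pragmatic default treats the bone-loss threshold at 2 mm as the
# mucositis/peri-implantitis discriminator and any inflammation sign
# (MGI >= 1, suppuration, or MPI >= 2) as qualifying disease.
classify_findings <- function(mgi, mpi, suppuration, mean_pd_mm,
                              bone_loss_mm, mode = c("pragmatic", "strict")) {
  mode <- match.arg(mode)
  score_index(mgi, "gingival_status")  # range validation
  score_index(mpi, "plaque_status")
  check_flag_vec(suppuration, "suppuration")
  check_number(mean_pd_mm, "mean_pd_mm", min = 0)
  check_number(bone_loss_mm, "bone_loss_mm", min = 0)

  healthy <- mgi == 0 & mpi == 0 & !suppuration &
    mean_pd_mm <= 5 & bone_loss_mm == 0
  if (mode == "strict") {
    mucositis <- mgi >= 1 & mpi == 1 & suppuration &
      mean_pd_mm > 5 & bone_loss_mm < 2
    implantitis <- mgi >= 1 & mpi >= 2 & suppuration &
      mean_pd_mm > 5 & bone_loss_mm > 2
    lab <- ifelse(healthy, "healthy",
           ifelse(implantitis, "peri_implantitis",
           ifelse(mucositis, "mucositis", "indeterminate")))
  } else {
    inflamed <- mgi >= 1 | suppuration | mpi >= 2
    lab <- ifelse(healthy, "healthy",
           ifelse(inflamed & bone_loss_mm > 2, "peri_implantitis",
                  "mucositis"))
  }
  factor(lab, levels = c("healthy", "mucositis", "peri_implantitis",
                         "indeterminate"))
}

#' Classify implants as healthy, mucositis or peri-implantitis
#'
#' Applies the clinical/radiographic diagnostic criteria to each implant
#' record: modified gingival and plaque indices, suppuration, mean
#' probing depth over the six sites, and crestal bone loss.
#'
#' Two modes are available. `"strict"` applies each diagnostic column as
#' a literal conjunction of all five criteria and yields `indeterminate`
#' when no conjunction holds — which happens for every implant without
#' suppuration, since both disease columns require it. The default
#' `"pragmatic"` mode is the operational reading: an implant is healthy
#' only with both indices at 0, no suppuration, mean probing depth of at
#' most 5 mm and zero bone loss; it is peri-implantitis when an
#' inflammation sign (MGI >= 1, suppuration, or MPI >= 2) coincides with
#' crestal bone loss strictly above 2 mm; otherwise it is mucositis.
#' Exactly 2 mm of bone loss — the conventional remodeling allowance —
#' stays on the mucositis side.
#'
#' @param records A tibble of implant records (schema of
#'   [read_cohort_csv()]).
#' @param mode `"pragmatic"` (default) or `"strict"`.
#' @return A tibble of class `implant_diagnoses`: ids, `mean_pd_mm`,
#'   per-criterion report columns (`crit_mgi`, `crit_mpi`,
#'   `crit_suppuration`, `crit_pd_over_5mm`, `crit_bone_loss_over_2mm`)
#'   and the `diagnosis` factor.
#' @examples
#' classify_implants(study_fixture())
#' @export
classify_implants <- function(records, mode = c("pragmatic", "strict")) {
  mode <- match.arg(mode)
  validate_records(records)
  pd <- mean_probing_depth(records[pd_site_columns()])
  loss <- crestal_bone_loss(records$crestal_bone_loss_mm)
  out <- tibble(
    patient_id = records$patient_id,
    implant_id = records$implant_id,
    mean_pd_mm = pd,
    crestal_bone_loss_mm = loss,
    crit_mgi = records$mgi,
    crit_mpi = records$mpi,
    crit_suppuration = records$suppuration,
    crit_pd_over_5mm = pd > 5,
    crit_bone_loss_over_2mm = loss > 2,
    diagnosis = classify_findings(records$mgi, records$mpi,
                                  records$suppuration, pd, loss, mode),
    mode = mode
  )
  n_ind <- sum(out$diagnosis == "indeterminate")
  if (n_ind > 0) {
    warn(sprintf(
      "%d implant(s) indeterminate under strict criteria (no diagnostic conjunction holds).",
      n_ind))
  }
  structure(out, class = c("implant_diagnoses", class(out)))
}

#' @method glance implant_diagnoses
#' @export
glance.implant_diagnoses <- function(x, ...) {
  counts <- table(x$diagnosis)
  tibble(n_implants = nrow(x),
         n_healthy = counts[["healthy"]],
         n_mucositis = counts[["mucositis"]],
         n_peri_implantitis = counts[["peri_implantitis"]],
         n_indeterminate = counts[["indeterminate"]],
         mode = x$mode[[1]])
}

#' @method autoplot implant_diagnoses
#' @export
autoplot.implant_diagnoses <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$diagnosis, fill = .data$diagnosis)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "Implants") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

pd_site_columns <- function() {
  c("pd_mesiobuccal_mm", "pd_midbuccal_mm", "pd_distobuccal_mm",
    "pd_distolingual_mm", "pd_midlingual_mm", "pd_mesiolingual_mm")
}
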