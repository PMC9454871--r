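## Encoding of pathologist ROI readings and surgical variables into the
## per-patient tissue/clinical feature block used by the risk model.

SUBTYPE_LEVELS <- c("AIS", "invasive adenocarcinoma", "carcinoid",
                    "large-cell", "squamous")

#' Derive per-patient tissue features from ROI readings
#'
#' Aggregates all annotated ROIs of each patient: histologic subtype flags
#' are the union over tumor ROIs, the highest grade is the maximum numeric
#' grade over graded ROIs (GX is excluded from the maximum and recorded as a
#' separate flag; a patient whose tumor ROIs are all GX has an undetermined
#' grade), and the largest invasive dimension is the maximum over ROIs.
#' Aggregation is invariant to ROI order.
#'
#' @param roi_readings data.frame as produced by
#'   [generate_pathology_readings()] (columns `patient_id`, `region_class`,
#'   `diagnosis`, `grade`, `invasive_dimension`).
#' @return data.frame, one row per patient: five `subtype_*` flags,
#'   `highest_grade` (integer, NA when undetermined), `grade_gx` flag,
#'   `largest_invasive_dimension`, `n_rois`, `any_premalignant`.
#' @export
derive_tissue_features <- function(roi_readings) {
  need <- c("patient_id", "region_class", "diagnosis", "grade",
            "invasive_dimension")
  miss <- setdiff(need, names(roi_readings))
  if (length(miss))
    stop("schema error: roi_readings lacks column(s) ",
         paste(miss, collapse = ", "))
  ids <- unique(roi_readings$patient_id)
  rows <- lapply(ids, function(pid) {
    r <- roi_readings[roi_readings$patient_id == pid, , drop = FALSE]
    if (nrow(r) == 0L) stop("patient with zero ROIs: ", pid)
    diags <- unique(r$diagnosis[!is.na(r$diagnosis)])
    flags <- as.list(as.numeric(SUBTYPE_LEVELS %in% diags))
    names(flags) <- paste0("subtype_", c("ais", "invasive_adeno", "carcinoid",
                                         "largecell", "squamous"))
    gr <- r$grade[!is.na(r$grade)]
    numeric_gr <- suppressWarnings(as.integer(gr[gr != "GX"]))
    data.frame(patient_id = pid, flags,
               highest_grade = if (length(numeric_gr)) max(numeric_gr)
                               else NA_integer_,
               grade_gx = as.numeric(any(gr == "GX")),
               largest_invasive_dimension = max(c(r$invasive_dimension, 0),
                                                na.rm = TRUE),
               n_rois = nrow(r),
               any_premalignant = as.numeric(any(r$region_class ==
                                                   "pre-malignant")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble per-patient model inputs
#'
#' Joins the tissue feature block to demographics, surgical parameters and
#' the LDCT-to-surgery interval; one-hot encodes categorical variables and
#' standardizes continuous columns using training-fold statistics only (so
#' fold assembly can never leak test-fold information). An undetermined
#' highest grade is imputed to the training-fold median with the `grade_gx`
#' missing-grade indicator retained.
#'
#' @param tissue data.frame from [derive_tissue_features()].
#' @param patients patient table.
#' @param train_ids patient ids defining the standardization statistics
#'   (default: all patients in `patients`).
#' @param standardize standardize continuous columns and impute undetermined
#'   grade (default TRUE); `FALSE` returns the raw encoded block (grade may
#'   be NA) for callers that standardize per fold.
#' @return numeric matrix (rownames = patient ids) with a fixed, documented
#'   column order; attributes `centers`/`scales` hold the statistics used,
#'   `continuous_cols`/`tissue_cols` the column roles.
#' @export
assemble_model_inputs <- function(tissue, patients, train_ids = NULL,
                                  standardize = TRUE) {
  if (!all(patients$patient_id %in% tissue$patient_id))
    stop("missing key: some patients lack tissue features")
  tissue <- tissue[match(patients$patient_id, tissue$patient_id), ,
                   drop = FALSE]
  if (is.null(train_ids)) train_ids <- patients$patient_id
  if (!all(train_ids %in% patients$patient_id)) stop("missing key in train_ids")

  x <- data.frame(
    age_at_surgery = patients$age_at_surgery,
    sex_female = as.numeric(patients$sex == "female"),
    smoke_pack_years = patients$smoke_pack_years,
    surgery_lobectomy = as.numeric(patients$surgery_type == "lobectomy"),
    residual_r0 = as.numeric(patients$residual_disease == "R0"),
    lymphadenectomy = as.numeric(patients$lymphadenectomy),
    days_ldct_to_surgery = patients$days_ldct_to_surgery,
    stage_t1b = as.numeric(patients$pathological_stage == "T1b"),
    stage_t1c = as.numeric(patients$pathological_stage == "T1c"),
    chemotherapy = as.numeric(patients$chemotherapy),
    radiotherapy = as.numeric(patients$radiotherapy),
    subtype_ais = tissue$subtype_ais,
    subtype_invasive_adeno = tissue$subtype_invasive_adeno,
    subtype_carcinoid = tissue$subtype_carcinoid,
    subtype_largecell = tissue$subtype_largecell,
    subtype_squamous = tissue$subtype_squamous,
    highest_grade = tissue$highest_grade,
    grade_gx = tissue$grade_gx,
    largest_invasive_dimension = tissue$largest_invasive_dimension,
    n_rois = tissue$n_rois,
    any_premalignant = tissue$any_premalignant)
  rownames(x) <- patients$patient_id

  continuous <- c("age_at_surgery", "smoke_pack_years",
                  "days_ldct_to_surgery", "highest_grade",
                  "largest_invasive_dimension", "n_rois")
  tissue_cols <- c(paste0("subtype_", c("ais", "invasive_adeno", "carcinoid",
                                        "largecell", "squamous")),
                   "highest_grade", "grade_gx",
                   "largest_invasive_dimension", "n_rois",
                   "any_premalignant")
  m <- as.matrix(x)
  centers <- stats::setNames(rep(0, ncol(m)), colnames(m))
  scales <- stats::setNames(rep(1, ncol(m)), colnames(m))
  if (standardize) {
    tr <- rownames(m) %in% train_ids
    med_gr <- stats::median(m[tr, "highest_grade"], na.rm = TRUE)
    if (is.na(med_gr)) med_gr <- 0
    m[is.na(m[, "highest_grade"]), "highest_grade"] <- med_gr
    for (cc in continuous) {
      mu <- mean(m[tr, cc]); sdv <- stats::sd(m[tr, cc])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      m[, cc] <- (m[, cc] - mu) / sdv
      centers[cc] <- mu; scales[cc] <- sdv
    }
  }
  structure(m, centers = centers, scales = scales,
            continuous_cols = continuous, tissue_cols = tissue_cols)
}
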