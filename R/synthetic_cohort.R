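## Synthetic cohort generator: CT lesion phantoms, pathologist ROI reading
## tables, clinical/surgical variables and progression outcomes wired to a
## latent risk that mixes a CT-platform signal, a tissue-platform signal and
## their interaction, so cross-platform synergy is recoverable by design.

#' Specify a synthetic cohort
#'
#' Defaults emulate the study conditions of a screening-detected stage IA
#' NSCLC surgical cohort: 182 patients, roughly 30% observed progression over
#' a 12-year administrative follow-up cap, light independent censoring, and
#' 96^3 phantom volumes at 0.5 mm isotropic spacing.
#'
#' @param n_patients number of patients (>= 2).
#' @param progression_fraction target fraction of patients with an observed
#'   progression event (the Weibull baseline is calibrated to it).
#' @param effect_sizes named numeric: `ct_signal`, `tissue_signal`,
#'   `interaction_signal` — coefficients of the latent-risk linear predictor.
#' @param censoring_rate exponential censoring hazard (1/years).
#' @param followup_cap administrative censoring time (years).
#' @param voxel_spacing mm triple for phantom volumes.
#' @param volume_shape voxel counts per axis for phantom volumes.
#' @param noise_sd sd of the non-systematic component of the recorded latent
#'   risk (does not enter the hazard).
#' @param local_fraction among progression events, fraction labelled local
#'   recurrence (the rest are distant metastases).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 182,
                        progression_fraction = 54 / 182,
                        effect_sizes = c(ct_signal = 0.7, tissue_signal = 0.7,
                                         interaction_signal = 0.4),
                        censoring_rate = 0.03,
                        followup_cap = 12,
                        voxel_spacing = c(0.5, 0.5, 0.5),
                        volume_shape = c(96L, 96L, 96L),
                        noise_sd = 0.15,
                        local_fraction = 0.5,
                        seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stop("invalid spec: n_patients must be >= 2")
  if (progression_fraction < 0 || progression_fraction > 1)
    stop("invalid spec: progression_fraction must be in [0, 1]")
  need <- c("ct_signal", "tissue_signal", "interaction_signal")
  if (!all(need %in% names(effect_sizes)))
    stop("invalid spec: effect_sizes must name ", paste(need, collapse = ", "))
  if (any(voxel_spacing <= 0)) stop("invalid spec: voxel spacing must be > 0")
  if (censoring_rate < 0 || followup_cap <= 0)
    stop("invalid spec: censoring_rate >= 0 and followup_cap > 0 required")
  if (local_fraction < 0 || local_fraction > 1)
    stop("invalid spec: local_fraction must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 progression_fraction = progression_fraction,
                 effect_sizes = effect_sizes[need],
                 censoring_rate = censoring_rate,
                 followup_cap = followup_cap,
                 voxel_spacing = as.numeric(voxel_spacing),
                 volume_shape = as.integer(volume_shape),
                 noise_sd = noise_sd,
                 local_fraction = local_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

WEIBULL_SHAPE <- 1.2

# Calibrate the Weibull baseline rate so the expected observed-event fraction
# (events before both exponential censoring and the administrative cap)
# matches the target, given the realized linear predictors.
calibrate_baseline <- function(eta, target, censoring_rate, cap,
                               shape = WEIBULL_SHAPE) {
  if (target <= 0) return(0)
  tgrid <- seq(1e-4, cap, length.out = 400)
  dt <- diff(tgrid)
  e_eta <- exp(eta)
  # P(event observed | eta) = int_0^cap f_T(t | eta) * exp(-c t) dt
  p_obs <- function(log_lambda) {
    lam <- exp(log_lambda)
    haz_t <- shape * tgrid^(shape - 1)
    cum_t <- tgrid^shape
    f <- (lam * e_eta) %o% haz_t *
      exp(-(lam * e_eta) %o% cum_t) *
      rep(exp(-censoring_rate * tgrid), each = length(eta))
    mean(f[, -1] %*% dt / 2 + f[, -ncol(f)] %*% dt / 2)
  }
  root <- stats::uniroot(function(l) p_obs(l) - target, c(-14, 6),
                         tol = 1e-7)$root
  exp(root)
}

#' Generate a synthetic cohort
#'
#' Draws per-patient CT-platform and tissue-platform latent signals, builds
#' the latent risk `eta = b_ct z_ct + b_tis z_tis + b_int z_ct z_tis`, draws
#' progression times from a Weibull proportional-hazards model on `eta` with
#' independent exponential censoring and an administrative cap, and derives
#' lesion ground truth, measured CT descriptors, pathologist ROI readings and
#' clinical tables. Deterministic for a fixed spec (including seed).
#'
#' @param spec a [cohort_spec()].
#' @param render_volumes also render CT phantom volumes for every patient
#'   (slow at scale; default FALSE — use [generate_ct_volume()] on
#'   `ground_truth` rows when a volume is needed).
#' @return An object of class `idle_cohort`: list with `spec`, `patients`,
#'   `outcomes`, `ground_truth`, `roi_readings`, `ct_measurements`,
#'   `lesion_tables` and (optionally) `volumes`.
#' @export
generate_cohort <- function(spec, render_volumes = FALSE) {
  if (!inherits(spec, "cohort_spec")) stop("invalid spec")
  set.seed(spec$seed)
  n <- spec$n_patients
  id <- sprintf("P%04d", seq_len(n))
  es <- spec$effect_sizes

  z_ct <- stats::rnorm(n)
  z_tis <- stats::rnorm(n)
  eta <- es[["ct_signal"]] * z_ct + es[["tissue_signal"]] * z_tis +
    es[["interaction_signal"]] * z_ct * z_tis
  latent_risk <- eta + stats::rnorm(n, sd = spec$noise_sd)

  # lesion ground truth driven by the CT latent
  solidity <- stats::plogis(0.9 * z_ct + 0.6)
  skewness <- pmax(0, 0.7 * z_ct + 0.7)
  cluster_count <- pmin(4L, stats::rpois(n, lambda = 0.8 * exp(0.35 * z_ct)))
  diameter_mm <- pmin(20, pmax(5, exp(log(11) + 0.22 * z_ct +
                                        stats::rnorm(n, sd = 0.18))))
  lobe <- sample(LOBE_CODES, n, replace = TRUE,
                 prob = c(0.30, 0.10, 0.25, 0.20, 0.15))

  # survival outcomes: Weibull PH on eta, exponential censoring, 12-year cap
  lambda <- calibrate_baseline(eta, spec$progression_fraction,
                               spec$censoring_rate, spec$followup_cap)
  u <- stats::runif(n)
  t_event <- if (lambda > 0) (-log(u) / (lambda * exp(eta)))^(1 / WEIBULL_SHAPE)
             else rep(Inf, n)
  t_cens <- if (spec$censoring_rate > 0)
    pmin(stats::rexp(n, spec$censoring_rate), spec$followup_cap)
  else rep(spec$followup_cap, n)
  time <- pmax(pmin(t_event, t_cens), 1 / 365)
  event <- as.integer(t_event <= t_cens)
  cause <- ifelse(event == 1,
                  ifelse(stats::runif(n) < spec$local_fraction,
                         "local_recurrence", "distant_metastasis"),
                  NA_character_)
  outcomes <- data.frame(patient_id = id, time = time, event = event,
                         cause = cause, stringsAsFactors = FALSE)

  roi_readings <- generate_pathology_readings(z_tis, patient_ids = id)

  # per-patient measured CT descriptors (ground truth + measurement error)
  ct_measurements <- data.frame(
    patient_id = id,
    ct_solidity = pmin(1, pmax(0, solidity + stats::rnorm(n, sd = 0.04))),
    ct_skewness = skewness + stats::rnorm(n, sd = 0.10),
    ct_cluster_count = pmax(0, cluster_count + stats::rnorm(n, sd = 0.30)),
    ct_diameter_mm = diameter_mm * exp(stats::rnorm(n, sd = 0.04)),
    stringsAsFactors = FALSE)

  largest_inv <- vapply(id, function(p) {
    r <- roi_readings[roi_readings$patient_id == p, "invasive_dimension"]
    max(c(r, 1), na.rm = TRUE)
  }, 0)

  stage <- cut(diameter_mm, c(-Inf, 10, 20, Inf),
               labels = c("T1a", "T1b", "T1c"))
  patients <- data.frame(
    patient_id = id,
    age_at_surgery = round(pmin(82, pmax(55, stats::rnorm(n, 65.1, 4.9))), 1),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.45, 0.55)),
    smoke_pack_years = round(pmin(200, pmax(15, stats::rnorm(n, 68, 32)))),
    surgery_type = sample(c("lobectomy", "sublobar"), n, TRUE,
                          prob = c(0.84, 0.16)),
    residual_disease = sample(c("R0", "R1"), n, TRUE, prob = c(0.97, 0.03)),
    lymphadenectomy = stats::rbinom(n, 1, 0.90) == 1,
    days_ldct_to_surgery = round(stats::rgamma(n, shape = 0.9, scale = 225)),
    pathological_stage = as.character(stage),
    largest_invasive_size = pmin(45, largest_inv),
    chemotherapy = stats::rbinom(n, 1, 0.03) == 1,
    radiotherapy = stats::rbinom(n, 1, 0.02) == 1,
    stringsAsFactors = FALSE)

  ground_truth <- data.frame(
    patient_id = id, latent_risk = latent_risk, linear_predictor = eta,
    z_ct = z_ct, z_tissue = z_tis,
    solidity = solidity, skewness = skewness,
    cluster_count = cluster_count, diameter_mm = diameter_mm,
    lobe = lobe, stringsAsFactors = FALSE)

  # lung-wide lesion tables: the primary lesion plus incidental small nodules
  mean_hu <- -800 + 850 * solidity
  n_extra <- stats::rpois(n, 0.7)
  lesion_tables <- lapply(seq_len(n), function(i) {
    prim <- data.frame(patient_id = id[i], lesion_id = "L1", lobe = lobe[i],
                       mean_hu = mean_hu[i],
                       diameter_mm = diameter_mm[i],
                       volume_mm3 = pi / 6 * diameter_mm[i]^3,
                       stringsAsFactors = FALSE)
    if (n_extra[i] == 0) return(prim)
    dmm <- stats::runif(n_extra[i], 4, 8)
    extra <- data.frame(
      patient_id = id[i],
      lesion_id = paste0("L", 1 + seq_len(n_extra[i])),
      lobe = sample(LOBE_CODES, n_extra[i], TRUE),
      mean_hu = stats::runif(n_extra[i], -750, -250),
      diameter_mm = dmm, volume_mm3 = pi / 6 * dmm^3,
      stringsAsFactors = FALSE)
    rbind(prim, extra)
  })
  names(lesion_tables) <- id

  volumes <- NULL
  if (render_volumes) {
    vseed <- sample.int(.Machine$integer.max - 1L, n)
    volumes <- lapply(seq_len(n), function(i)
      generate_ct_volume(lesion_params(solidity[i], skewness[i],
                                       cluster_count[i], diameter_mm[i]),
                         spacing = spec$voxel_spacing,
                         shape = spec$volume_shape, seed = vseed[i]))
    names(volumes) <- id
  }

  structure(list(spec = spec, patients = patients, outcomes = outcomes,
                 ground_truth = ground_truth, roi_readings = roi_readings,
                 ct_measurements = ct_measurements,
                 lesion_tables = lesion_tables, volumes = volumes),
            class = "idle_cohort")
}

#' @export
print.idle_cohort <- function(x, ...) {
  cat(sprintf("<idle_cohort> %d patients, %d progression events, %d ROIs%s\n",
              nrow(x$patients), sum(x$outcomes$event),
              nrow(x$roi_readings),
              if (is.null(x$volumes)) "" else ", volumes rendered"))
  invisible(x)
}

#' Lesion parameter bundle
#'
#' @param solidity mean-contrast knob in (0, 1]: 1 gives a solid lesion.
#' @param skewness intensity-asymmetry knob (>= 0; 0 = symmetric noise).
#' @param cluster_count number of compact high-intensity blobs planted.
#' @param diameter_mm lesion diameter in mm.
#' @return list of class `lesion_params`.
#' @export
lesion_params <- function(solidity = 0.8, skewness = 0.5, cluster_count = 1L,
                          diameter_mm = 12) {
  stopifnot(solidity > 0, solidity <= 1, skewness >= 0, cluster_count >= 0,
            diameter_mm > 0)
  structure(list(solidity = solidity, skewness = skewness,
                 cluster_count = as.integer(cluster_count),
                 diameter_mm = diameter_mm), class = "lesion_params")
}

#' Render a CT phantom volume with a planted lesion
#'
#' Body-density shell with an ellipsoidal lung of low attenuation and
#' Gaussian noise; the lesion is an ellipsoid whose mean contrast tracks
#' `solidity`, whose intensity asymmetry tracks `skewness` (gamma-shaped
#' residuals), and in which `cluster_count` compact high-intensity blobs are
#' planted. The planted voxel mask is returned with the volume.
#'
#' @param params a [lesion_params()].
#' @param spacing voxel spacing (mm).
#' @param shape voxel counts per axis.
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise sd in HU.
#' @return list with `volume` ([volume3d()]), `mask` (logical array),
#'   `gross_box` (`list(lo, hi)`, the lesion bounding cube + 1 cm margin).
#' @export
generate_ct_volume <- function(params, spacing = c(0.5, 0.5, 0.5),
                               shape = c(96L, 96L, 96L), seed = 1L,
                               noise_sd = 20) {
  stopifnot(inherits(params, "lesion_params"))
  set.seed(seed)
  shape <- as.integer(shape)
  extent <- shape * spacing
  lung_semi <- 0.45 * extent
  if (params$diameter_mm / 2 + 10 > min(lung_semi))
    stop(sprintf(
      "geometry error: lesion (d = %g mm) does not fit with >= 1 cm clearance",
      params$diameter_mm))

  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 0.5) * spacing[a] -
                                   extent[a] / 2))
  # normalized squared distance fields, vectorized by recycling over the array
  x2 <- (ax[[1]] / lung_semi[1])^2
  y2 <- (ax[[2]] / lung_semi[2])^2
  z2 <- (ax[[3]] / lung_semi[3])^2
  lung <- outer(outer(x2, y2, "+"), z2, "+") < 1

  vol <- array(stats::rnorm(prod(shape), 300, noise_sd), shape)
  vol[lung] <- stats::rnorm(sum(lung), -800, noise_sd)

  semi <- params$diameter_mm / 2 * c(1, 0.92, 1.08)
  lx2 <- (ax[[1]] / semi[1])^2
  ly2 <- (ax[[2]] / semi[2])^2
  lz2 <- (ax[[3]] / semi[3])^2
  lesion <- outer(outer(lx2, ly2, "+"), lz2, "+") < 1
  nles <- sum(lesion)
  lesion_mean <- -800 + 850 * params$solidity
  if (params$skewness > 1e-8) {
    sh <- (2 / params$skewness)^2
    resid <- (stats::rgamma(nles, shape = sh, rate = 1) - sh) / sqrt(sh)
  } else {
    resid <- stats::rnorm(nles)
  }
  vol[lesion] <- lesion_mean + 60 * resid

  if (params$cluster_count > 0) {
    cl_val <- min(lesion_mean + 180, 120)
    for (ci in seq_len(params$cluster_count)) {
      off <- stats::runif(3, -0.55, 0.55) * semi
      cx2 <- ((ax[[1]] - off[1]) / 2)^2
      cy2 <- ((ax[[2]] - off[2]) / 2)^2
      cz2 <- ((ax[[3]] - off[3]) / 2)^2
      blob <- (outer(outer(cx2, cy2, "+"), cz2, "+") < 1) & lesion
      vol[blob] <- stats::rnorm(sum(blob), cl_val, noise_sd / 2)
    }
  }

  idx <- which(lesion, arr.ind = TRUE)
  marg <- ceiling(10 / spacing)
  lo <- pmax(1L, apply(idx, 2, min) - marg)
  hi <- pmin(shape, apply(idx, 2, max) + marg)
  list(volume = volume3d(vol, spacing = spacing), mask = lesion,
       gross_box = list(lo = as.integer(lo), hi = as.integer(hi)))
}

#' Generate pathologist ROI reading tables
#'
#' Per patient, 2-3 slides and 1-10 ROIs drawn from invasive-tumor,
#' pre-malignant and nontumor regions; tumor grade and invasive dimension
#' shift monotonically with the tissue latent signal. Mixed-histology
#' patients (a second subtype, usually AIS) occur at a realistic rate.
#'
#' @param tissue_signal numeric vector of per-patient tissue latents.
#' @param patient_ids optional character ids (default `P0001`, ...).
#' @return data.frame with one row per ROI: `patient_id`, `slide_id`,
#'   `roi_id`, `region_class`, `diagnosis`, `grade`, `invasive_dimension`.
#' @export
generate_pathology_readings <- function(tissue_signal, patient_ids = NULL) {
  n <- length(tissue_signal)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  subtypes <- c("invasive adenocarcinoma", "squamous", "large-cell", "AIS",
                "carcinoid")
  primary <- sample(subtypes, n, TRUE, prob = c(0.45, 0.12, 0.28, 0.10, 0.05))
  mixed <- stats::runif(n) < 0.30 & primary != "AIS"
  out <- vector("list", n)
  for (i in seq_len(n)) {
    n_slides <- sample(2:3, 1)
    n_rois <- 1L + stats::rbinom(1, 9, 0.545)
    region <- c("invasive tumor",
                sample(c("invasive tumor", "pre-malignant", "nontumor"),
                       n_rois - 1, TRUE, prob = c(0.70, 0.15, 0.15)))
    is_tumor <- region == "invasive tumor"
    diag <- rep(NA_character_, n_rois)
    second <- if (mixed[i]) "AIS" else primary[i]
    diag[is_tumor] <- ifelse(stats::runif(sum(is_tumor)) < 0.75, primary[i],
                             second)
    # ordinal grade from the tissue latent (cumulative-logit thresholds)
    s <- 1.2 * tissue_signal[i] + stats::rlogis(n_rois)
    gr <- as.character(cut(s, c(-Inf, -1.4, 0.8, 2.9, Inf),
                           labels = c("1", "2", "3", "4")))
    gr[diag == "AIS"] <- "1"        # in situ disease is well differentiated
    gr[stats::runif(n_rois) < 0.02] <- "GX"
    gr[!is_tumor] <- NA_character_
    dim_mm <- ifelse(is_tumor & diag != "AIS",
                     pmin(45, exp(log(9) + 0.30 * tissue_signal[i] +
                                    stats::rnorm(n_rois, sd = 0.35))),
                     0)
    out[[i]] <- data.frame(
      patient_id = patient_ids[i],
      slide_id = paste0(patient_ids[i], "_S",
                        sample(seq_len(n_slides), n_rois, TRUE)),
      roi_id = paste0(patient_ids[i], "_R", seq_len(n_rois)),
      region_class = region, diagnosis = diag, grade = gr,
      invasive_dimension = dim_mm, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Apply the study eligibility filters
#'
#' Sequentially filters patients on: (1) primary tumor surgery received,
#' (2) pathologist readings present, (3) pathological stage IA, (4) largest
#' invasive tumor size no greater than 30 mm, and (5) surgery within 2 years
#' of the last LDCT screening; and reports CONSORT-style per-filter
#' exclusion counts.
#'
#' @param patients patient table (see [generate_cohort()]).
#' @param roi_readings ROI reading table.
#' @return list with `eligible` (patient table subset), `exclusions`
#'   (data.frame `criterion`, `n_excluded`), `n_input`, `n_eligible`.
#' @export
apply_selection_criteria <- function(patients, roi_readings) {
  need <- c("patient_id", "surgery_type", "pathological_stage",
            "largest_invasive_size", "days_ldct_to_surgery")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    stop("schema error: patients table lacks column(s) ",
         paste(miss, collapse = ", "))
  if (!"patient_id" %in% names(roi_readings))
    stop("schema error: roi_readings lacks patient_id")
  filters <- list(
    surgery_received = function(d) !is.na(d$surgery_type) &
      d$surgery_type %in% c("sublobar", "lobectomy"),
    readings_present = function(d) d$patient_id %in% roi_readings$patient_id,
    stage_ia = function(d) d$pathological_stage %in% c("T1a", "T1b", "T1c"),
    invasive_size_le_30mm = function(d) d$largest_invasive_size <= 30,
    surgery_within_2y_of_ldct = function(d) d$days_ldct_to_surgery <= 730)
  cur <- patients
  excl <- data.frame(criterion = names(filters),
                     n_excluded = 0L, stringsAsFactors = FALSE)
  for (fi in seq_along(filters)) {
    keep <- filters[[fi]](cur)
    excl$n_excluded[fi] <- sum(!keep)
    cur <- cur[keep, , drop = FALSE]
  }
  rownames(cur) <- NULL
  list(eligible = cur, exclusions = excl,
       n_input = nrow(patients), n_eligible = nrow(cur))
}

#' Export a cohort to plain-text tables (and optional NIfTI volumes)
#'
#' Writes `patients.csv`, `outcomes.csv`, `roi_readings.csv`,
#' `ground_truth.csv`, `ct_measurements.csv` and, when volumes were rendered,
#' one `<patient_id>.nii.gz` plus `<patient_id>_mask.nii.gz` per patient.
#'
#' @param cohort an `idle_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "idle_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$roi_readings, file.path(dir, "roi_readings.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ct_measurements,
                   file.path(dir, "ct_measurements.csv"), row.names = FALSE)
  if (!is.null(cohort$volumes)) {
    for (pid in names(cohort$volumes)) {
      v <- cohort$volumes[[pid]]
      write_volume(v$volume, file.path(dir, paste0(pid, ".nii.gz")))
      write_volume(volume3d(array(as.numeric(v$mask), dim(v$mask)),
                            v$volume$spacing),
                   file.path(dir, paste0(pid, "_mask.nii.gz")))
    }
  }
  invisible(dir)
}
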