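## CT feature extraction: nested intensity-weighted dispersion, first-order,
## GLCM and GLRLM texture families over the tumor / peritumor / extra-tumor
## VOIs, tumor-vs-peritumor intensity ratios, and lung-level lesion features.
## Together the registry holds exactly 173 named features per image.

FIRST_ORDER_NAMES <- c("mean", "median", "sd", "skewness", "kurtosis",
                       "min", "max", "q10", "q25", "q75", "q90",
                       "energy", "rms", "entropy", "uniformity")

GLCM_NAMES <- c("autocorrelation", "cluster_prominence", "cluster_shade",
                "cluster_tendency", "contrast", "correlation",
                "difference_entropy", "dissimilarity", "energy", "entropy",
                "homogeneity1", "homogeneity2", "imc1", "imc2", "idmn",
                "idn", "inverse_variance", "max_probability", "sum_average",
                "sum_entropy", "sum_variance", "variance")

GLRLM_NAMES <- c("sre", "lre", "gln", "rln", "rp",
                 "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle")

SPATIAL_NAMES <- c("volume_mm3", "locsd100", "locsd50", "locsd20",
                   "locsd100v", "locsd50v", "locsd20v", "d50", "d20")

RATIO_NAMES <- c("mean_intensity_ratio", "r50", "r90")

LOBE_CODES <- c("rul", "rml", "rll", "lul", "lll")

#' The 13 texture direction vectors
#'
#' In-plane angles of 0/45/90/135 degrees taken in the sagittal, transverse
#' and coronal planes reduce, after removing sign-duplicates, to 13 unique 3D
#' displacement vectors used by both the GLCM and GLRLM stages.
#'
#' @return A 13 x 3 integer matrix, one direction per row.
#' @export
texture_directions <- function() {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0),
             c(1, 0, 1), c(1, 1, 1), c(1, -1, 1), c(0, 0, 1),
             c(0, 1, 1), c(0, -1, 1), c(-1, 0, 1), c(-1, 1, 1),
             c(-1, -1, 1))
  storage.mode(m) <- "integer"
  m
}

# Fixed-bin-size quantization anchored at 0; intended for post-normalization
# (non-negative) intensities. Values below 0 fall in level 1.
quantize_levels <- function(values, bin_size = 100) {
  pmax(1L, as.integer(floor(values / bin_size)) + 1L)
}

#' Intensity-weighted center of the top-p% voxels
#'
#' The weighted center uses voxel intensities as linear weights over the
#' selected voxels; for p < 100 the selection keeps the p% of mask voxels with
#' the highest intensities.
#'
#' @param vol a [volume3d()] with non-negative (normalized) intensities.
#' @param mask logical array selecting the lesion voxels.
#' @param p percentage of highest-intensity voxels to use (100, 50 or 20).
#' @return Named numeric length-3 (`cx`, `cy`, `cz`) in mm.
#' @export
weighted_center <- function(vol, mask, p = 100) {
  sel <- top_fraction_idx(vol, mask, p)
  w <- vol$data[sel$idx]
  if (sum(w) <= 0) stop("all-zero weights: weighted center undefined")
  ctr <- colSums(sel$coords * w) / sum(w)
  names(ctr) <- c("cx", "cy", "cz")
  ctr
}

top_fraction_idx <- function(vol, mask, p) {
  stopifnot(is_volume3d(vol), any(mask), p > 0, p <= 100)
  idx <- which(mask, arr.ind = TRUE)
  vals <- vol$data[idx]
  n_keep <- max(1L, ceiling(length(vals) * p / 100))
  # intensity ties at the cut are all retained, so a homogeneous lesion
  # yields identical selections (and coincident centers) at every p
  thr <- sort(vals, decreasing = TRUE)[n_keep]
  keep <- which(vals >= thr)
  list(idx = idx[keep, , drop = FALSE],
       coords = voxel_coords(vol, idx[keep, , drop = FALSE]))
}

#' Spatial dispersion of the top-p% voxels about a center
#'
#' Square-root of the squared-intensity-weighted mean squared distance from
#' `center`; note the weights here are the squared intensities while the
#' center itself uses linear weights — the two stages deliberately use
#' different weightings.
#'
#' @inheritParams weighted_center
#' @param center mm coordinates (typically from [weighted_center()] at the
#'   same `p`).
#' @return Dispersion in mm (0 for a single voxel).
#' @export
loc_sd <- function(vol, mask, center, p = 100) {
  sel <- top_fraction_idx(vol, mask, p)
  w <- vol$data[sel$idx]^2
  if (sum(w) <= 0) stop("all-zero weights: dispersion undefined")
  d2 <- rowSums(sweep(sel$coords, 2, center)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Euclidean shifts between nested centers
#'
#' @param c100,c50,c20 centers in mm from [weighted_center()].
#' @return Named numeric: `d50 = ||C50 - C100||`, `d20 = ||C20 - C100||` (mm).
#' @export
center_shifts <- function(c100, c50, c20) {
  c(d50 = sqrt(sum((c50 - c100)^2)), d20 = sqrt(sum((c20 - c100)^2)))
}

#' Nested-dispersion feature block (9 features)
#'
#' Tumor volume, the three nested dispersions, their volume-normalized forms
#' (`locsd*v = locsd* / V`) and the two center shifts.
#'
#' @inheritParams weighted_center
#' @return Named numeric length 9.
#' @export
nested_dispersion_features <- function(vol, mask) {
  v_mm3 <- sum(mask) * prod(vol$spacing)
  cs <- lapply(c(100, 50, 20), function(p) weighted_center(vol, mask, p))
  ls <- mapply(function(ctr, p) loc_sd(vol, mask, ctr, p),
               cs, c(100, 50, 20))
  sh <- center_shifts(cs[[1]], cs[[2]], cs[[3]])
  out <- c(v_mm3, ls, ls / v_mm3, sh)
  names(out) <- SPATIAL_NAMES
  out
}

#' First-order intensity features (15 features)
#'
#' Moments and quantiles on the raw values; energy, RMS, and histogram
#' entropy/uniformity on a fixed-bin-size histogram (default 100 HU bins).
#' Quantiles use the type-7 (midpoint-interpolating) convention. Skewness and
#' kurtosis are population moments (kurtosis not excess-corrected); both are
#' defined as 0 for constant input.
#'
#' @param values numeric vector of VOI voxel intensities.
#' @param bin_size histogram bin width in HU.
#' @return Named numeric length 15.
#' @export
first_order_features <- function(values, bin_size = 100) {
  if (length(values) < 1L) stop("empty voxel set")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - m)^4) / m2^2 else 0
  q <- stats::quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE,
                       type = 7)
  lev <- quantize_levels(values, bin_size)
  pb <- tabulate(lev) / length(lev)
  pb <- pb[pb > 0]
  out <- c(m, stats::median(values), stats::sd(values), skew, kurt,
           min(values), max(values), q[1], q[2], q[3], q[4],
           sum(values^2), sqrt(mean(values^2)),
           -sum(pb * log2(pb)), sum(pb^2))
  if (length(values) == 1L) out[3] <- 0  # sd() is NA for n = 1
  names(out) <- FIRST_ORDER_NAMES
  out
}

# 22 Haralick-family statistics of one normalized symmetric GLCM.
glcm_stats <- function(P, n_levels) {
  ng <- n_levels
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sdx <- sqrt(sum((i - mux)^2 * P)); sdy <- sqrt(sum((j - muy)^2 * P))
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), 0)
  k_diff <- 0:(ng - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  pxpy <- outer(px, py)
  hxy1 <- -sum(P[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- ent(pxpy)
  hx <- ent(px); hy <- ent(py)
  sa <- sum(k_sum * pxy_sum)
  corr <- if (sdx > 0 && sdy > 0) (sum(i * j * P) - mux * muy) / (sdx * sdy)
          else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  off <- i != j
  c(autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_entropy = ent(pxy_diff),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = hxy,
    homogeneity1 = sum(P / (1 + abs(i - j))),
    homogeneity2 = sum(P / (1 + (i - j)^2)),
    imc1 = imc1,
    imc2 = imc2,
    idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    idn = sum(P / (1 + abs(i - j) / ng)),
    inverse_variance = sum(P[off] / (i[off] - j[off])^2),
    max_probability = max(P),
    sum_average = sa,
    sum_entropy = ent(pxy_sum),
    sum_variance = sum((k_sum - sa)^2 * pxy_sum),
    variance = sum((i - mux)^2 * P))
}

# Co-occurrence pairs of quantized levels along one direction; symmetric
# accumulation (each ordered pair counted both ways).
glcm_matrix <- function(levels_arr, mask, dir, n_levels) {
  d <- dim(mask)
  src <- vector("list", 3); dst <- vector("list", 3)
  for (a in 1:3) {
    v <- dir[a]
    if (abs(v) >= d[a]) return(NULL)
    if (v >= 0) { src[[a]] <- 1:(d[a] - v); dst[[a]] <- (1 + v):d[a] }
    else { src[[a]] <- (1 - v):d[a]; dst[[a]] <- 1:(d[a] + v) }
  }
  m1 <- mask[src[[1]], src[[2]], src[[3]], drop = FALSE]
  m2 <- mask[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  both <- m1 & m2
  if (!any(both)) return(NULL)
  g1 <- levels_arr[src[[1]], src[[2]], src[[3]], drop = FALSE][both]
  g2 <- levels_arr[dst[[1]], dst[[2]], dst[[3]], drop = FALSE][both]
  counts <- tabulate((g1 - 1L) * n_levels + g2, n_levels * n_levels) +
            tabulate((g2 - 1L) * n_levels + g1, n_levels * n_levels)
  P <- matrix(counts, n_levels, n_levels)
  P / sum(P)
}

#' GLCM texture features (22 features)
#'
#' Builds one symmetric, normalized gray-level co-occurrence matrix per
#' direction (displacement of one step along each of the 13 direction
#' vectors), computes 22 Haralick-family statistics per matrix, and reports
#' their mean over directions.
#'
#' @param vol a [volume3d()] with normalized intensities.
#' @param mask logical VOI mask.
#' @param bin_size quantization bin width in HU (default 100).
#' @return Named numeric length 22, with attribute `n_directions`.
#' @export
glcm_features <- function(vol, mask, bin_size = 100) {
  stopifnot(is_volume3d(vol))
  if (!any(mask)) stop("empty VOI mask")
  lev <- array(quantize_levels(vol$data, bin_size), dim(vol$data))
  lev[!mask] <- NA_integer_
  ng <- max(lev, na.rm = TRUE)
  dirs <- texture_directions()
  acc <- NULL; used <- 0L
  for (r in seq_len(nrow(dirs))) {
    P <- glcm_matrix(lev, mask, dirs[r, ], ng)
    if (is.null(P)) next
    s <- glcm_stats(P, ng)
    acc <- if (is.null(acc)) s else acc + s
    used <- used + 1L
  }
  if (used == 0L) stop("no valid voxel pairs for any GLCM direction")
  out <- acc / used
  names(out) <- GLCM_NAMES
  structure(out, n_directions = used)
}

# Decompose mask voxels into strided chains along `dir` with stride
# `dist * dir` and run-length encode the quantized levels.
glrlm_matrix <- function(levels_arr, mask, dir, dist, n_levels) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  step <- dir * dist
  # backwards steps possible before leaving the grid, per nonzero axis
  b <- rep(.Machine$integer.max, nrow(idx))
  for (a in 1:3) {
    if (dir[a] > 0) b <- pmin(b, (idx[, a] - 1L) %/% dist)
    else if (dir[a] < 0) b <- pmin(b, (d[a] - idx[, a]) %/% dist)
  }
  anchor <- idx - b %o% step
  key <- (anchor[, 3] - 1L) * d[1] * d[2] + (anchor[, 2] - 1L) * d[1] +
         anchor[, 1]
  g <- levels_arr[idx]
  ord <- order(key, b)
  key <- key[ord]; t <- b[ord]; g <- g[ord]
  # a new run starts at a chain break, a stride gap, or a gray change
  brk <- c(TRUE, key[-1] != key[-length(key)] |
                 t[-1] != t[-length(t)] + 1L |
                 g[-1] != g[-length(g)])
  run_id <- cumsum(brk)
  run_len <- tabulate(run_id)
  run_gray <- g[brk]
  max_len <- max(run_len)
  counts <- tabulate((run_gray - 1L) * max_len + run_len,
                     n_levels * max_len)
  matrix(counts, nrow = max_len, ncol = n_levels)  # rows = length, cols = gray
}

glrlm_stats <- function(Rm, n_voxels) {
  l <- row(Rm); i <- col(Rm)
  nr <- sum(Rm)
  pg <- colSums(Rm); pl <- rowSums(Rm)
  c(sre = sum(Rm / l^2) / nr,
    lre = sum(Rm * l^2) / nr,
    gln = sum(pg^2) / nr,
    rln = sum(pl^2) / nr,
    rp = nr / n_voxels,
    lglre = sum(Rm / i^2) / nr,
    hglre = sum(Rm * i^2) / nr,
    srlgle = sum(Rm / (i^2 * l^2)) / nr,
    srhgle = sum(Rm * i^2 / l^2) / nr,
    lrlgle = sum(Rm * l^2 / i^2) / nr,
    lrhgle = sum(Rm * i^2 * l^2) / nr)
}

#' GLRLM texture features (11 features)
#'
#' Runs are maximal sequences of collinear voxels visited at a stride of
#' `distance` voxels along a direction vector that share a quantized gray
#' level (the strided-run reading of the distance parameter). One run-length
#' matrix is built per direction-by-distance combination (13 x 4 = 52 by
#' default) and the 11 run statistics are averaged over all combinations.
#'
#' @inheritParams glcm_features
#' @param distances integer stride distances (default 2:5).
#' @return Named numeric length 11, with attribute `n_matrices`.
#' @export
glrlm_features <- function(vol, mask, distances = 2:5, bin_size = 100) {
  stopifnot(is_volume3d(vol))
  if (!any(mask)) stop("empty VOI mask: no runs")
  lev <- array(quantize_levels(vol$data, bin_size), dim(vol$data))
  ng <- max(lev[mask])
  nv <- sum(mask)
  dirs <- texture_directions()
  acc <- NULL; used <- 0L
  for (dist in distances) {
    for (r in seq_len(nrow(dirs))) {
      Rm <- glrlm_matrix(lev, mask, dirs[r, ], as.integer(dist), ng)
      s <- glrlm_stats(Rm, nv)
      acc <- if (is.null(acc)) s else acc + s
      used <- used + 1L
    }
  }
  out <- acc / used
  names(out) <- GLRLM_NAMES
  structure(out, n_matrices = used)
}

#' Tumor-vs-peritumor intensity ratios (3 features)
#'
#' Ratio of mean intensities and of the 50th and 90th percentiles (type-7
#' quantiles) between tumor and peritumoral voxels. Requires normalized,
#' non-negative intensities; a zero denominator is surfaced as an error.
#'
#' @param tumor_values,peritumor_values numeric voxel intensity vectors.
#' @return Named numeric length 3.
#' @export
intensity_ratios <- function(tumor_values, peritumor_values) {
  if (length(tumor_values) < 1L || length(peritumor_values) < 1L)
    stop("both voxel sets must be nonempty")
  qs_t <- stats::quantile(tumor_values, c(0.5, 0.9), names = FALSE, type = 7)
  qs_p <- stats::quantile(peritumor_values, c(0.5, 0.9), names = FALSE,
                          type = 7)
  den <- c(mean(peritumor_values), qs_p)
  if (any(den == 0)) stop("zero denominator in intensity ratio")
  out <- c(mean(tumor_values), qs_t) / den
  names(out) <- RATIO_NAMES
  out
}

#' Lung-level lesion features (17 features)
#'
#' Per-lobe lesion count and solid / part-solid flags for the five lobes,
#' plus the total lesion count and total lesion volume, computed from a
#' lung-wide lesion table. Lesions with mean intensity above `solid_hu`
#' count as solid; those between `part_solid_hu` and `solid_hu` as
#' part-solid.
#'
#' @param lesion_table data.frame with columns `lobe` (one of
#'   `"rul","rml","rll","lul","lll"`), `mean_hu`, `volume_mm3`.
#' @param solid_hu,part_solid_hu attenuation thresholds (default -300, -600).
#' @return Named numeric length 17.
#' @export
lung_level_features <- function(lesion_table, solid_hu = -300,
                                part_solid_hu = -600) {
  req <- c("lobe", "mean_hu", "volume_mm3")
  if (!all(req %in% names(lesion_table)))
    stop("lesion_table must have columns lobe, mean_hu, volume_mm3")
  out <- numeric(0)
  for (lb in LOBE_CODES) {
    rows <- lesion_table[lesion_table$lobe == lb, , drop = FALSE]
    solid <- rows$mean_hu > solid_hu
    part <- rows$mean_hu > part_solid_hu & !solid
    v <- c(nrow(rows), as.numeric(any(solid)), as.numeric(any(part)))
    names(v) <- paste0("lobe_", lb, c("_lesion_count", "_any_solid",
                                      "_any_part_solid"))
    out <- c(out, v)
  }
  c(out, total_lesion_count = nrow(lesion_table),
    total_lesion_volume_mm3 = sum(lesion_table$volume_mm3))
}

#' The CT feature registry
#'
#' Fixed, ordered catalog of the 173 per-image CT features: 15 first-order +
#' 22 GLCM + 11 GLRLM per VOI over three VOIs (144), 9 nested-dispersion, 3
#' intensity-ratio and 17 lung-level features.
#'
#' @return data.frame with columns `name`, `family`, `voi` (173 rows).
#' @export
feature_registry <- function() {
  rows <- list()
  for (voi in c("tumor", "peritumor", "extratumor")) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = paste0(voi, "_fo_", FIRST_ORDER_NAMES),
                 family = "first_order", voi = voi)
    rows[[length(rows) + 1L]] <-
      data.frame(name = paste0(voi, "_glcm_", GLCM_NAMES),
                 family = "glcm", voi = voi)
    rows[[length(rows) + 1L]] <-
      data.frame(name = paste0(voi, "_glrlm_", GLRLM_NAMES),
                 family = "glrlm", voi = voi)
  }
  rows[[length(rows) + 1L]] <-
    data.frame(name = paste0("tumor_", SPATIAL_NAMES),
               family = "nested_spatial", voi = "tumor")
  rows[[length(rows) + 1L]] <-
    data.frame(name = RATIO_NAMES, family = "intensity_ratio",
               voi = "tumor_vs_peritumor")
  lung_names <- c(as.vector(t(outer(paste0("lobe_", LOBE_CODES),
                                    c("_lesion_count", "_any_solid",
                                      "_any_part_solid"), paste0))),
                  "total_lesion_count", "total_lesion_volume_mm3")
  rows[[length(rows) + 1L]] <-
    data.frame(name = lung_names, family = "lung_level", voi = "lung")
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  stopifnot(nrow(reg) == 173L, !anyDuplicated(reg$name))
  reg
}

# Lesion eligibility: noncalcified and equivalent diameter >= 4 mm.
check_lesion_eligibility <- function(raw_vol, tumor_mask, min_diameter_mm = 4,
                                     calcified_hu = 130,
                                     calcified_fraction = 0.10) {
  v_mm3 <- sum(tumor_mask) * prod(raw_vol$spacing)
  eq_diam <- (6 * v_mm3 / pi)^(1 / 3)
  if (eq_diam < min_diameter_mm)
    stop(sprintf("ineligible lesion: equivalent diameter %.2f mm < %g mm",
                 eq_diam, min_diameter_mm))
  frac_cal <- mean(raw_vol$data[tumor_mask] > calcified_hu)
  if (frac_cal > calcified_fraction)
    stop(sprintf("ineligible lesion: calcified (%.0f%% of voxels > %g HU)",
                 100 * frac_cal, calcified_hu))
  invisible(TRUE)
}

#' Extract the full 173-feature CT vector
#'
#' End-to-end per-image extraction: checks lesion eligibility (noncalcified,
#' equivalent diameter at least 4 mm) on the raw intensities, normalizes
#' against adjacent normal lung, then computes every registry family. Any
#' failing family raises an error naming it.
#'
#' @param vol a [volume3d()] with raw (HU-calibrated) intensities on the
#'   0.5 mm isotropic grid.
#' @param vois a [voi_set()].
#' @param lesion_table lung-wide lesion table for [lung_level_features()].
#' @param bin_size texture quantization bin width (default 100 HU).
#' @param check_eligibility apply the lesion eligibility rules (default TRUE).
#' @return Named numeric vector of length 173 in registry order, with
#'   attribute `registry`.
#' @export
extract_all <- function(vol, vois, lesion_table, bin_size = 100,
                        check_eligibility = TRUE) {
  stopifnot(is_volume3d(vol), inherits(vois, "voi_set"))
  if (check_eligibility) check_lesion_eligibility(vol, vois$tumor)
  nv <- normalize_intensities(vol, vois)
  fam <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("ct feature family '%s' failed: %s", label,
                   conditionMessage(e)), call. = FALSE))
  }
  out <- numeric(0)
  for (voi in c("tumor", "peritumor", "extratumor")) {
    m <- vois[[if (voi == "extratumor") "extratumor" else voi]]
    vals <- nv$data[m]
    fo <- fam(paste0(voi, "/first_order"),
              first_order_features(vals, bin_size))
    gl <- fam(paste0(voi, "/glcm"), glcm_features(nv, m, bin_size))
    rl <- fam(paste0(voi, "/glrlm"), glrlm_features(nv, m,
                                                    bin_size = bin_size))
    names(fo) <- paste0(voi, "_fo_", FIRST_ORDER_NAMES)
    names(gl) <- paste0(voi, "_glcm_", GLCM_NAMES)
    names(rl) <- paste0(voi, "_glrlm_", GLRLM_NAMES)
    out <- c(out, fo, gl, rl)
  }
  sp <- fam("nested_spatial", nested_dispersion_features(nv, vois$tumor))
  names(sp) <- paste0("tumor_", SPATIAL_NAMES)
  ir <- fam("intensity_ratio",
            intensity_ratios(nv$data[vois$tumor], nv$data[vois$peritumor]))
  lu <- fam("lung_level", lung_level_features(lesion_table))
  out <- c(out, sp, ir, lu)
  reg <- feature_registry()
  stopifnot(identical(names(out), reg$name))
  structure(out, registry = reg)
}
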