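## Segmentation of lung and lesion, VOI shell construction, and the
## adjacent-normal intensity normalization applied before feature extraction.

dilate_mask <- function(mask, spacing, radius_mm) {
  if (radius_mm <= 0 || !any(mask)) return(mask)
  distance_transform(mask, spacing) <= radius_mm
}

erode_mask <- function(mask, spacing, radius_mm) {
  if (radius_mm <= 0 || !any(mask)) return(mask)
  if (all(mask)) return(mask)
  distance_transform(!mask, spacing) > radius_mm
}

close_mask <- function(mask, spacing, radius_mm)
  erode_mask(dilate_mask(mask, spacing, radius_mm), spacing, radius_mm)

open_mask <- function(mask, spacing, radius_mm)
  dilate_mask(erode_mask(mask, spacing, radius_mm), spacing, radius_mm)

largest_component <- function(mask) {
  lab <- array(.label_components3d(as.vector(mask), dim(mask)), dim(mask))
  if (max(lab) == 0L) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

#' Segment the whole lung
#'
#' Thresholds air-like voxels, keeps the largest connected component, and
#' applies a morphological closing whose radius is chosen to swallow
#' lesion-sized holes in the parenchyma, removing chest wall and bone
#' (anything at or above `bone_hu`). Intended for HU-calibrated volumes where
#' lung parenchyma sits far below soft tissue.
#'
#' @param vol a [volume3d()] with HU-like intensities.
#' @param air_hu upper intensity bound for lung parenchyma (default -300 HU).
#' @param bone_hu intensities at or above this are never part of the mask
#'   (default 130 HU).
#' @param closing_mm radius of the final morphological closing (default
#'   12 mm, enough to close holes left by lesions up to ~24 mm).
#' @return logical 3D array, the lung mask.
#' @export
segment_lung <- function(vol, air_hu = -300, bone_hu = 130, closing_mm = 12) {
  stopifnot(is_volume3d(vol))
  m <- vol$data < air_hu
  if (!any(m)) stop("empty lung mask: no voxels below the air threshold")
  m <- largest_component(m)
  m <- close_mask(m, vol$spacing, closing_mm)
  m & (vol$data < bone_hu)
}

#' Segment a lesion inside its gross bounding box
#'
#' The gross volume is a 3D cube covering the entire lesion with at least 1 cm
#' margin. Inside it the volume is median-filtered (3x3x3) to suppress noise,
#' Otsu-thresholded, cleaned by morphological opening and closing, and the
#' largest connected component is retained as the tumor mask.
#'
#' @param vol a [volume3d()].
#' @param gross_box list with integer vectors `lo` and `hi` (1-based voxel
#'   index bounds per axis) delimiting the cube.
#' @param lung_mask optional lung mask; when given, thresholding is
#'   restricted to lung voxels so chest wall entering the cube's corners
#'   cannot masquerade as lesion.
#' @param morph_mm radius (mm) of the opening/closing (default one voxel).
#' @return logical 3D array on the full volume grid (TRUE = tumor).
#' @export
segment_lesion <- function(vol, gross_box, lung_mask = NULL, morph_mm = NULL) {
  stopifnot(is_volume3d(vol))
  d <- dim(vol$data)
  lo <- as.integer(gross_box$lo); hi <- as.integer(gross_box$hi)
  if (any(lo < 1L) || any(hi > d) || any(lo >= hi))
    stop("gross box outside the volume grid")
  if (is.null(morph_mm)) morph_mm <- max(vol$spacing)
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub <- array(.median_filter3d(as.vector(sub), dim(sub)), dim(sub))
  dom <- if (is.null(lung_mask)) array(TRUE, dim(sub))
         else lung_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (!any(dom)) stop("empty lesion: gross box contains no lung")
  vals <- sub[dom]
  thr <- otsu_threshold(vals)
  m <- sub > thr & dom
  # Otsu always splits; require real contrast over the filtered background
  bg <- dom & !m
  if (!any(m) || !any(bg) || (stats::sd(vals) < 1e-8) ||
      (mean(sub[m]) - mean(sub[bg])) < 4 * stats::sd(sub[bg]))
    stop("empty lesion: no component found inside the gross box")
  m <- open_mask(m, vol$spacing, morph_mm)
  if (!any(m)) stop("empty lesion: no component found inside the gross box")
  m <- close_mask(m, vol$spacing, morph_mm)
  m <- largest_component(m)
  full <- array(FALSE, d)
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- m
  full
}

# Otsu's threshold on a 256-bin histogram.
otsu_threshold <- function(x) {
  x <- as.vector(x)
  r <- range(x)
  if (diff(r) < 1e-12) return(r[1])
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((x - r[1]) / diff(r) * nb)), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nb) - 0.5) * diff(r) / nb
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

#' Construct the VOI set around a segmented tumor
#'
#' Builds the peritumoral shell, the adjacent-normal reference shell and the
#' extra-tumor region from the tumor and lung masks using exact Euclidean
#' distances from the tumor surface. Shell widths are design parameters: the
#' peritumoral region is the 0-5 mm dilation shell clipped to lung, the
#' adjacent-normal region the 10-15 mm shell, and the extra-tumor VOI is lung
#' minus tumor and peritumor, restricted to the gross cube when one is given.
#'
#' @param vol a [volume3d()].
#' @param tumor_mask logical array, the segmented tumor.
#' @param lung_mask logical array, the segmented lung.
#' @param gross_box optional gross cube (`list(lo, hi)`) restricting the
#'   extra-tumor VOI.
#' @param peri_mm peritumoral shell outer radius (mm).
#' @param adjacent_mm length-2, inner/outer radii of the adjacent-normal shell.
#' @return An object of class `voi_set`: list of logical arrays
#'   `tumor`, `peritumor`, `extratumor`, `adjacent_normal`.
#' @export
build_voi_set <- function(vol, tumor_mask, lung_mask, gross_box = NULL,
                          peri_mm = 5, adjacent_mm = c(10, 15)) {
  stopifnot(is_volume3d(vol), any(tumor_mask))
  dist <- distance_transform(tumor_mask, vol$spacing)
  peri <- dist > 0 & dist <= peri_mm & lung_mask
  adj <- dist > adjacent_mm[1] & dist <= adjacent_mm[2] & lung_mask
  extra <- lung_mask & !tumor_mask & !peri
  if (!is.null(gross_box)) {
    keep <- array(FALSE, dim(vol$data))
    keep[gross_box$lo[1]:gross_box$hi[1],
         gross_box$lo[2]:gross_box$hi[2],
         gross_box$lo[3]:gross_box$hi[3]] <- TRUE
    extra <- extra & keep
  }
  voi_set(tumor_mask, peri, extra, adj)
}

#' @rdname build_voi_set
#' @param tumor,peritumor,extratumor,adjacent_normal logical arrays on one grid.
#' @export
voi_set <- function(tumor, peritumor, extratumor, adjacent_normal) {
  dims <- list(dim(tumor), dim(peritumor), dim(extratumor),
               dim(adjacent_normal))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all VOI masks must share one grid")
  if (!any(tumor)) stop("tumor mask is empty")
  if (any(tumor & peritumor)) stop("tumor and peritumor masks overlap")
  structure(list(tumor = tumor, peritumor = peritumor,
                 extratumor = extratumor, adjacent_normal = adjacent_normal),
            class = "voi_set")
}

#' Normalize intensities against adjacent normal lung
#'
#' Subtracts the median voxel intensity of the adjacent normal lung tissue
#' from the volume and adds 300, making tumor/peritumor intensities
#' non-negative so that energy-type features quantify the lesion intensity
#' distribution effectively. The shift is applied to the whole volume, which
#' leaves every downstream feature invariant to constant offsets in the raw
#' scan.
#'
#' @param vol a [volume3d()].
#' @param vois a [voi_set()]; `adjacent_normal` must be nonempty.
#' @param offset additive constant applied after the median subtraction
#'   (default 300).
#' @return A [volume3d()] with normalized intensities.
#' @export
normalize_intensities <- function(vol, vois, offset = 300) {
  stopifnot(is_volume3d(vol), inherits(vois, "voi_set"))
  if (!any(vois$adjacent_normal))
    stop("adjacent normal mask is empty; cannot normalize")
  med <- stats::median(vol$data[vois$adjacent_normal])
  volume3d(vol$data - med + offset, vol$spacing, vol$origin)
}
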