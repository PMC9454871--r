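#' 3D scalar volume with voxel spacing
#'
#' Lightweight container for a regular 3D grid of HU-like intensities, the
#' common currency of the CT feature extractor. Physical coordinates of voxel
#' `(i, j, k)` (1-based array indices) are `origin + (index - 1) * spacing`,
#' in mm.
#'
#' @param data numeric 3D array of intensities (finite values).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @return An object of class `volume3d`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @export
volume3d <- function(data, spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

#' Physical coordinates of voxels
#'
#' @param vol a [volume3d()].
#' @param idx integer matrix (n x 3) of 1-based voxel indices; default all
#'   voxels in array order.
#' @return n x 3 matrix of mm coordinates.
#' @keywords internal
voxel_coords <- function(vol, idx = NULL) {
  if (is.null(idx)) {
    d <- dim(vol$data)
    idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                 k = seq_len(d[3])))
  }
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Resample a volume onto a 0.5 mm isotropic grid
#'
#' Trilinear interpolation onto a grid of 0.5 mm cubic voxels covering the
#' original field of view (preserved to within one voxel). A volume already on
#' the target grid is returned unchanged.
#'
#' @param vol a [volume3d()].
#' @param target_spacing isotropic target voxel size in mm (default 0.5).
#' @return A [volume3d()] with `spacing = rep(target_spacing, 3)`.
#' @export
resample_isotropic <- function(vol, target_spacing = 0.5) {
  stopifnot(is_volume3d(vol))
  if (!is.finite(target_spacing) || target_spacing <= 0)
    stop("degenerate target spacing")
  if (all(abs(vol$spacing - target_spacing) < 1e-12)) return(vol)

  d <- dim(vol$data)
  extent <- (d - 1) * vol$spacing            # physical span, mm
  nd <- pmax(2L, as.integer(round(extent / target_spacing)) + 1L)

  # continuous source index (0-based) of each target voxel, per axis
  ax <- lapply(1:3, function(a) {
    pos <- (seq_len(nd[a]) - 1) * target_spacing
    pmin(pmax(pos / vol$spacing[a], 0), d[a] - 1)
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  i0 <- pmin(floor(g$x), d[1] - 2); j0 <- pmin(floor(g$y), d[2] - 2)
  k0 <- pmin(floor(g$z), d[3] - 2)
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  fx <- g$x - i0; fy <- g$y - j0; fz <- g$z - k0

  at <- function(di, dj, dk) {
    vol$data[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  v <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    at(1, 1, 0) * fx       * fy       * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx       * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy       * fz +
    at(1, 1, 1) * fx       * fy       * fz
  volume3d(array(v, nd), spacing = rep(target_spacing, 3), origin = vol$origin)
}

#' Euclidean distance transform of a voxel mask
#'
#' Exact distance (mm) from every voxel to the nearest mask voxel, honouring
#' anisotropic spacing.
#'
#' @param mask logical 3D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return numeric 3D array of distances (0 inside the mask).
#' @export
distance_transform <- function(mask, spacing = c(0.5, 0.5, 0.5)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("distance transform of an empty mask is undefined")
  array(.edt3d(as.vector(mask), dim(mask), as.numeric(spacing)), dim(mask))
}

#' Write / read a volume as NIfTI
#'
#' Convenience I/O through the RNifti package; voxel spacing is carried in the
#' header. Masks are written as 0/1 volumes on the identical grid.
#'
#' @param vol a [volume3d()] (or logical array for masks with `spacing`).
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly (`read_volume` returns a [volume3d()]).
#' @export
write_volume <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI I/O")
  img <- RNifti::asNifti(vol$data, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param path input `.nii.gz` path.
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI I/O")
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3])
}
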