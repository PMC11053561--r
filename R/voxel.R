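#' Voxel grid container
#'
#' A `voxel_grid` is the in-memory form of a micro-CT image stack: a 3D
#' scalar intensity array together with the physical voxel spacing. Arrays
#' are indexed `[z, y, x]` with `z` the vertical axis and slice `z = 1` at
#' the apex (top) of the specimen; spacing is given in micrometres per
#' voxel along `(z, y, x)`.
#'
#' @param intensities 3D numeric array, indexed `[z, y, x]`.
#' @param spacing Voxel spacing in µm, either a single number (isotropic)
#'   or a length-3 vector along `(z, y, x)`.
#' @param origin Physical coordinate (µm) of the centre of voxel
#'   `[1, 1, 1]`, along `(z, y, x)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array indexed [z, y, x]")
  if (any(dim(intensities) < 1L)) stop("`intensities` must be non-empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel `spacing` must be positive (um per voxel along z, y, x)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3 (z, y, x)")
  structure(
    list(intensities = intensities, spacing = spacing, origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels [z,y,x], spacing %.6g x %.6g x %.6g um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' Congruent with the `voxel_grid` it was derived from; carries the
#' threshold that produced it and the number of small connected
#' components removed during cleanup.
#'
#' @param mask 3D logical array `[z, y, x]`.
#' @param spacing Voxel spacing in µm along `(z, y, x)`.
#' @param threshold Intensity threshold that produced the mask.
#' @param components_removed Count of connected components discarded.
#' @param origin Physical coordinate (µm) of voxel `[1, 1, 1]` centre.
#' @param crop_height_mm Height retained by [crop_top()], if cropped.
#' @param apex_slice z-index of the apex slice detected by [crop_top()].
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(mask, spacing, threshold = NA_real_,
                              components_removed = 0L, origin = c(0, 0, 0),
                              crop_height_mm = NULL, apex_slice = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a 3D logical array indexed [z, y, x]")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("voxel `spacing` must be positive (um)")
  structure(
    list(mask = mask, spacing = spacing, threshold = threshold,
         components_removed = as.integer(components_removed),
         origin = as.numeric(origin),
         crop_height_mm = crop_height_mm, apex_slice = apex_slice),
    class = "segmentation_mask"
  )
}

#' @export
print.segmentation_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<segmentation_mask> %d x %d x %d [z,y,x], %d foreground voxels\n",
    d[1], d[2], d[3], sum(x$mask)
  ))
  cat(sprintf("  threshold %.6g, components removed %d\n",
              x$threshold, x$components_removed))
  if (!is.null(x$crop_height_mm))
    cat(sprintf("  cropped to %.3g mm below apex slice %d\n",
                x$crop_height_mm, x$apex_slice))
  invisible(x)
}

# Physical voxel volume in mm^3 (spacing is um).
voxel_volume_mm3 <- function(spacing) prod(spacing) * 1e-9

# Voxel-centre physical coordinates along one axis (um).
axis_coords <- function(n, spacing, origin = 0) origin + (seq_len(n) - 1) * spacing
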