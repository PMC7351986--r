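#' Construct a fat/water volume pair
#'
#' Bundles already-separated fat and water signal volumes (e.g. from a
#' 2-point Dixon acquisition) on a common voxel grid, together with the
#' slice annotation mapping each cervical level to a contiguous axial
#' slice range.
#'
#' Arrays are indexed \code{[row, column, slice]}, 1-based; columns run
#' left-right in the axial plane (the medial-lateral direction), the third
#' axis indexes axial slices.
#'
#' @param fat,water non-negative numeric 3-D arrays of identical shape.
#' @param levels named list mapping level names (\code{"C4"}..\code{"C7"})
#'   to inclusive slice ranges \code{c(first, last)}; ranges must be
#'   disjoint and each span at least 3 slices.
#' @param voxel_size numeric length-3 voxel dimensions in mm.
#' @return object of class \code{fw_volume}.
#' @export
fw_volume <- function(fat, water, levels, voxel_size = c(0.7, 0.7, 3.0)) {
  if (!identical(dim(fat), dim(water)) || length(dim(fat)) != 3L) {
    mfigeo_stop("mfigeo_input_error",
                "fat and water must be 3-D arrays of identical shape")
  }
  if (min(fat, na.rm = TRUE) < 0 || min(water, na.rm = TRUE) < 0) {
    mfigeo_stop("mfigeo_input_error", "signal intensities must be non-negative")
  }
  validate_levels(levels, n_slices = dim(fat)[3])
  structure(list(fat = fat, water = water, levels = levels,
                 voxel_size = as.numeric(voxel_size)),
            class = "fw_volume")
}

#' @noRd
validate_levels <- function(levels, n_slices) {
  if (!all(CERVICAL_LEVELS %in% names(levels))) {
    mfigeo_stop("mfigeo_input_error",
                "level annotation must cover all of %s",
                paste(CERVICAL_LEVELS, collapse = ", "))
  }
  occ <- integer(0)
  for (nm in names(levels)) {
    r <- levels[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1 || r[2] > n_slices) {
      mfigeo_stop("mfigeo_input_error", "invalid slice range for %s", nm)
    }
    if (r[2] - r[1] + 1 < 3) {
      mfigeo_stop("mfigeo_input_error",
                  "level %s spans %d slice(s); at least 3 required",
                  nm, r[2] - r[1] + 1)
    }
    occ <- c(occ, r[1]:r[2])
  }
  if (anyDuplicated(occ)) {
    mfigeo_stop("mfigeo_input_error", "level slice ranges overlap")
  }
  invisible(TRUE)
}

#' Voxelwise muscle fat infiltration map
#'
#' Computes the fat fraction MFI = I_F / (I_F + I_W) x 100 at every voxel
#' of a fat/water volume pair. Voxels with zero total signal carry no
#' measurement: they are flagged invalid (value \code{NA}) rather than
#' assigned 0 or 100, and stay excluded from every downstream mean.
#'
#' The ratio is scale-invariant: rescaling both channels by any positive
#' constant leaves the map unchanged, so no intensity normalisation is
#' applied beforehand.
#'
#' @param volume a [fw_volume()].
#' @return object of class \code{mfi_map}: list with \code{values}
#'   (percent array, \code{NA} where invalid), \code{valid} (logical
#'   array), and the volume's \code{levels} annotation.
#' @examples
#' fat <- array(25, c(2, 2, 12)); water <- array(75, c(2, 2, 12))
#' v <- fw_volume(fat, water, list(C4 = c(1, 3), C5 = c(4, 6),
#'                                 C6 = c(7, 9), C7 = c(10, 12)))
#' m <- compute_mfi_map(v)
#' m$values[1, 1, 1]  # 25
#' @export
compute_mfi_map <- function(volume) {
  stopifnot(inherits(volume, "fw_volume"))
  total <- volume$fat + volume$water
  valid <- total > 0
  values <- array(NA_real_, dim(total))
  values[valid] <- 100 * volume$fat[valid] / total[valid]
  structure(list(values = values, valid = valid, levels = volume$levels),
            class = "mfi_map")
}

#' Mean MFI over a voxel selection
#'
#' Arithmetic mean of the valid MFI values over a set of grid positions.
#' A selection containing no valid voxel means no measurable tissue; that
#' is signalled as a classed error (\code{mfigeo_no_tissue}), never
#' returned as 0.
#'
#' @param map an \code{mfi_map}.
#' @param voxels logical array matching the map's grid, or an integer
#'   matrix of \code{[row, col, slice]} indices (one voxel per row).
#' @return mean MFI in percent, in [0, 100].
#' @export
masked_mean <- function(map, voxels) {
  stopifnot(inherits(map, "mfi_map"))
  if (is.logical(voxels)) {
    if (!identical(dim(voxels), dim(map$values))) {
      mfigeo_stop("mfigeo_input_error", "selection grid does not match map grid")
    }
    vals <- map$values[voxels & map$valid]
  } else {
    vox <- as.matrix(voxels)
    if (ncol(vox) != 3L) {
      mfigeo_stop("mfigeo_input_error", "index selection must have 3 columns")
    }
    vals <- map$values[vox]
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0L) {
    mfigeo_stop("mfigeo_no_tissue", "no measurable tissue in selection")
  }
  mean(vals)
}
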