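#' Construct a bilateral muscle mask
#'
#' A labelled mask volume for the deep cervical extensor compartment, with
#' one integer label per (cervical level, side) and a per-slice medial
#' landmark column marking the spinous-process midline.
#'
#' Label scheme: \code{10 * level_index + side_code}, where level_index is
#' 1..4 for C4..C7 and side_code is 1 (left, columns below the landmark)
#' or 2 (right, columns above the landmark); 0 is background. The "left"
#' side is the lower-column half of the image; no radiological/anatomical
#' orientation convention is imposed.
#'
#' @param labels integer 3-D array of ROI labels (0 = background).
#' @param landmark_column integer vector, one spinous-process column per
#'   slice.
#' @param levels named list of inclusive slice ranges per level, as in
#'   [fw_volume()].
#' @return object of class \code{muscle_mask}.
#' @export
muscle_mask <- function(labels, landmark_column, levels) {
  if (length(dim(labels)) != 3L) {
    mfigeo_stop("mfigeo_input_error", "labels must be a 3-D array")
  }
  if (length(landmark_column) != dim(labels)[3]) {
    mfigeo_stop("mfigeo_input_error",
                "need one landmark column per slice (%d), got %d",
                dim(labels)[3], length(landmark_column))
  }
  validate_levels(levels, n_slices = dim(labels)[3])
  structure(list(labels = labels,
                 landmark_column = as.integer(landmark_column),
                 levels = levels),
            class = "muscle_mask")
}

#' @noRd
mask_label <- function(level, side) {
  10L * match(level, CERVICAL_LEVELS) + match(side, SIDE_LEVELS)
}

#' Voxel indices of one slice-side ROI
#'
#' @param mask a \code{muscle_mask}.
#' @param slice slice index.
#' @param side \code{"left"} or \code{"right"}.
#' @return integer matrix with columns \code{row}, \code{col} (possibly
#'   0 rows).
#' @export
mask_slice_voxels <- function(mask, slice, side) {
  side_code <- match(side, SIDE_LEVELS)
  sl <- mask$labels[, , slice]
  idx <- which(sl > 0 & sl %% 10L == side_code, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx
}

#' Medial-lateral coordinate of ROI voxels
#'
#' The medial-lateral position of each ROI voxel is its unsigned column
#' distance from the slice's spinous-process landmark column, increasing
#' laterally on both sides, so mirror-image masks receive identical
#' coordinate multisets.
#'
#' @param voxels integer matrix with columns \code{row}, \code{col} (one
#'   ROI voxel per row).
#' @param landmark_column spinous-process column for this slice.
#' @param side \code{"left"} (columns <= landmark) or \code{"right"}
#'   (columns >= landmark). Voxels strictly on the far side of the
#'   landmark mean the mask and landmark are inconsistent: input error.
#' @return numeric vector of coordinates, one per voxel (0 at the
#'   landmark column itself).
#' @export
medial_lateral_coordinate <- function(voxels, landmark_column, side) {
  if (nrow(voxels) == 0L) {
    mfigeo_stop("mfigeo_input_error", "ROI is empty")
  }
  side <- match.arg(side, SIDE_LEVELS)
  d <- voxels[, "col"] - landmark_column
  if (side == "right" && any(d < 0) || side == "left" && any(d > 0)) {
    mfigeo_stop("mfigeo_input_error",
                "ROI voxels found medial of the landmark column on the %s side",
                side)
  }
  abs(d)
}

#' Partition one slice-side ROI into four medial-lateral quartiles
#'
#' Voxels are ranked by (medial-lateral coordinate, then row, then column)
#' and split into four contiguous rank bins of near-equal size (sizes
#' differ by at most 1; when the count is not divisible by 4 the larger
#' bins are placed medially first). Q1 is the most medial bin, abutting
#' the spinous process; Q4 the most lateral.
#'
#' Equal-area (equal voxel count) bins make the per-quartile means equally
#' precise; equal-width bands along the medial-lateral axis are available
#' via \code{rule = "width"} (bin edges at quarters of the coordinate
#' range, which generally yields unequal voxel counts).
#'
#' @param voxels integer matrix with columns \code{row}, \code{col}.
#' @param coordinates medial-lateral coordinate per voxel, from
#'   [medial_lateral_coordinate()].
#' @param rule \code{"area"} (default, equal voxel count) or
#'   \code{"width"} (equal coordinate bands).
#' @return integer vector of quartile labels 1-4, aligned with the rows
#'   of \code{voxels}.
#' @export
partition_quartiles <- function(voxels, coordinates, rule = c("area", "width")) {
  rule <- match.arg(rule)
  n <- nrow(voxels)
  if (n == 0L || length(coordinates) != n) {
    mfigeo_stop("mfigeo_input_error",
                "need a coordinate for every ROI voxel (non-empty)")
  }
  if (rule == "width") {
    lo <- min(coordinates); hi <- max(coordinates)
    if (hi == lo) return(rep(1L, n))
    q <- findInterval(coordinates, lo + (hi - lo) * (1:3) / 4,
                      left.open = TRUE) + 1L
    return(as.integer(q))
  }
  ord <- order(coordinates, voxels[, "row"], voxels[, "col"])
  base <- n %/% 4L
  sizes <- base + as.integer(seq_len(4L) <= n %% 4L)
  q <- integer(n)
  q[ord] <- rep.int(1:4, sizes)
  q
}

#' Partition every slice and side of a mask volume
#'
#' Applies [medial_lateral_coordinate()] and [partition_quartiles()]
#' independently to each (slice, side) ROI within the annotated level
#' ranges. A slice-side with an empty ROI is recorded as missing, not
#' fatal.
#'
#' @param mask a \code{muscle_mask}.
#' @param rule quartile rule, see [partition_quartiles()].
#' @return object of class \code{quartile_map}: list with \code{labels}
#'   (integer array, 0 background / 1-4 quartile) and \code{missing}
#'   (data frame of empty slice-sides).
#' @export
partition_volume <- function(mask, rule = c("area", "width")) {
  rule <- match.arg(rule)
  stopifnot(inherits(mask, "muscle_mask"))
  qlab <- array(0L, dim(mask$labels))
  miss <- list()
  slices <- sort(unique(unlist(lapply(mask$levels, function(r) r[1]:r[2]))))
  for (s in slices) {
    for (side in SIDE_LEVELS) {
      vox <- mask_slice_voxels(mask, s, side)
      if (nrow(vox) == 0L) {
        miss[[length(miss) + 1L]] <- data.frame(slice = s, side = side)
        next
      }
      coords <- medial_lateral_coordinate(vox, mask$landmark_column[s], side)
      q <- partition_quartiles(vox, coords, rule = rule)
      qlab[cbind(vox, slice = s)] <- q
    }
  }
  missing <- if (length(miss)) do.call(rbind, miss) else
    data.frame(slice = integer(0), side = character(0))
  structure(list(labels = qlab, missing = missing, rule = rule),
            class = "quartile_map")
}
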