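#' Central three slices of a cervical level
#'
#' MFI per level is averaged over three axial slices. The three slices
#' centred on the midpoint of the level's annotated range are used:
#' \code{mid = floor((first + last) / 2)} and its two neighbours. Central
#' slices are least affected by ambiguity in where one level ends and the
#' next begins.
#'
#' @param levels named list of inclusive slice ranges (or an
#'   \code{fw_volume} / \code{mfi_map} / \code{muscle_mask} carrying one).
#' @param level level name, e.g. \code{"C5"}.
#' @return integer vector of three slice indices.
#' @examples
#' slices_for_level(list(C4 = c(4, 9), C5 = c(10, 12),
#'                       C6 = c(13, 15), C7 = c(16, 18)), "C4")  # 5 6 7
#' @export
slices_for_level <- function(levels, level) {
  if (!is.list(levels) || inherits(levels, c("fw_volume", "mfi_map", "muscle_mask"))) {
    levels <- levels$levels
  }
  r <- levels[[level]]
  if (is.null(r)) {
    mfigeo_stop("mfigeo_input_error", "no slice range annotated for %s", level)
  }
  if (r[2] - r[1] + 1 < 3) {
    mfigeo_stop("mfigeo_input_error",
                "level %s spans fewer than 3 slices", level)
  }
  mid <- (r[1] + r[2]) %/% 2L
  as.integer(c(mid - 1L, mid, mid + 1L))
}

#' Aggregate an MFI map to per-level, per-quartile records
#'
#' For each cervical level and quartile, pools every valid MFI voxel of
#' that quartile across the level's three central slices and (by default)
#' both sides, and takes the arithmetic mean. This voxel-weighted pooling
#' weights each side by the amount of measured tissue;
#' \code{bilateral = "side-mean"} instead averages the two per-side means
#' with equal weight.
#'
#' @param map an \code{mfi_map}.
#' @param qmap a \code{quartile_map} on the same grid.
#' @param mask the \code{muscle_mask} the quartile map was derived from.
#' @param bilateral \code{"pool"} (default) or \code{"side-mean"}.
#' @param cache optional precomputed [quartile_indices()] for this
#'   (qmap, mask) pair; pass it when aggregating many volumes that share
#'   one mask.
#' @return data frame with columns \code{level}, \code{quartile},
#'   \code{mfi}, \code{n_voxels}; cells with zero valid voxels are
#'   omitted and listed in the \code{"missing"} attribute.
#' @export
quartile_level_mfi <- function(map, qmap, mask,
                               bilateral = c("pool", "side-mean"),
                               cache = NULL) {
  bilateral <- match.arg(bilateral)
  stopifnot(inherits(map, "mfi_map"), inherits(qmap, "quartile_map"),
            inherits(mask, "muscle_mask"))
  if (!identical(dim(map$values), dim(qmap$labels))) {
    mfigeo_stop("mfigeo_input_error", "MFI map and quartile map grids differ")
  }
  cache <- cache %||% quartile_indices(qmap, mask)
  rows <- list(); miss <- list()
  for (level in CERVICAL_LEVELS) {
    for (q in 1:4) {
      per_side <- lapply(SIDE_LEVELS, function(side) {
        i <- cache[[level]][[q]][[side]]
        v <- map$values[i]
        v[!is.na(v)]
      })
      n_side <- lengths(per_side)
      if (sum(n_side) == 0L) {
        miss[[length(miss) + 1L]] <- data.frame(level = level, quartile = q)
        next
      }
      if (bilateral == "pool") {
        mfi <- mean(unlist(per_side))
      } else {
        mfi <- mean(vapply(per_side[n_side > 0], mean, numeric(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        level = level, quartile = q, mfi = mfi, n_voxels = sum(n_side))
    }
  }
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = CERVICAL_LEVELS)
  attr(out, "missing") <- if (length(miss)) do.call(rbind, miss) else
    data.frame(level = character(0), quartile = integer(0))
  out
}

#' Precompute voxel indices per (level, quartile, side)
#'
#' Linear indices into the volume grid of every quartile-labelled ROI
#' voxel within each level's three central slices. The result depends
#' only on the quartile map and the mask, so it can be computed once and
#' reused across all participants sharing that mask.
#'
#' @param qmap a \code{quartile_map}.
#' @param mask the matching \code{muscle_mask}.
#' @return nested list \code{[[level]][[quartile]][[side]]} of integer
#'   vectors.
#' @export
quartile_indices <- function(qmap, mask) {
  dims <- dim(mask$labels)
  plane <- dims[1] * dims[2]
  out <- list()
  for (level in CERVICAL_LEVELS) {
    sl <- slices_for_level(mask$levels, level)
    out[[level]] <- lapply(1:4, function(q) {
      per_side <- lapply(SIDE_LEVELS, function(side) {
        side_code <- match(side, SIDE_LEVELS)
        unlist(lapply(sl, function(s) {
          m <- mask$labels[, , s]
          keep <- which(qmap$labels[, , s] == q & m > 0 &
                          m %% 10L == side_code)
          keep + (s - 1L) * plane
        }))
      })
      names(per_side) <- SIDE_LEVELS
      per_side
    })
  }
  out
}

#' Build the long analysis table
#'
#' Joins per-participant MFI records with participant metadata into the
#' unit-of-analysis table: one row per participant x level x quartile,
#' with demographics, NDI and recovery group, ready for the mixed model.
#'
#' @param records data frame with columns \code{id}, \code{level},
#'   \code{quartile}, \code{mfi}, \code{n_voxels} (e.g. row-bound
#'   [quartile_level_mfi()] outputs with an \code{id} column added).
#' @param participants metadata data frame with columns \code{id},
#'   \code{age}, \code{sex}, \code{bmi}, \code{ndi_percent},
#'   \code{group}.
#' @return data frame in long format, one row per available record.
#' @export
build_analysis_table <- function(records, participants) {
  if (nrow(records) == 0L) {
    mfigeo_stop("mfigeo_input_error", "no MFI records to tabulate")
  }
  bad <- setdiff(unique(records$id), participants$id)
  if (length(bad)) {
    mfigeo_stop("mfigeo_join_error",
                "records reference unknown participant id(s): %s",
                paste(bad, collapse = ", "))
  }
  meta_cols <- c("id", "group", "age", "sex", "bmi", "ndi_percent")
  out <- merge(records, participants[meta_cols], by = "id", sort = FALSE)
  out <- out[order(out$id, out$level, out$quartile), ]
  rownames(out) <- NULL
  out$group <- factor(as.character(out$group), levels = GROUP_LEVELS)
  out$level <- factor(as.character(out$level), levels = CERVICAL_LEVELS)
  out[, c("id", "group", "age", "sex", "bmi", "ndi_percent",
          "level", "quartile", "mfi", "n_voxels")]
}
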