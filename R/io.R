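#' Write a synthetic cohort to disk in standard formats
#'
#' Fat, water and mask volumes are written as NIfTI (one file per
#' participant for fat/water; the shared mask once), participant
#' metadata and ground truth as CSV, level/landmark annotations and a
#' manifest (seed, config hash, file list) as JSON.
#'
#' @param cohort a \code{synthetic_cohort} from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- cohort$volumes[[1]]$voxel_size
  files <- character(0)
  for (id in names(cohort$volumes)) {
    v <- cohort$volumes[[id]]
    fp <- file.path(dir, sprintf("%s_fat.nii.gz", id))
    wp <- file.path(dir, sprintf("%s_water.nii.gz", id))
    RNifti::writeNifti(RNifti::asNifti(v$fat, pixdim = vox), fp)
    RNifti::writeNifti(RNifti::asNifti(v$water, pixdim = vox), wp)
    files <- c(files, fp, wp)
  }
  mp <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(cohort$mask$labels, pixdim = vox), mp)
  meta_p <- file.path(dir, "participants.csv")
  write.csv(cohort$participants, meta_p, row.names = FALSE)
  truth_p <- file.path(dir, "ground_truth.csv")
  write.csv(cohort$truth, truth_p, row.names = FALSE)
  ann_p <- file.path(dir, "annotations.json")
  jsonlite::write_json(list(
    levels = cohort$mask$levels,
    landmark_column = cohort$mask$landmark_column,
    voxel_size = vox,
    label_scheme = "10*level_index(C4..C7=1..4) + side(left=1,right=2)"),
    ann_p, auto_unbox = FALSE)
  files <- c(files, mp, meta_p, truth_p, ann_p)
  manifest <- list(seed = cohort$seed,
                   config_hash = config_hash(list(
                     n = nrow(cohort$participants),
                     profiles = cohort$profiles$means,
                     seed = cohort$seed)),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' @noRd
read_annotations <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- lapply(ann$levels, as.integer)
  list(levels = levels,
       landmark_column = as.integer(ann$landmark_column),
       voxel_size = as.numeric(ann$voxel_size %||% c(0.7, 0.7, 3.0)))
}

#' Read one participant's fat/water pair from NIfTI files
#'
#' Verifies that the two volumes share a grid before bundling them.
#'
#' @param fat_path,water_path NIfTI file paths.
#' @param annotations_path JSON annotation file carrying the level slice
#'   ranges (and landmark columns / voxel size), as written by
#'   [write_cohort()].
#' @return an \code{fw_volume}.
#' @export
read_fatwater <- function(fat_path, water_path, annotations_path) {
  fat <- as.array(RNifti::readNifti(fat_path))
  water <- as.array(RNifti::readNifti(water_path))
  if (!identical(dim(fat), dim(water))) {
    mfigeo_stop("mfigeo_input_error",
                "grid mismatch between %s (%s) and %s (%s)",
                fat_path, paste(dim(fat), collapse = "x"),
                water_path, paste(dim(water), collapse = "x"))
  }
  ann <- read_annotations(annotations_path)
  fw_volume(fat, water, ann$levels, ann$voxel_size)
}

#' Read a labelled mask volume from NIfTI
#'
#' @param mask_path NIfTI file of integer ROI labels.
#' @param annotations_path JSON annotations carrying landmark columns
#'   and level ranges.
#' @param reference_dim optional grid dimensions to validate against
#'   (e.g. \code{dim(volume$fat)}); a mismatch is a hard error naming
#'   both grids.
#' @return a \code{muscle_mask}.
#' @export
read_mask <- function(mask_path, annotations_path, reference_dim = NULL) {
  lab <- as.array(RNifti::readNifti(mask_path))
  storage.mode(lab) <- "integer"
  if (!is.null(reference_dim) && !identical(dim(lab), as.integer(reference_dim))) {
    mfigeo_stop("mfigeo_input_error",
                "mask grid (%s) does not match image grid (%s)",
                paste(dim(lab), collapse = "x"),
                paste(reference_dim, collapse = "x"))
  }
  ann <- read_annotations(annotations_path)
  muscle_mask(lab, ann$landmark_column, ann$levels)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param paths either a directory path (the [write_cohort()] layout) or
#'   a list with components \code{dir} or explicit \code{mask},
#'   \code{annotations}, \code{metadata} paths.
#' @return a \code{synthetic_cohort}-shaped list usable by
#'   [cohort_analysis_table()] (without ground truth unless present).
#' @export
read_cohort <- function(paths) {
  dir <- if (is.character(paths)) paths else paths$dir
  if (is.null(dir) || !dir.exists(dir)) {
    mfigeo_stop("mfigeo_input_error", "cohort directory not found")
  }
  ann_p <- file.path(dir, "annotations.json")
  meta <- read.csv(file.path(dir, "participants.csv"),
                   stringsAsFactors = FALSE)
  meta$group <- factor(meta$group, levels = GROUP_LEVELS)
  meta$sex <- factor(meta$sex, levels = c("female", "male"))
  volumes <- list()
  for (id in meta$id) {
    fp <- file.path(dir, sprintf("%s_fat.nii.gz", id))
    wp <- file.path(dir, sprintf("%s_water.nii.gz", id))
    if (!file.exists(fp) || !file.exists(wp)) {
      mfigeo_stop("mfigeo_input_error",
                  "missing fat/water file(s) for participant %s", id)
    }
    volumes[[id]] <- read_fatwater(fp, wp, ann_p)
  }
  mask <- read_mask(file.path(dir, "mask.nii.gz"), ann_p,
                    reference_dim = dim(volumes[[1]]$fat))
  truth_p <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_p)) read.csv(truth_p) else NULL
  structure(list(participants = meta, volumes = volumes, mask = mask,
                 qmap = NULL, truth = truth),
            class = "synthetic_cohort")
}

#' Write an MFI map as a NIfTI volume for quality control
#'
#' Invalid voxels (no signal) are written as NaN.
#'
#' @param map an \code{mfi_map}.
#' @param path output NIfTI path.
#' @param voxel_size voxel dimensions in mm.
#' @export
write_mfi_map <- function(map, path, voxel_size = c(0.7, 0.7, 3.0)) {
  vals <- map$values
  vals[!map$valid] <- NaN
  RNifti::writeNifti(RNifti::asNifti(vals, pixdim = voxel_size), path)
  invisible(path)
}
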