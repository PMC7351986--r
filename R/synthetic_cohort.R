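#' Default per-group demographic parameters
#'
#' Means/SDs for age and BMI and the female fraction per recovery group,
#' matching the sub-study's reported demographics (severe: BMI
#' 25.7 +/- 2.8, age 37.0 +/- 12.5, 80% female; mild: 23.8 +/- 3.7,
#' 37.9 +/- 12.5, 88% female; recovered: 23.6 +/- 3.1, 31.5 +/- 10.7,
#' 56% female).
#'
#' @return named list of per-group parameter lists.
#' @export
default_demographics <- function() {
  list(
    severe    = list(age_mean = 37.0, age_sd = 12.5,
                     bmi_mean = 25.7, bmi_sd = 2.8, female_frac = 0.80),
    mild      = list(age_mean = 37.9, age_sd = 12.5,
                     bmi_mean = 23.8, bmi_sd = 3.7, female_frac = 0.88),
    recovered = list(age_mean = 31.5, age_sd = 10.7,
                     bmi_mean = 23.6, bmi_sd = 3.1, female_frac = 0.56)
  )
}

#' Default NDI sampling bands per group
#'
#' Uniform sampling bands consistent with the group thresholds: severe
#' [30, 60], mild [10, 30), recovered [0, 10). Only band membership is
#' knowable from group labels, so uniform within the band is the
#' least-assumptive choice.
#' @return named list of \code{c(lo, hi)} bands (sampling is uniform on
#'   [lo, hi)).
#' @export
default_ndi_bands <- function() {
  list(severe = c(30, 60), mild = c(10, 30), recovered = c(0, 10))
}

#' Default quartile MFI profiles
#'
#' Generator calibration for the medial-lateral MFI geography: within
#' every group Q1 (most medial) carries the highest MFI and the lateral
#' quartiles are low and flat; the symptomatic groups are elevated in Q1
#' at all levels and in Q2 at C4-C5 only. The numeric means are this
#' package's calibration (chosen to land in the plausible 10-45% range
#' for deep cervical extensor fat fraction), not measured values.
#'
#' @param participant_sd between-participant random-intercept SD (MFI %).
#' @param slope_sd between-participant random-slope SD per quartile step.
#' @param voxel_noise_sd intensity-unit SD of voxel noise.
#' @param water_reference total (fat+water) signal per voxel, intensity
#'   units.
#' @return object of class \code{quartile_profiles}: list with
#'   \code{means} (data frame group x level x Q1..Q4) and the four noise
#'   parameters.
#' @export
default_profiles <- function(participant_sd = 4, slope_sd = 1,
                             voxel_noise_sd = 50, water_reference = 1000) {
  base <- expand.grid(group = GROUP_LEVELS, level = CERVICAL_LEVELS,
                      stringsAsFactors = FALSE)
  q <- t(vapply(seq_len(nrow(base)), function(i) {
    g <- base$group[i]; lv <- base$level[i]
    q1 <- switch(g, recovered = 28, mild = 36, severe = 40)
    q2 <- if (g != "recovered" && lv %in% c("C4", "C5"))
      switch(g, mild = 22, severe = 24) else 18
    c(q1, q2, 15, 14.5)
  }, numeric(4)))
  colnames(q) <- paste0("Q", 1:4)
  quartile_profiles(cbind(base, q), participant_sd = participant_sd,
                    slope_sd = slope_sd, voxel_noise_sd = voxel_noise_sd,
                    water_reference = water_reference)
}

#' Construct (and validate) a quartile-profile set
#'
#' @param means data frame with columns \code{group}, \code{level},
#'   \code{Q1}..\code{Q4} covering every group x level combination.
#' @inheritParams default_profiles
#' @export
quartile_profiles <- function(means, participant_sd = 4, slope_sd = 1,
                              voxel_noise_sd = 50, water_reference = 1000) {
  need <- c("group", "level", paste0("Q", 1:4))
  stopifnot(all(need %in% names(means)))
  m <- as.matrix(means[, paste0("Q", 1:4)])
  if (any(m < 0 | m > 100)) {
    mfigeo_stop("mfigeo_config_error", "profile means must lie in [0, 100]")
  }
  if (any(m[, 1] <= m[, 2]) || any(m[, 2] < m[, 3])) {
    mfigeo_stop("mfigeo_config_error",
                "profiles must satisfy Q1 > Q2 >= Q3 (medial concentration)")
  }
  if (min(participant_sd, slope_sd, voxel_noise_sd) < 0 || water_reference <= 0) {
    mfigeo_stop("mfigeo_config_error", "SDs must be >= 0 and water_reference > 0")
  }
  structure(list(means = means, participant_sd = participant_sd,
                 slope_sd = slope_sd, voxel_noise_sd = voxel_noise_sd,
                 water_reference = water_reference),
            class = "quartile_profiles")
}

#' Null profiles (no group differences)
#'
#' Every group shares the recovered group's medial-lateral profile;
#' useful for type-I-error simulation.
#' @inheritParams default_profiles
#' @export
null_profiles <- function(participant_sd = 4, slope_sd = 1,
                          voxel_noise_sd = 50, water_reference = 1000) {
  p <- default_profiles(participant_sd, slope_sd, voxel_noise_sd,
                        water_reference)
  rec <- p$means[p$means$group == "recovered", c("level", paste0("Q", 1:4))]
  for (g in c("mild", "severe")) {
    i <- match(p$means$level[p$means$group == g], rec$level)
    p$means[p$means$group == g, paste0("Q", 1:4)] <- rec[i, paste0("Q", 1:4)]
  }
  p
}

#' Generate participant metadata
#'
#' Draws a cohort of the requested per-group sizes. NDI scores are
#' sampled uniformly within each group's band; age and BMI are Gaussian
#' with the group's mean/SD (age clipped to the 18-65 inclusion band,
#' BMI floored at 15); sex is Bernoulli with the group's female
#' fraction. Deterministic given \code{seed}.
#'
#' @param n_severe,n_mild,n_recovered group sizes (>= 0).
#' @param demographics per-group demographic parameters, see
#'   [default_demographics()].
#' @param ndi_bands per-group NDI intervals, see [default_ndi_bands()].
#'   Bands must be disjoint and consistent with the group thresholds.
#' @param seed integer RNG seed.
#' @return data frame with columns \code{id}, \code{age}, \code{sex},
#'   \code{bmi}, \code{ndi_percent}, \code{group}.
#' @examples
#' meta <- generate_metadata(10, 26, 25, seed = 1)
#' table(meta$group)
#' @export
generate_metadata <- function(n_severe, n_mild, n_recovered,
                              demographics = default_demographics(),
                              ndi_bands = default_ndi_bands(),
                              seed = 1L) {
  counts <- c(severe = n_severe, mild = n_mild, recovered = n_recovered)
  if (any(counts < 0)) {
    mfigeo_stop("mfigeo_config_error", "group counts must be >= 0")
  }
  check_ndi_bands(ndi_bands)
  set.seed(as.integer(seed))
  rows <- list()
  k <- 0L
  for (g in c("severe", "mild", "recovered")) {
    n <- counts[[g]]
    if (n == 0L) next
    d <- demographics[[g]]
    b <- ndi_bands[[g]]
    age <- pmin(65, pmax(18, rnorm(n, d$age_mean, d$age_sd)))
    bmi <- pmax(15, rnorm(n, d$bmi_mean, d$bmi_sd))
    sex <- ifelse(runif(n) < d$female_frac, "female", "male")
    ndi <- runif(n, b[1], b[2])
    ndi[ndi >= b[2]] <- b[1]  # guard the half-open upper edge
    rows[[g]] <- data.frame(
      id = sprintf("P%03d", k + seq_len(n)),
      age = age, sex = factor(sex, levels = c("female", "male")),
      bmi = bmi, ndi_percent = ndi,
      group = factor(g, levels = GROUP_LEVELS))
    k <- k + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  chk <- assign_group(out$ndi_percent)
  if (!all(chk == out$group)) {
    mfigeo_stop("mfigeo_config_error",
                "ndi_bands are inconsistent with the group thresholds")
  }
  out
}

#' @noRd
check_ndi_bands <- function(bands) {
  stopifnot(all(c("severe", "mild", "recovered") %in% names(bands)))
  iv <- do.call(rbind, bands[c("recovered", "mild", "severe")])
  if (any(iv[, 1] >= iv[, 2]) || any(iv < 0) || any(iv > 100)) {
    mfigeo_stop("mfigeo_config_error", "NDI bands must be valid sub-intervals of [0, 100]")
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    mfigeo_stop("mfigeo_config_error", "NDI bands overlap")
  }
  invisible(TRUE)
}

#' Rasterize one elliptical slice-side ROI
#'
#' Stands in for manual segmentation: a filled ellipse placed lateral of
#' the spinous-process landmark column, on the requested side. The
#' medial-most column of the ROI abuts the landmark at the given offset.
#'
#' @param grid_shape \code{c(n_rows, n_cols)} of the slice.
#' @param side \code{"left"} or \code{"right"}.
#' @param semi_axes \code{c(a_cols, b_rows)} ellipse semi-axes in voxels.
#' @param landmark_column spinous-process column (1-based).
#' @param medial_offset gap in columns between the landmark and the ROI's
#'   medial edge (default 1, i.e. the ROI starts in the next column).
#' @param center_row ellipse centre row (default: middle of the grid).
#' @return logical matrix of the ROI (class \code{matrix}).
#' @export
generate_mask_slice <- function(grid_shape, side, semi_axes,
                                landmark_column, medial_offset = 1,
                                center_row = NULL) {
  side <- match.arg(side, SIDE_LEVELS)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  a <- semi_axes[1]; b <- semi_axes[2]
  if (landmark_column < 1 || landmark_column > nc) {
    mfigeo_stop("mfigeo_config_error", "landmark column outside grid")
  }
  center_row <- center_row %||% ((nr + 1) %/% 2)
  sgn <- if (side == "right") 1 else -1
  center_col <- landmark_column + sgn * (medial_offset + a)
  if (center_col - a < 1 || center_col + a > nc ||
      center_row - b < 1 || center_row + b > nr) {
    mfigeo_stop("mfigeo_config_error", "ellipse does not fit inside the grid")
  }
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rows <- matrix(seq_len(nr), nr, nc)
  roi <- ((cols - center_col) / a)^2 + ((rows - center_row) / b)^2 <= 1
  if (!any(roi)) {
    mfigeo_stop("mfigeo_generation_error", "rasterized ROI is empty")
  }
  roi
}

#' Build the cohort's shared mask volume
#'
#' One bilateral elliptical ROI pair per slice over the C4-C7 stack, with
#' the landmark at the grid's middle column. All synthetic participants
#' share this mask (morphological variation between participants is not
#' emulated).
#'
#' @param grid_shape \code{c(n_rows, n_cols)}.
#' @param slices_per_level axial slices per cervical level (>= 3).
#' @param semi_axes ellipse semi-axes \code{c(a_cols, b_rows)}.
#' @param medial_offset columns between landmark and medial ROI edge.
#' @return a \code{muscle_mask}.
#' @export
build_cohort_mask <- function(grid_shape = c(48, 80), slices_per_level = 3,
                              semi_axes = c(14, 6), medial_offset = 1) {
  if (slices_per_level < 3) {
    mfigeo_stop("mfigeo_config_error", "need at least 3 slices per level")
  }
  n_slices <- 4L * slices_per_level
  landmark <- rep((grid_shape[2] + 1L) %/% 2L, n_slices)
  levels <- setNames(lapply(seq_along(CERVICAL_LEVELS), function(i) {
    c((i - 1L) * slices_per_level + 1L, i * slices_per_level)
  }), CERVICAL_LEVELS)
  labels <- array(0L, c(grid_shape, n_slices))
  for (lv in CERVICAL_LEVELS) {
    r <- levels[[lv]]
    for (s in r[1]:r[2]) {
      for (side in SIDE_LEVELS) {
        roi <- generate_mask_slice(grid_shape, side, semi_axes,
                                   landmark[s], medial_offset)
        labels[, , s][roi] <- mask_label(lv, side)
      }
    }
  }
  muscle_mask(labels, landmark, levels)
}

#' Synthesize fat/water volumes for a cohort
#'
#' Inverts the fat-fraction relation to turn target MFI values into
#' intensities. Each participant's target MFI at a voxel in quartile q of
#' level L is the group profile mean plus a participant random intercept
#' plus a participant random slope times q, clipped to [0, 100]; fat
#' intensity is \code{water_reference * m/100 + noise} and water
#' intensity \code{water_reference * (1 - m/100) + noise}, with
#' independent zero-mean Gaussian noise and the resulting intensity
#' truncated at 0. With all SDs zero the pipeline recovers the profile
#' means exactly.
#'
#' Randomness is fanned out per participant: participant i's volume
#' depends only on (\code{seed}, i), not on generation order.
#'
#' @param participants metadata from [generate_metadata()].
#' @param profiles a \code{quartile_profiles}.
#' @param mask shared \code{muscle_mask} from [build_cohort_mask()].
#' @param seed integer seed.
#' @return list with \code{volumes} (named list of \code{fw_volume}),
#'   \code{truth} (data frame id x level x quartile with the true cell
#'   mean \code{true_mfi} and realized random effects \code{b0},
#'   \code{b1}), and the inputs.
#' @export
generate_fatwater <- function(participants, profiles = default_profiles(),
                              mask = build_cohort_mask(), seed = 1L) {
  stopifnot(inherits(profiles, "quartile_profiles"),
            inherits(mask, "muscle_mask"))
  qmap <- partition_volume(mask)
  dims <- dim(mask$labels)
  R <- profiles$water_reference

  # per-voxel (level, quartile) lookup, shared by all participants
  lvl_of_slice <- character(dims[3])
  for (lv in CERVICAL_LEVELS) {
    r <- mask$levels[[lv]]
    lvl_of_slice[r[1]:r[2]] <- lv
  }
  in_roi <- mask$labels > 0L & qmap$labels > 0L
  idx <- which(in_roi)
  slice_of_idx <- ((idx - 1L) %/% (dims[1] * dims[2])) + 1L
  lvl_idx <- match(lvl_of_slice[slice_of_idx], CERVICAL_LEVELS)
  q_idx <- qmap$labels[idx]

  pm <- profiles$means
  mean_lookup <- array(NA_real_, c(length(GROUP_LEVELS), 4L, 4L))
  for (i in seq_len(nrow(pm))) {
    gi <- match(pm$group[i], GROUP_LEVELS)
    li <- match(pm$level[i], CERVICAL_LEVELS)
    mean_lookup[gi, li, ] <- as.numeric(pm[i, paste0("Q", 1:4)])
  }

  volumes <- list(); truth <- list()
  for (p in seq_len(nrow(participants))) {
    # double arithmetic: exact below 2^53, avoids 32-bit overflow
    set.seed(as.integer((as.numeric(seed) * 10007 + p) %% 2147483647))
    gi <- match(as.character(participants$group[p]), GROUP_LEVELS)
    b0 <- rnorm(1, 0, profiles$participant_sd)
    b1 <- rnorm(1, 0, profiles$slope_sd)
    m <- mean_lookup[cbind(gi, lvl_idx, q_idx)] + b0 + b1 * q_idx
    m <- pmin(100, pmax(0, m))
    fat <- array(0, dims)
    water <- array(R, dims)
    nz <- profiles$voxel_noise_sd
    fat[idx] <- pmax(0, R * m / 100 +
                       (if (nz > 0) rnorm(length(idx), 0, nz) else 0))
    water[idx] <- pmax(0, R * (1 - m / 100) +
                         (if (nz > 0) rnorm(length(idx), 0, nz) else 0))
    volumes[[participants$id[p]]] <- fw_volume(fat, water, mask$levels)
    tt <- expand.grid(level = CERVICAL_LEVELS, quartile = 1:4,
                      stringsAsFactors = FALSE)
    tt$true_mfi <- pmin(100, pmax(0,
      mean_lookup[cbind(gi, match(tt$level, CERVICAL_LEVELS), tt$quartile)] +
        b0 + b1 * tt$quartile))
    tt$id <- participants$id[p]; tt$b0 <- b0; tt$b1 <- b1
    truth[[p]] <- tt
  }
  truth <- do.call(rbind, truth)[, c("id", "level", "quartile",
                                     "true_mfi", "b0", "b1")]
  list(volumes = volumes, truth = truth, mask = mask, qmap = qmap,
       participants = participants, profiles = profiles, seed = seed)
}

#' Simulate a full synthetic Dixon cohort
#'
#' Metadata plus fat/water volumes with ground truth, in one call.
#'
#' @inheritParams generate_metadata
#' @inheritParams generate_fatwater
#' @param grid_shape,slices_per_level,semi_axes mask geometry, see
#'   [build_cohort_mask()].
#' @return a \code{synthetic_cohort} list: \code{participants},
#'   \code{volumes}, \code{mask}, \code{qmap}, \code{truth},
#'   \code{profiles}, \code{seed}.
#' @examples
#' co <- simulate_cohort(2, 2, 2, seed = 42)
#' names(co$volumes)
#' @export
simulate_cohort <- function(n_severe = 10, n_mild = 26, n_recovered = 25,
                            profiles = default_profiles(),
                            grid_shape = c(48, 80), slices_per_level = 3,
                            semi_axes = c(14, 6), seed = 1L,
                            demographics = default_demographics(),
                            ndi_bands = default_ndi_bands()) {
  meta <- generate_metadata(n_severe, n_mild, n_recovered,
                            demographics, ndi_bands, seed = seed)
  mask <- build_cohort_mask(grid_shape, slices_per_level, semi_axes)
  gen <- generate_fatwater(meta, profiles, mask, seed = seed)
  structure(gen, class = "synthetic_cohort")
}
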