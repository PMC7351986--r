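# Shared fixture builders and independent oracles.

# A 12-slice level annotation (3 slices per level).
tiny_levels <- function(slices_per_level = 3) {
  setNames(lapply(1:4, function(i) {
    c((i - 1L) * slices_per_level + 1L, i * slices_per_level)
  }), c("C4", "C5", "C6", "C7"))
}

# Constant-intensity fat/water volume on a small grid.
tiny_volume <- function(fat_val, water_val, dims = c(4, 6, 12)) {
  fw_volume(array(fat_val, dims), array(water_val, dims), tiny_levels())
}

# Random connected-ish blob ROI: voxels of a random ellipse union, as an
# index matrix (row, col), all strictly on the requested side of the
# landmark.
random_blob <- function(n_target, landmark, side, nrows = 40, ncols = 80,
                        rng = NULL) {
  sgn <- if (side == "right") 1 else -1
  cols <- landmark + sgn * sample.int(30, n_target, replace = TRUE)
  rows <- sample.int(nrows, n_target, replace = TRUE)
  unique(cbind(row = rows, col = cols))
}

# Independent brute-force oracle: sort voxels by (coordinate, row, col)
# and slice the sorted list into four bins, larger bins first.
oracle_sort_slice <- function(voxels, coords) {
  df <- data.frame(i = seq_len(nrow(voxels)), coord = coords,
                   row = voxels[, "row"], col = voxels[, "col"])
  df <- df[order(df$coord, df$row, df$col), ]
  n <- nrow(df)
  sizes <- rep(n %/% 4, 4)
  rem <- n %% 4
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  lab <- integer(n)
  pos <- 1
  for (q in 1:4) {
    if (sizes[q] == 0) next
    lab[df$i[pos:(pos + sizes[q] - 1)]] <- q
    pos <- pos + sizes[q]
  }
  lab
}

# Brute-force pooled mean: explicit voxel loop accumulating sum and count.
oracle_pooled_mean <- function(values, valid, index_list) {
  s <- 0; n <- 0L
  for (i in index_list) {
    if (valid[i]) { s <- s + values[i]; n <- n + 1L }
  }
  if (n == 0L) return(NA_real_)
  s / n
}

# Small noisy cohort for model tests (shared sizes keep tests quick).
small_cohort_table <- function(n = c(5, 5, 5), seed = 1,
                               profiles = default_profiles()) {
  co <- simulate_cohort(n[1], n[2], n[3], profiles = profiles,
                        grid_shape = c(32, 56), semi_axes = c(10, 5),
                        seed = seed)
  cohort_analysis_table(co)
}
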