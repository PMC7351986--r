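test_that("metadata generator reproduces requested group sizes and bands", {
  meta <- generate_metadata(10, 26, 25, seed = 1)
  expect_equal(nrow(meta), 61)
  expect_equal(as.vector(table(meta$group)[c("severe", "mild", "recovered")]),
               c(10L, 26L, 25L))
  # NDI values land in the group bands and re-classify identically
  expect_identical(assign_group(meta$ndi_percent), meta$group)
  expect_true(all(meta$age >= 18 & meta$age <= 65))
  expect_true(all(meta$bmi > 0))
  expect_true(all(meta$ndi_percent >= 0 & meta$ndi_percent <= 100))
  # single recovered participant has NDI < 10
  one <- generate_metadata(0, 0, 1, seed = 7)
  expect_equal(nrow(one), 1)
  expect_lt(one$ndi_percent, 10)
  # determinism
  expect_identical(meta, generate_metadata(10, 26, 25, seed = 1))
  expect_false(identical(meta$ndi_percent,
                         generate_metadata(10, 26, 25, seed = 2)$ndi_percent))
})

test_that("overlapping NDI bands are a configuration error", {
  bands <- default_ndi_bands()
  bands$mild <- c(5, 35)
  expect_error(generate_metadata(1, 1, 1, ndi_bands = bands, seed = 1),
               class = "mfigeo_config_error")
})

test_that("mask slices respect side convention, mirror symmetry and degeneracy", {
  roi_r <- generate_mask_slice(c(40, 130), "right", c(20, 8), 64)
  idx_r <- which(roi_r, arr.ind = TRUE)
  expect_true(all(idx_r[, 2] > 64))
  roi_l <- generate_mask_slice(c(40, 130), "left", c(20, 8), 64)
  idx_l <- which(roi_l, arr.ind = TRUE)
  expect_true(all(idx_l[, 2] < 64))
  expect_equal(sum(roi_r), sum(roi_l))
  # mirrored column sets
  expect_setequal(2L * 64L - unique(idx_r[, 2]), unique(idx_l[, 2]))
  # degenerate semi-axes still produce a non-empty connected ROI
  tiny <- generate_mask_slice(c(11, 21), "right", c(1, 1), 10)
  expect_gte(sum(tiny), 1)
  # ellipse that cannot fit is a generation-time error
  expect_error(generate_mask_slice(c(10, 20), "right", c(15, 3), 10),
               class = "mfigeo_config_error")
})

test_that("noise-free generation inverts the MFI formula exactly", {
  p <- default_profiles(participant_sd = 0, slope_sd = 0, voxel_noise_sd = 0)
  co <- simulate_cohort(1, 1, 1, profiles = p, grid_shape = c(32, 56),
                        semi_axes = c(10, 5), seed = 2)
  tab <- cohort_analysis_table(co)
  m <- merge(tab, co$truth, by = c("id", "level", "quartile"))
  expect_equal(m$mfi, m$true_mfi, tolerance = 1e-12)
  # and the recovered-group C6 profile is the configured means
  pm <- p$means[p$means$group == "recovered" & p$means$level == "C6", ]
  got <- m[m$group == "recovered" & m$level == "C6", ]
  expect_equal(got$mfi[order(got$quartile)],
               as.numeric(pm[, c("Q1", "Q2", "Q3", "Q4")]))
})

test_that("noisy per-quartile mean is within Monte-Carlo error of target", {
  # one participant, no random effects; >= 1e4 voxels per quartile
  p <- default_profiles(participant_sd = 0, slope_sd = 0, voxel_noise_sd = 30)
  mask <- build_cohort_mask(grid_shape = c(160, 250), slices_per_level = 3,
                            semi_axes = c(60, 40))
  meta <- generate_metadata(1, 0, 0, seed = 3)
  gen <- generate_fatwater(meta, p, mask, seed = 3)
  qm <- gen$qmap
  v <- gen$volumes[[1]]
  m <- compute_mfi_map(v)
  cache <- quartile_indices(qm, mask)
  for (q in 1:4) {
    idx <- c(cache$C4[[q]]$left, cache$C4[[q]]$right)
    expect_gte(length(idx), 1e4)
    vals <- m$values[idx]
    target <- gen$truth$true_mfi[gen$truth$level == "C4" &
                                   gen$truth$quartile == q]
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - target), 3 * se + 0.05)
  }
})

test_that("generation is deterministic and participant-order independent", {
  p <- default_profiles()
  mask <- build_cohort_mask(grid_shape = c(32, 56), semi_axes = c(10, 5))
  meta <- generate_metadata(1, 1, 1, seed = 9)
  g1 <- generate_fatwater(meta, p, mask, seed = 9)
  g2 <- generate_fatwater(meta, p, mask, seed = 9)
  expect_identical(g1$volumes$P001$fat, g2$volumes$P001$fat)
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(g1$volumes$P001$fat,
                         generate_fatwater(meta, p, mask, seed = 10)$volumes$P001$fat))
})

test_that("calibrated defaults reproduce the medial-concentration geography", {
  meta <- generate_metadata(10, 26, 25, seed = 21)
  p <- default_profiles()
  # assertable on ground truth directly: per-group mean over participants
  mask <- build_cohort_mask(grid_shape = c(32, 56), semi_axes = c(10, 5))
  truth <- generate_fatwater(meta, p, mask, seed = 21)$truth
  truth <- merge(truth, meta[, c("id", "group")], by = "id")
  gm <- aggregate(true_mfi ~ group + quartile, data = truth, FUN = mean)
  for (g in levels(gm$group)) {
    prof <- gm$true_mfi[gm$group == g][order(gm$quartile[gm$group == g])]
    expect_true(all(prof[1] > prof[2:4]))
  }
  # symptomatic groups exceed recovered in Q1, not in Q3/Q4
  q1 <- gm[gm$quartile == 1, ]
  expect_gt(q1$true_mfi[q1$group == "severe"], q1$true_mfi[q1$group == "recovered"])
  expect_gt(q1$true_mfi[q1$group == "mild"], q1$true_mfi[q1$group == "recovered"])
  pm <- p$means
  for (q in c("Q3", "Q4")) {
    expect_true(all(tapply(pm[[q]], pm$group, unique) ==
                      pm[[q]][pm$group == "recovered"][1]))
  }
})

test_that("profile validation enforces geography and positivity", {
  bad <- default_profiles()$means
  bad$Q2[1] <- bad$Q1[1] + 1  # violates Q1 > Q2
  expect_error(quartile_profiles(bad), class = "mfigeo_config_error")
  expect_error(default_profiles(participant_sd = -1),
               class = "mfigeo_config_error")
  expect_error(default_profiles(water_reference = 0),
               class = "mfigeo_config_error")
})
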