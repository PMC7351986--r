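test_that("noiseless tables are recovered exactly by the mixed model", {
  p <- default_profiles(participant_sd = 0, slope_sd = 0, voxel_noise_sd = 0)
  co <- simulate_cohort(3, 3, 3, profiles = p, grid_shape = c(32, 56),
                        semi_axes = c(10, 5), seed = 2)
  tab <- cohort_analysis_table(co)
  f <- fit_level_model(tab[tab$level == "C4", ])
  # (the optimizer may grumble at the degenerate zero-residual problem;
  # the estimates below are still exact, which is what matters here)
  expect_false(is.null(f$fit))
  # residual variance collapses to zero
  resid_var <- f$varcomp$vcov[f$varcomp$grp == "Residual"]
  expect_lt(resid_var, 1e-12)
  # model-implied cell means equal the generating profile means
  emm <- summary(emmeans::emmeans(f$fit, ~ group * quartile_f,
                                  lmer.df = "asymptotic"))
  pm <- p$means[p$means$level == "C4", ]
  for (i in seq_len(nrow(emm))) {
    g <- as.character(emm$group[i])
    q <- as.character(emm$quartile_f[i])
    expect_equal(emm$emmean[i], pm[pm$group == g, q][[1]], tolerance = 1e-8)
  }
})

test_that("with zero random-effect SDs the fit matches the OLS oracle", {
  # With no true between-participant variance the REML estimates of the
  # random-effect variances land exactly on the zero boundary in a
  # sizeable fraction of datasets; those fits are plain OLS. Datasets
  # where chance clustering keeps the estimates interior still satisfy
  # the balanced-design identity: within-participant terms (quartile and
  # group:quartile) are invariant to the random-effect weighting.
  p <- default_profiles(participant_sd = 0, slope_sd = 0, voxel_noise_sd = 60)
  within_terms <- function(b) b[grepl("quartile_f", names(b))]
  n_boundary <- 0L
  for (s in 1:6) {
    co <- simulate_cohort(4, 4, 4, profiles = p, grid_shape = c(32, 56),
                          semi_axes = c(10, 5), seed = s)
    tab <- cohort_analysis_table(co)
    f <- fit_level_model(tab[tab$level == "C4", ])
    ols <- lm(mfi ~ group * quartile_f + age_c + sex + bmi_c, data = f$data)
    b_mixed <- lme4::fixef(f$fit); b_ols <- coef(ols)
    vc <- f$varcomp
    re_var <- vc$vcov[vc$grp == "id" & is.na(vc$var2)]
    if (all(re_var < 1e-10)) {
      n_boundary <- n_boundary + 1L
      expect_equal(unname(b_mixed), unname(b_ols), tolerance = 1e-6)
    }
    expect_equal(unname(within_terms(b_mixed)), unname(within_terms(b_ols)),
                 tolerance = 1e-6)
  }
  expect_gte(n_boundary, 1L)
})

test_that("variance components are recovered on a large simulated cohort", {
  p <- default_profiles(participant_sd = 4, slope_sd = 1, voxel_noise_sd = 20)
  co <- simulate_cohort(66, 67, 67, profiles = p, grid_shape = c(32, 56),
                        semi_axes = c(10, 5), seed = 13)
  tab <- cohort_analysis_table(co)
  f <- fit_level_model(tab[tab$level == "C5", ])
  vc <- f$varcomp
  sd_int <- vc$sdcor[vc$grp == "id" & vc$var1 == "(Intercept)" & is.na(vc$var2)]
  sd_slope <- vc$sdcor[vc$grp == "id" & vc$var1 == "quart_num" & is.na(vc$var2)]
  expect_lt(abs(sd_int - 4) / 4, 0.20)
  expect_lt(abs(sd_slope - 1) / 1, 0.20)
})

test_that("adding a constant shifts only the intercept", {
  tab <- small_cohort_table(seed = 17)
  tab_c4 <- tab[tab$level == "C4", ]
  f1 <- fit_level_model(tab_c4)
  shifted <- tab_c4
  shifted$mfi <- shifted$mfi + 7.5
  f2 <- fit_level_model(shifted)
  b1 <- lme4::fixef(f1$fit); b2 <- lme4::fixef(f2$fit)
  expect_equal(unname(b2["(Intercept)"] - b1["(Intercept)"]), 7.5,
               tolerance = 1e-6)
  expect_equal(unname(b2[-1]), unname(b1[-1]), tolerance = 1e-6)
  c1 <- pairwise_quartile_contrasts(f1)
  c2 <- pairwise_quartile_contrasts(f2)
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-6)
  expect_equal(c1$p, c2$p, tolerance = 1e-6)
})

test_that("contrast table is complete, consistent and respects adjustment", {
  tab <- small_cohort_table(seed = 23)
  f <- fit_level_model(tab[tab$level == "C5", ])
  ct <- pairwise_quartile_contrasts(f)
  expect_equal(nrow(ct), 12L)  # 3 contrasts x 4 quartiles
  expect_true(all(ct$p >= 0 & ct$p <= 1))
  expect_setequal(unique(ct$contrast),
                  c("mild-recovered", "severe-recovered", "severe-mild"))
  # linearity: severe-recovered = severe-mild + mild-recovered, exactly
  for (q in 1:4) {
    cc <- ct[ct$quartile == q, ]
    expect_equal(cc$estimate[cc$contrast == "severe-recovered"],
                 cc$estimate[cc$contrast == "severe-mild"] +
                   cc$estimate[cc$contrast == "mild-recovered"],
                 tolerance = 1e-8)
  }
  # Bonferroni multiplies the within-quartile family of 3 by 3, capped at 1
  fb <- fit_level_model(tab[tab$level == "C5", ],
                        model_spec(adjust = "bonferroni"))
  cb <- pairwise_quartile_contrasts(fb)
  expect_equal(cb$p, pmin(1, 3 * ct$p), tolerance = 1e-10)
})

test_that("non-converged fits yield an empty, flagged contrast table", {
  stub <- structure(list(level = "C4", fit = NULL, spec = model_spec(),
                         converged = FALSE, singular = NA),
                    class = "mfi_level_fit")
  ct <- pairwise_quartile_contrasts(stub)
  expect_equal(nrow(ct), 0L)
  expect_false(attr(ct, "converged"))
})

test_that("run_all_levels fits each level once and summarizes significance", {
  tab <- small_cohort_table(seed = 29)
  res <- run_all_levels(tab)
  expect_named(res$fits, c("C4", "C5", "C6", "C7"))
  expect_equal(nrow(res$contrasts), 48L)
  expect_equal(nrow(res$summary), 48L)
  # single-level table -> one result
  res1 <- run_all_levels(tab[tab$level == "C6", ])
  expect_named(res1$fits, "C6")
  expect_equal(nrow(res1$contrasts), 12L)
  # summary marks exactly the contrasts below alpha
  expect_identical(res$summary$significant,
                   res$contrasts$p < res$spec$alpha)
})

test_that("model input validation rejects unusable tables", {
  tab <- small_cohort_table(seed = 31)
  expect_error(fit_level_model(tab), class = "mfigeo_input_error")  # >1 level
  one_group <- tab[tab$level == "C4" & tab$group == "mild", ]
  expect_error(fit_level_model(one_group), class = "mfigeo_input_error")
})
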