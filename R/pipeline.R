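#' Run the image stages for a whole cohort
#'
#' Computes the MFI map for every participant volume, partitions the
#' shared mask into quartiles (reused across participants), aggregates
#' per level x quartile, and joins the metadata into the long analysis
#' table.
#'
#' @param cohort a \code{synthetic_cohort} (or any list with
#'   \code{volumes}, \code{mask}, \code{participants}).
#' @param bilateral \code{"pool"} or \code{"side-mean"}, see
#'   [quartile_level_mfi()].
#' @param rule quartile rule, see [partition_quartiles()].
#' @return long analysis table, see [build_analysis_table()].
#' @export
cohort_analysis_table <- function(cohort, bilateral = c("pool", "side-mean"),
                                  rule = c("area", "width")) {
  bilateral <- match.arg(bilateral)
  rule <- match.arg(rule)
  qmap <- if (rule == "area" && !is.null(cohort$qmap)) cohort$qmap else
    partition_volume(cohort$mask, rule = rule)
  cache <- quartile_indices(qmap, cohort$mask)
  recs <- lapply(names(cohort$volumes), function(id) {
    map <- compute_mfi_map(cohort$volumes[[id]])
    r <- quartile_level_mfi(map, qmap, cohort$mask, bilateral = bilateral,
                            cache = cache)
    if (nrow(r)) r$id <- id
    r
  })
  build_analysis_table(do.call(rbind, recs), cohort$participants)
}

#' Operating characteristics of the pipeline by simulation
#'
#' Repeatedly simulates a cohort, runs the full image-and-model pipeline,
#' and records which intra-quartile group contrasts reject at the spec's
#' alpha. With null profiles this estimates the type-I error of each
#' contrast; with effect-carrying profiles, its power. The Monte-Carlo
#' standard error of each rejection rate is reported.
#'
#' @param n_severe,n_mild,n_recovered per-group cohort sizes.
#' @param profiles a \code{quartile_profiles} ([default_profiles()] or
#'   [null_profiles()]).
#' @param levels cervical levels to fit (default all four; fitting a
#'   single level quarters the cost when one rate is of interest).
#' @param n_reps number of simulation replicates (>= 1).
#' @param seed integer seed; replicate r uses a seed derived from
#'   (\code{seed}, r).
#' @param spec a [model_spec()].
#' @param grid_shape,slices_per_level,semi_axes mask geometry, see
#'   [build_cohort_mask()].
#' @return object of class \code{mfi_oc_study}: \code{rates} (data frame
#'   level x quartile x contrast -> \code{reject_rate}, \code{mc_se},
#'   \code{n_reps_used}), \code{q1_top} (per-group fraction of
#'   replicates in which Q1 had the highest observed group-mean MFI),
#'   \code{n_failed} (replicates with non-converged fits, excluded from
#'   the affected rates).
#' @export
power_typeI_study <- function(n_severe, n_mild, n_recovered,
                              profiles = default_profiles(),
                              levels = CERVICAL_LEVELS,
                              n_reps = 100, seed = 1L,
                              spec = model_spec(),
                              grid_shape = c(48, 80), slices_per_level = 3,
                              semi_axes = c(14, 6)) {
  stopifnot(n_reps >= 1)
  levels <- match.arg(levels, CERVICAL_LEVELS, several.ok = TRUE)
  mask <- build_cohort_mask(grid_shape, slices_per_level, semi_axes)
  rejections <- list(); q1_top <- list(); n_failed <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- as.integer((as.numeric(seed) + 7919 * r) %% 2147483647)
    meta <- generate_metadata(n_severe, n_mild, n_recovered, seed = rep_seed)
    gen <- generate_fatwater(meta, profiles, mask, seed = rep_seed)
    tab <- cohort_analysis_table(gen)
    tab_lv <- tab[as.character(tab$level) %in% levels, , drop = FALSE]
    res <- run_all_levels(tab_lv, spec)
    ok <- vapply(res$fits, function(f) isTRUE(f$converged), logical(1))
    if (!all(ok)) n_failed <- n_failed + 1L
    if (nrow(res$contrasts)) {
      s <- res$contrasts[, c("level", "quartile", "contrast", "significant")]
      s$rep <- r
      rejections[[length(rejections) + 1L]] <- s
    }
    # observed group-mean MFI per quartile (pooled over levels fitted)
    gm <- stats::aggregate(mfi ~ group + quartile, data = tab_lv, FUN = mean)
    top <- vapply(split(gm, gm$group), function(g) {
      g$quartile[which.max(g$mfi)] == 1
    }, logical(1))
    q1_top[[r]] <- top
  }
  rej <- do.call(rbind, rejections)
  rates <- stats::aggregate(significant ~ level + quartile + contrast,
                            data = rej, FUN = mean)
  names(rates)[names(rates) == "significant"] <- "reject_rate"
  nre <- stats::aggregate(significant ~ level + quartile + contrast,
                          data = rej, FUN = length)
  rates$n_reps_used <- nre$significant
  rates$mc_se <- sqrt(rates$reject_rate * (1 - rates$reject_rate) /
                        rates$n_reps_used)
  q1m <- do.call(rbind, q1_top)
  structure(list(rates = rates,
                 q1_top = colMeans(q1m),
                 n_failed = n_failed, n_reps = n_reps, seed = seed,
                 levels = levels, spec = spec),
            class = "mfi_oc_study")
}

#' @export
print.mfi_oc_study <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d replicates (%d with fit issues)\n",
              x$n_reps, x$n_failed))
  cat("Fraction of replicates with Q1 the highest-MFI quartile, per group:\n")
  print(round(x$q1_top, 3))
  cat("Rejection rates (head):\n")
  print(utils::head(x$rates[order(-x$rates$reject_rate), ], 12), row.names = FALSE)
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Drives simulate (optional) -> MFI maps -> quartiles -> aggregation ->
#' per-level mixed models, writing the analysis table (CSV), per-level
#' results (JSON), a plain-text contrast report, and a manifest carrying
#' the seed and a hash of the effective configuration. Rerunning with
#' the same config and seed reproduces all numeric outputs.
#'
#' @param config list; either \code{simulate = list(...)} (arguments to
#'   [simulate_cohort()]) or \code{paths = list(fat=, water=, mask=,
#'   annotations=, metadata=)} naming input files per participant;
#'   optional \code{bilateral}, \code{rule}, \code{spec}, \code{seed}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the analysis table, model results and
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  spec <- config$spec %||% model_spec()
  bilateral <- config$bilateral %||% "pool"
  rule <- config$rule %||% "area"
  if (!is.null(config$simulate)) {
    cohort <- do.call(simulate_cohort, c(config$simulate, list(seed = seed)))
  } else if (!is.null(config$paths)) {
    cohort <- read_cohort(config$paths)
  } else {
    mfigeo_stop("mfigeo_config_error",
                "config must provide either $simulate or $paths")
  }
  tab <- cohort_analysis_table(cohort, bilateral = bilateral, rule = rule)
  csv_path <- file.path(out_dir, "analysis_table.csv")
  write.csv(tab, csv_path, row.names = FALSE)
  res <- run_all_levels(tab, spec)
  res_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(list(
    levels = lapply(res$fits, function(f) list(
      level = f$level, converged = f$converged, singular = f$singular,
      interaction = f$interaction,
      fixed = f$fixed, varcomp = f$varcomp)),
    contrasts = res$contrasts), res_path, auto_unbox = TRUE, digits = NA,
    na = "null")
  rep_path <- file.path(out_dir, "report.txt")
  writeLines(format_report(res), rep_path)
  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = basename(c(csv_path, res_path, rep_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(table = tab, results = res, manifest = manifest))
}

#' @noRd
format_report <- function(res) {
  out <- c(sprintf("Intra-quartile group contrasts (alpha = %g, adjust = %s)",
                   res$spec$alpha, res$spec$adjust), "")
  for (lv in names(res$fits)) {
    f <- res$fits[[lv]]
    out <- c(out, sprintf("Level %s%s:", lv,
                          if (isTRUE(f$converged)) "" else " [not converged]"))
    cc <- res$contrasts[res$contrasts$level == lv, , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      out <- c(out, sprintf("  Q%d %-16s %+7.2f (SE %.2f)  p = %.4f%s",
                            cc$quartile[i], cc$contrast[i], cc$estimate[i],
                            cc$se[i], cc$p[i],
                            if (cc$significant[i]) " *" else ""))
    }
    out <- c(out, "")
  }
  out
}

#' @noRd
config_hash <- function(config) {
  js <- jsonlite::toJSON(config[setdiff(names(config), "spec")],
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  fnv1a32(as.character(js))
}

# FNV-1a 32-bit hash of a string; tiny, dependency-free fingerprint for
# manifests (not cryptographic).
#' @noRd
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime, split to stay below 2^53
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
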