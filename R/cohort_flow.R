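#' Assign whiplash recovery group from a Neck Disability Index score
#'
#' Classifies participants into recovery groups from their 12-month Neck
#' Disability Index (NDI) percentage: \code{severe} for NDI >= 30,
#' \code{mild} for 10 <= NDI < 30, and \code{recovered} for NDI < 10.
#' The mild band is read as the half-open interval [10, 30) so that the
#' three bands tile [0, 100] with no gap at non-integer scores.
#'
#' @param ndi_percent numeric vector of NDI scores on the 0-100 scale.
#' @return factor with levels \code{recovered < mild < severe}
#'   (\code{recovered} first, so it is the reference in models).
#' @examples
#' assign_group(c(31.8, 19.5, 6.1, 10, 30, 9.999))
#' @export
assign_group <- function(ndi_percent) {
  if (!is.numeric(ndi_percent) || anyNA(ndi_percent)) {
    mfigeo_stop("mfigeo_input_error", "ndi_percent must be numeric and non-missing")
  }
  if (any(ndi_percent < 0 | ndi_percent > 100)) {
    mfigeo_stop("mfigeo_input_error",
                "NDI scores must lie in [0, 100]; got values outside range")
  }
  out <- ifelse(ndi_percent >= 30, "severe",
         ifelse(ndi_percent >= 10, "mild", "recovered"))
  factor(out, levels = GROUP_LEVELS)
}

#' Participant-flow accounting from per-participant flags
#'
#' Reproduces the sub-study's participant flow: of the enrolled cohort,
#' those lost to attrition never return for the 12-month scan; of the
#' returnees, scans of poor quality, and scans otherwise not amenable to
#' quartile segmentation in the transverse plane, are excluded.
#'
#' @param flags data frame with one row per enrolled participant and
#'   logical columns \code{returned}, \code{scan_quality_ok},
#'   \code{quartile_amenable}. The two scan flags must be \code{NA} for
#'   participants who did not return (no scan exists to rate) and
#'   non-missing for returnees; any other combination is a validation
#'   error.
#' @return list with components \code{included} (integer row indices of
#'   included participants) and \code{counts}, a \code{flow_counts} list
#'   of \code{enrolled}, \code{lost_to_attrition}, \code{returned_12mo},
#'   \code{excluded_poor_quality}, \code{excluded_not_amenable},
#'   \code{included}.
#' @seealso [flow_flags()] to build the flag table from aggregate counts.
#' @export
apply_flow <- function(flags) {
  req <- c("returned", "scan_quality_ok", "quartile_amenable")
  if (!is.data.frame(flags) || !all(req %in% names(flags))) {
    mfigeo_stop("mfigeo_input_error",
                "flags must be a data frame with columns %s",
                paste(req, collapse = ", "))
  }
  if (anyNA(flags$returned)) {
    mfigeo_stop("mfigeo_validation_error", "returned flag must be non-missing")
  }
  nr <- !flags$returned
  if (any(nr & (!is.na(flags$scan_quality_ok) | !is.na(flags$quartile_amenable)))) {
    mfigeo_stop("mfigeo_validation_error",
                "scan flags present for participants who did not return")
  }
  if (anyNA(flags$scan_quality_ok[flags$returned])) {
    mfigeo_stop("mfigeo_validation_error",
                "scan quality flag missing for returned participants")
  }
  # Poor quality is assessed first; amenability only among usable scans.
  poor <- flags$returned & !flags$scan_quality_ok
  usable <- flags$returned & flags$scan_quality_ok
  if (anyNA(flags$quartile_amenable[usable])) {
    mfigeo_stop("mfigeo_validation_error",
                "amenability flag missing for usable returned scans")
  }
  not_amen <- usable & !flags$quartile_amenable
  inc <- usable & flags$quartile_amenable
  counts <- structure(list(
    enrolled = nrow(flags),
    lost_to_attrition = sum(nr),
    returned_12mo = sum(flags$returned),
    excluded_poor_quality = sum(poor),
    excluded_not_amenable = sum(not_amen),
    included = sum(inc)
  ), class = "flow_counts")
  stopifnot(counts$returned_12mo == counts$enrolled - counts$lost_to_attrition,
            counts$included == counts$returned_12mo -
              counts$excluded_poor_quality - counts$excluded_not_amenable)
  list(included = which(inc), counts = counts)
}

#' Build a per-participant flag table from aggregate flow counts
#'
#' Convenience constructor for [apply_flow()] when only the aggregate
#' counts are known (e.g. when auditing a published flow diagram).
#'
#' @param enrolled total enrolled in the parent study.
#' @param lost_to_attrition number not returning at 12 months.
#' @param excluded_poor_quality returnees excluded for poor scan quality.
#' @param excluded_not_amenable returnees whose imaging was not amenable
#'   to quartile segmentation.
#' @return data frame of flags suitable for [apply_flow()].
#' @examples
#' fl <- flow_flags(97, 19, 1, 16)
#' apply_flow(fl)$counts
#' @export
flow_flags <- function(enrolled, lost_to_attrition,
                       excluded_poor_quality, excluded_not_amenable) {
  n_ret <- enrolled - lost_to_attrition
  n_inc <- n_ret - excluded_poor_quality - excluded_not_amenable
  if (min(enrolled, lost_to_attrition, excluded_poor_quality,
          excluded_not_amenable, n_ret, n_inc) < 0) {
    mfigeo_stop("mfigeo_input_error", "flow counts must be non-negative and nested")
  }
  returned <- rep(c(FALSE, TRUE), c(lost_to_attrition, n_ret))
  quality <- c(rep(NA, lost_to_attrition),
               rep(c(FALSE, TRUE), c(excluded_poor_quality,
                                     n_ret - excluded_poor_quality)))
  amen <- c(rep(NA, lost_to_attrition), rep(NA, excluded_poor_quality),
            rep(c(FALSE, TRUE), c(excluded_not_amenable, n_inc)))
  # amenability is NA where quality already failed (not assessed)
  data.frame(returned = returned, scan_quality_ok = quality,
             quartile_amenable = amen)
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("Participant flow:\n")
  cat(sprintf("  enrolled            %4d\n", x$enrolled))
  cat(sprintf("  lost to attrition   %4d\n", x$lost_to_attrition))
  cat(sprintf("  returned at 12 mo   %4d\n", x$returned_12mo))
  cat(sprintf("  excl. poor quality  %4d\n", x$excluded_poor_quality))
  cat(sprintf("  excl. not amenable  %4d\n", x$excluded_not_amenable))
  cat(sprintf("  included            %4d\n", x$included))
  invisible(x)
}
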