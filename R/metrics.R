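#' Classify stimuli as scotomatous
#'
#' A stimulus is scotomatous when the device recorded the -1 dB raw value
#' (brightest stimulus not seen) or its mapped sensitivity is below 0 dB.
#' The inequality is strict: 0 dB seen is not scotomatous.
#'
#' @param sensitivity_db numeric vector of sensitivities in dB.
#' @param raw_not_seen logical vector (or 0/1) of raw not-seen flags.
#' @return Logical vector.
#' @export
classify_scotomatous <- function(sensitivity_db, raw_not_seen) {
  raw_not_seen <- as.logical(raw_not_seen)
  stopifnot(length(sensitivity_db) == length(raw_not_seen))
  raw_not_seen | sensitivity_db < 0
}

#' Zone-restricted visual-function metrics for one eye
#'
#' Computes the mean sensitivity and scotomatous-point count over the
#' stimuli whose signed stimulus-to-margin distance falls inside the zone.
#'
#' Averaging of not-seen stimuli is configurable, because devices record
#' them with a -1 dB sentinel that is not a measured threshold:
#' `"floor_zero"` (default) maps the sentinel to 0 dB for averaging,
#' `"as_recorded"` averages the -1 dB value, `"exclude"` drops not-seen
#' stimuli from the mean (but never from the scotomatous count). The
#' convention used is recorded in the result.
#'
#' @param exam an [mp_exam].
#' @param distances data.frame from [signed_distance()] covering every
#'   stimulus of the exam.
#' @param zone a [zone_spec].
#' @param sentinel_policy how not-seen stimuli enter the mean sensitivity.
#' @return An object of class `zone_metrics`: `eye_id`, `zone`,
#'   `n_in_zone`, `mean_sensitivity_db` (`NA` with `empty_zone = TRUE` when
#'   no stimulus is in the zone), `n_scotomatous_in_zone`,
#'   `sentinel_policy`, and a `per_stimulus` data.frame (`stimulus_id`,
#'   `distance_um`, `in_zone`, `scotomatous`, `sensitivity_db`).
#' @export
zone_metrics <- function(exam, distances, zone = zone_spec("junctional"),
                         sentinel_policy = c("floor_zero", "as_recorded",
                                             "exclude")) {
  stopifnot(inherits(exam, "mp_exam"), inherits(zone, "zone_spec"))
  sentinel_policy <- match.arg(sentinel_policy)
  s <- exam$stimuli
  idx <- match(s$stimulus_id, distances$stimulus_id)
  if (anyNA(idx))
    stop("'distances' must cover every stimulus_id in the exam",
         call. = FALSE)
  d <- distances$distance_um[idx]
  in_zone <- zone_membership(d, zone)
  scot <- classify_scotomatous(s$sensitivity_db, s$raw_not_seen)
  sens <- s$sensitivity_db
  averaged <- switch(sentinel_policy,
                     floor_zero = ifelse(s$raw_not_seen, 0, sens),
                     as_recorded = sens,
                     exclude = ifelse(s$raw_not_seen, NA_real_, sens))
  n_in <- sum(in_zone)
  mean_sens <- if (n_in > 0L) mean(averaged[in_zone], na.rm = TRUE)
               else NA_real_
  if (is.nan(mean_sens)) mean_sens <- NA_real_  # all in-zone excluded
  structure(
    list(eye_id = exam$eye_id,
         zone = zone,
         n_in_zone = n_in,
         mean_sensitivity_db = mean_sens,
         n_scotomatous_in_zone = sum(scot & in_zone),
         empty_zone = n_in == 0L,
         sentinel_policy = sentinel_policy,
         per_stimulus = data.frame(stimulus_id = s$stimulus_id,
                                   distance_um = d,
                                   in_zone = in_zone,
                                   scotomatous = scot,
                                   sensitivity_db = sens)),
    class = "zone_metrics")
}

#' @export
print.zone_metrics <- function(x, ...) {
  cat(sprintf("zone metrics: eye %s, %s zone [%g, %g] um\n", x$eye_id,
              x$zone$kind, x$zone$inner_limit_um, x$zone$outer_limit_um))
  if (x$empty_zone) {
    cat("  empty zone: no stimulus within bounds; metrics undefined\n")
  } else {
    cat(sprintf("  n in zone: %d, mean sensitivity: %.2f dB (%s), scotomatous: %d\n",
                x$n_in_zone, x$mean_sensitivity_db, x$sentinel_policy,
                x$n_scotomatous_in_zone))
  }
  invisible(x)
}

#' Per-stimulus coordinate differences between two graders' registrations
#'
#' Euclidean distance between corresponding stimulus positions after each
#' grader's transform into the FAF frame, in micrometers, plus the per-eye
#' mean and standard deviation of those distances. Correspondence is by
#' position in the matrices (the same exam transformed twice), never by
#' nearest-neighbor matching.
#'
#' @param p1_um,p2_um n x 2 matrices of the same stimuli transformed by
#'   grader 1 and grader 2, in FAF-frame micrometers.
#' @return List with `per_stimulus_um` (length-n vector), `mean_um`,
#'   `sd_um`, `n`.
#' @export
coordinate_differences <- function(p1_um, p2_um) {
  p1 <- as_xy(p1_um, "p1_um"); p2 <- as_xy(p2_um, "p2_um")
  if (nrow(p1) != nrow(p2))
    stop("grader point sets must have the same number of stimuli",
         call. = FALSE)
  d <- sqrt(rowSums((p1 - p2)^2))
  list(per_stimulus_um = d, mean_um = mean(d), sd_um = stats::sd(d),
       n = length(d))
}
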