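#' Analyze one eye: register, measure distances, compute zone metrics
#'
#' The per-eye workflow: fit the similarity transform from the grader's
#' fiducial pairs, transform the MP stimulus centers (fovea-centered
#' degrees -> SLO pixels -> FAF pixels -> micrometers), compute the signed
#' stimulus-to-margin distance for every stimulus, and summarize the
#' requested zone.
#'
#' @param exam an [mp_exam].
#' @param tracing a [lesion_tracing] in FAF-frame micrometers.
#' @param fiducials the grader's [fiducial_set] (SLO pixels -> FAF pixels),
#'   or an already-fitted [similarity_transform].
#' @param faf_frame the FAF [image_frame].
#' @param zone a [zone_spec].
#' @param sentinel_policy averaging convention for not-seen stimuli, see
#'   [zone_metrics()].
#' @return A list of class `eye_analysis`: `eye_id`, `grader_id`,
#'   `transform`, `stimulus_faf_um`, `distances`, `metrics`.
#' @export
analyze_exam <- function(exam, tracing, fiducials, faf_frame,
                         zone = zone_spec("junctional"),
                         sentinel_policy = "floor_zero") {
  stopifnot(inherits(exam, "mp_exam"), inherits(tracing, "lesion_tracing"),
            inherits(faf_frame, "image_frame"))
  grader_id <- NA
  if (inherits(fiducials, "fiducial_set")) {
    grader_id <- fiducials$grader_id
    transform <- fit_similarity(fiducials)
  } else if (inherits(fiducials, "similarity_transform")) {
    transform <- fiducials
  } else {
    stop("'fiducials' must be a fiducial_set or a similarity_transform",
         call. = FALSE)
  }
  slo_px <- degrees_to_slo_pixels(
    as.matrix(exam$stimuli[c("x_deg", "y_deg")]), exam$slo_frame)
  faf_um <- apply_transform(transform, slo_px) * um_per_pixel(faf_frame)
  distances <- signed_distance(faf_um, tracing,
                               stimulus_id = exam$stimuli$stimulus_id)
  metrics <- zone_metrics(exam, distances, zone,
                          sentinel_policy = sentinel_policy)
  structure(list(eye_id = exam$eye_id, grader_id = grader_id,
                 transform = transform, stimulus_faf_um = faf_um,
                 distances = distances, metrics = metrics),
            class = "eye_analysis")
}

#' @export
print.eye_analysis <- function(x, ...) {
  cat(sprintf("eye analysis: eye %s, grader %s (fit RMSE %.3g px)\n",
              x$eye_id, x$grader_id,
              if (is.null(x$transform$rmse)) NA else x$transform$rmse))
  print(x$metrics)
  invisible(x)
}

#' Inter-grader agreement battery over a study
#'
#' Runs both graders' analyses for every eye of a (simulated or assembled)
#' study and computes the full repeatability battery:
#' \itemize{
#'   \item eye-level mean zone sensitivity: Bland-Altman + ICC + CoR;
#'   \item eye-level scotomatous-point count in the zone: same battery;
#'   \item stimulus-level signed margin distances (all stimuli, 68 per
#'     eye): same battery plus the repeated-measures Bland-Altman variant
#'     with eye as the cluster;
#'   \item stimulus coordinate differences between the two graders'
#'     transforms, summarized per eye (mean, SD) and overall.
#' }
#' Eyes whose zone is empty under either grader are excluded from the
#' eye-level comparisons and listed in `excluded_eyes`.
#'
#' @param study a `ga_study` from [simulate_study()], or any list with the
#'   same shape (`config` with `faf_frame`, and `eyes` each carrying `exam`,
#'   `tracing`, `fiducials`).
#' @param zone a [zone_spec].
#' @param sentinel_policy averaging convention for not-seen stimuli.
#' @return A list of class `grader_agreement` with components
#'   `mean_sensitivity`, `scotomatous_count`, `margin_distance`
#'   ([repeatability_report]s), `coordinate_difference` (per-eye
#'   data.frame plus overall mean/SD), `per_eye` (data.frame of eye-level
#'   metrics for both graders), `excluded_eyes`, `zone`,
#'   `sentinel_policy`, `um_per_degree`.
#' @export
grader_agreement <- function(study, zone = zone_spec("junctional"),
                             sentinel_policy = "floor_zero") {
  stopifnot(inherits(study, "ga_study") || is.list(study))
  faf <- study$config$faf_frame
  n_eye <- length(study$eyes)
  per_eye <- vector("list", n_eye)
  coord <- vector("list", n_eye)
  coord_all <- list()
  dist1 <- list(); dist2 <- list(); dist_cluster <- list()
  for (i in seq_len(n_eye)) {
    eye <- study$eyes[[i]]
    a1 <- analyze_exam(eye$exam, eye$tracing, eye$fiducials[[1L]], faf,
                       zone, sentinel_policy)
    a2 <- analyze_exam(eye$exam, eye$tracing, eye$fiducials[[2L]], faf,
                       zone, sentinel_policy)
    cd <- coordinate_differences(a1$stimulus_faf_um, a2$stimulus_faf_um)
    per_eye[[i]] <- data.frame(
      eye_id = eye$exam$eye_id,
      mean_sens_g1 = a1$metrics$mean_sensitivity_db,
      mean_sens_g2 = a2$metrics$mean_sensitivity_db,
      n_scot_g1 = a1$metrics$n_scotomatous_in_zone,
      n_scot_g2 = a2$metrics$n_scotomatous_in_zone,
      n_in_zone_g1 = a1$metrics$n_in_zone,
      n_in_zone_g2 = a2$metrics$n_in_zone,
      empty_zone = a1$metrics$empty_zone || a2$metrics$empty_zone)
    coord[[i]] <- data.frame(eye_id = eye$exam$eye_id,
                             mean_um = cd$mean_um, sd_um = cd$sd_um)
    coord_all[[i]] <- cd$per_stimulus_um
    dist1[[i]] <- a1$distances$distance_um
    dist2[[i]] <- a2$distances$distance_um
    dist_cluster[[i]] <- rep(eye$exam$eye_id, nrow(a1$distances))
  }
  per_eye <- do.call(rbind, per_eye)
  coord <- do.call(rbind, coord)
  usable <- !per_eye$empty_zone
  if (sum(usable) < 3L)
    stop("fewer than 3 eyes with a non-empty zone; eye-level agreement ",
         "is not estimable", call. = FALSE)
  d1 <- unlist(dist1); d2 <- unlist(dist2); cl <- unlist(dist_cluster)
  structure(
    list(mean_sensitivity = repeatability_report(
           per_eye$mean_sens_g1[usable], per_eye$mean_sens_g2[usable],
           units = "dB"),
         scotomatous_count = repeatability_report(
           per_eye$n_scot_g1[usable], per_eye$n_scot_g2[usable],
           units = "points"),
         margin_distance = repeatability_report(
           d1, d2, cluster = cl, units = "um"),
         coordinate_difference = list(
           per_eye = coord,
           pooled_mean_um = mean(unlist(coord_all)),
           pooled_sd_um = stats::sd(unlist(coord_all)),
           n_eyes = n_eye),
         per_eye = per_eye,
         excluded_eyes = per_eye$eye_id[!usable],
         zone = zone, sentinel_policy = sentinel_policy,
         um_per_degree = faf$um_per_degree),
    class = "grader_agreement")
}

#' @export
print.grader_agreement <- function(x, digits = 4, ...) {
  cat(sprintf("inter-grader agreement, %s zone [%g, %g] um (sentinel: %s, %g um/deg)\n",
              x$zone$kind, x$zone$inner_limit_um, x$zone$outer_limit_um,
              x$sentinel_policy, x$um_per_degree))
  if (length(x$excluded_eyes))
    cat("  eyes excluded (empty zone): ",
        paste(x$excluded_eyes, collapse = ", "), "\n")
  cat("\n-- mean zone sensitivity (per eye) --\n")
  print(x$mean_sensitivity, digits = digits)
  cat("\n-- scotomatous points in zone (per eye) --\n")
  print(x$scotomatous_count, digits = digits)
  cat("\n-- stimulus-to-margin distance (per stimulus, eye-clustered) --\n")
  print(x$margin_distance, digits = digits)
  cat(sprintf("\n-- stimulus coordinate difference: %.*g +/- %.*g um (pooled over stimuli) --\n",
              digits, x$coordinate_difference$pooled_mean_um,
              digits, x$coordinate_difference$pooled_sd_um))
  invisible(x)
}
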