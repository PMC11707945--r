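#' Simulation configuration for a synthetic grader-repeatability study
#'
#' Defines every parameter of the synthetic study generator: the lesion
#' model (number of foci, focus size distribution, boundary roughness), the
#' distance-dependent sensitivity field, the measurement model (4-2
#' staircase or direct field readout), the grader model (number of fiducials
#' picked and fiducial jitter), and the imaging frames.
#'
#' Defaults emulate a 30-eye GA cohort: multifocal lesions with an expected
#' total area of 6.5 mm^2 around the fovea (per-focus radii shrink with the
#' focus count so the total does not depend on focality), dense scotoma
#' inside the atrophy (-5 dB true
#' threshold, i.e., below the device floor), near-normal mesopic sensitivity
#' (28 dB) outside, a 125 um transition half-width across the margin,
#' graders picking on average 3.3 and 4.6 vessel-bifurcation fiducials with
#' 1 px picking jitter, a 30 deg/768 px FAF frame and a 36 deg/1024 px SLO
#' frame, both at 291 um per degree.
#'
#' @param n_eyes number of eyes to simulate.
#' @param seed RNG seed; a fixed seed makes [simulate_study()] fully
#'   deterministic.
#' @param n_foci_range integer range (min, max) of GA foci per eye.
#' @param mean_radius_um median focus radius of the log-normal size
#'   distribution, in micrometers.
#' @param radius_sdlog log-scale SD of the focus radius distribution.
#' @param roughness relative amplitude of the smooth periodic boundary
#'   perturbation (0 = circular foci).
#' @param n_boundary_vertices vertices per focus polygon (>= 64).
#' @param inside_db,outside_db asymptotic true thresholds (dB) deep inside
#'   and far outside the lesion.
#' @param half_width_um transition half-width of the logistic sensitivity
#'   profile across the margin, in micrometers.
#' @param staircase logical: measure sensitivities with the simulated 4-2
#'   staircase (`TRUE`) or read the true field directly (`FALSE`).
#' @param observer_slope psychometric slope (per dB) of the staircase
#'   observer; `Inf` gives a deterministic observer.
#' @param jitter_sd_px length-2 vector: fiducial picking jitter SD in pixels
#'   for grader 1 and grader 2 (applied at both the SLO and FAF end).
#' @param n_fiducials_mean,n_fiducials_sd length-2 vectors: mean and SD of
#'   the number of fiducials each grader picks (truncated below at 3).
#' @param faf_frame,slo_frame [image_frame] metadata for the FAF and MP-SLO
#'   images.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_eyes = 30L,
                       seed = 1L,
                       n_foci_range = c(1L, 3L),
                       mean_radius_um = 1300,
                       radius_sdlog = 0.3,
                       roughness = 0.15,
                       n_boundary_vertices = 128L,
                       inside_db = -5,
                       outside_db = 28,
                       half_width_um = 125,
                       staircase = TRUE,
                       observer_slope = 1,
                       jitter_sd_px = c(1, 1),
                       n_fiducials_mean = c(3.3, 4.6),
                       n_fiducials_sd = c(0.7, 1.7),
                       faf_frame = image_frame(30, 768, 291),
                       slo_frame = image_frame(36, 1024, 291)) {
  stopifnot(n_eyes >= 1, length(n_foci_range) == 2L,
            n_foci_range[1L] >= 1L, n_foci_range[2L] >= n_foci_range[1L],
            mean_radius_um > 0, radius_sdlog >= 0, roughness >= 0,
            n_boundary_vertices >= 64L, half_width_um > 0,
            length(jitter_sd_px) == 2L, all(jitter_sd_px >= 0),
            length(n_fiducials_mean) == 2L, all(n_fiducials_mean >= 3),
            length(n_fiducials_sd) == 2L, all(n_fiducials_sd >= 0),
            inherits(faf_frame, "image_frame"),
            inherits(slo_frame, "image_frame"))
  structure(as.list(environment()), class = "sim_config")
}

#' Expected focus area implied by a simulation configuration
#'
#' Closed-form mean of the per-focus polygon area under the log-normal
#' radius model with boundary roughness: `pi * R^2 * exp(2 sdlog^2) *
#' (1 + roughness^2)` (the roughness profile has unit RMS).
#'
#' @param config a [sim_config].
#' @return Expected focus area in mm^2.
#' @export
expected_focus_area_mm2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pi * config$mean_radius_um^2 * exp(2 * config$radius_sdlog^2) *
    (1 + config$roughness^2) / 1e6
}

# smooth periodic boundary perturbation, zero mean, unit RMS
radial_noise_profile <- function(theta, harmonics = 2:5) {
  amp <- stats::rnorm(length(harmonics)) / harmonics
  phase <- stats::runif(length(harmonics), 0, 2 * pi)
  g <- rowSums(vapply(seq_along(harmonics),
                      function(i) amp[i] * cos(harmonics[i] * theta + phase[i]),
                      numeric(length(theta))))
  rms <- sqrt(sum(amp^2) / 2)
  if (rms == 0) return(rep(0, length(theta)))
  g / rms
}

simulate_focus <- function(config, center_um, focus_id, radius_scale = 1) {
  theta <- seq(0, 2 * pi, length.out = config$n_boundary_vertices + 1L)[-1L]
  base_r <- radius_scale * config$mean_radius_um *
    exp(stats::rnorm(1L, 0, config$radius_sdlog))
  for (try in seq_len(100L)) {
    g <- radial_noise_profile(theta)
    r <- base_r * (1 + config$roughness * g)
    if (min(r) > 0.05 * base_r)
      return(ga_focus(cbind(center_um[1L] + r * cos(theta),
                            center_um[2L] + r * sin(theta)),
                      focus_id = focus_id))
  }
  stop("simulate_focus: could not generate a valid boundary after 100 tries",
       call. = FALSE)
}

#' Simulate a multifocal GA lesion tracing
#'
#' Draws 1-3 (configurable) star-convex GA foci around the fovea. Each focus
#' has a log-normally distributed base radius and a smooth periodic radial
#' perturbation `r(theta) = R (1 + roughness * g(theta))` discretized at
#' `n_boundary_vertices` vertices; star-convexity keeps every generated
#' polygon simple. Foci are placed disjointly (centers separated beyond the
#' sum of their maximal radii).
#'
#' @param config a [sim_config].
#' @param eye_id identifier for the simulated eye.
#' @return A [lesion_tracing] in FAF-frame micrometers.
#' @export
simulate_lesion <- function(config, eye_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  fovea <- frame_center_um(config$faf_frame)
  n_foci <- sample(seq(config$n_foci_range[1L], config$n_foci_range[2L]), 1L)
  # per-focus radii scale with 1/sqrt(n_foci) so the expected total lesion
  # area does not depend on the focus count
  rscale <- 1 / sqrt(n_foci)
  foci <- vector("list", n_foci)
  centers <- matrix(NA_real_, 0L, 2L)
  max_r <- numeric(0L)
  for (i in seq_len(n_foci)) {
    placed <- FALSE
    for (try in seq_len(100L)) {
      # the search widens as placement retries accumulate
      offset <- stats::rnorm(2L, 0, 600 * (1 + (try - 1L) / 15))
      f <- simulate_focus(config, fovea + offset, focus_id = i,
                          radius_scale = rscale)
      rmax <- max(sqrt(rowSums(sweep(f$vertices, 2L, fovea + offset)^2)))
      ok <- TRUE
      if (nrow(centers) > 0L) {
        dc <- sqrt(rowSums(sweep(centers, 2L, fovea + offset)^2))
        ok <- all(dc > 1.05 * (max_r + rmax))
      }
      if (ok) {
        foci[[i]] <- f
        centers <- rbind(centers, fovea + offset)
        max_r <- c(max_r, rmax)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("simulate_lesion: could not place disjoint foci", call. = FALSE)
  }
  lesion_tracing(foci, eye_id = eye_id)
}

#' True sensitivity field across the lesion margin
#'
#' Logistic profile of the true threshold as a function of the signed
#' stimulus-to-margin distance:
#' `inside + (outside - inside) / (1 + exp(-d / half_width))`.
#' Deep inside the lesion (d -> -Inf) the threshold approaches `inside_db`;
#' far outside, `outside_db`; at the margin (d = 0), their midpoint. The
#' profile is monotone non-decreasing in d whenever
#' `outside_db >= inside_db`.
#'
#' @param distance_um signed stimulus-to-margin distance(s) in micrometers.
#' @param config a [sim_config] (fields `inside_db`, `outside_db`,
#'   `half_width_um`).
#' @return Numeric vector of true thresholds in dB.
#' @export
sensitivity_field <- function(distance_um, config) {
  stopifnot(inherits(config, "sim_config"))
  config$inside_db + (config$outside_db - config$inside_db) /
    (1 + exp(-distance_um / config$half_width_um))
}

#' Simulate one 4-2 staircase threshold measurement
#'
#' Two-phase staircase on the 0-36 dB attenuation scale: presentations start
#' at 25 dB and move in 4 dB steps (dimmer after seen, brighter after not
#' seen) until the first response reversal, then in 2 dB steps until the
#' second reversal; the estimate is the last-seen level. A presentation at
#' 0 dB (the brightest stimulus) that is not seen terminates the test with
#' the device's -1 dB not-seen sentinel. The observer responds "seen" with
#' probability `pnorm(observer_slope * (true - level))`; an infinite slope
#' gives the deterministic observer (seen iff `level <= true`).
#'
#' @param true_threshold_db true threshold in dB (values below 0 yield
#'   not-seen outcomes under the deterministic observer).
#' @param observer_slope psychometric slope per dB; `Inf` = deterministic.
#' @param start_level_db first presentation level.
#' @param db_range device attenuation range.
#' @return List with `sensitivity_db` (the estimate, or -1) and
#'   `raw_not_seen`.
#' @export
staircase_4_2 <- function(true_threshold_db, observer_slope = Inf,
                          start_level_db = 25, db_range = c(0, 36)) {
  stopifnot(length(true_threshold_db) == 1L, is.finite(true_threshold_db))
  level <- start_level_db
  step <- 4
  n_reversals <- 0L
  last_seen <- NA_real_
  prev_response <- NA
  for (i in seq_len(60L)) {
    seen <- if (is.infinite(observer_slope)) {
      level <= true_threshold_db
    } else {
      stats::runif(1L) <
        stats::pnorm(observer_slope * (true_threshold_db - level))
    }
    if (!seen && level <= db_range[1L])
      return(list(sensitivity_db = -1, raw_not_seen = TRUE))
    if (seen) last_seen <- level
    if (!is.na(prev_response) && seen != prev_response) {
      n_reversals <- n_reversals + 1L
      if (n_reversals == 1L) step <- 2
      if (n_reversals == 2L) break
    }
    prev_response <- seen
    nxt <- level + if (seen) step else -step
    nxt <- min(max(nxt, db_range[1L]), db_range[2L])
    if (nxt == level) break  # pinned at the range ceiling while seeing
    level <- nxt
  }
  if (is.na(last_seen))
    return(list(sensitivity_db = -1, raw_not_seen = TRUE))
  list(sensitivity_db = last_seen, raw_not_seen = FALSE)
}

#' Simulate one grader's fiducial picks for an eye
#'
#' Draws the number of fiducials from the grader's configured distribution
#' (truncated below at the 3-point minimum of the similarity transform),
#' spreads source points over the central SLO frame with a minimum pairwise
#' separation (which also guarantees a non-collinear configuration), maps
#' them through the true transform, and adds isotropic Gaussian picking
#' jitter at both the SLO and FAF end. With zero jitter the pairs are
#' exactly consistent with the true transform.
#'
#' @param true_transform the eye's true SLO-to-FAF [similarity_transform]
#'   (pixel coordinates).
#' @param config a [sim_config].
#' @param grader integer 1 or 2 selecting the grader model.
#' @param eye_id identifier.
#' @return A [fiducial_set] in pixel coordinates.
#' @export
simulate_grader_fiducials <- function(true_transform, config, grader = 1L,
                                      eye_id = NA) {
  stopifnot(inherits(true_transform, "similarity_transform"),
            inherits(config, "sim_config"), grader %in% c(1L, 2L))
  n <- max(3L, round(stats::rnorm(1L, config$n_fiducials_mean[grader],
                                  config$n_fiducials_sd[grader])))
  dims <- config$slo_frame$pixel_dims
  lo <- 0.2 * dims; hi <- 0.8 * dims
  min_sep <- 0.12 * dims
  src <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    for (try in seq_len(200L)) {
      cand <- stats::runif(2L, lo, hi)
      if (i == 1L ||
          all(sqrt(rowSums(sweep(src[seq_len(i - 1L), , drop = FALSE],
                                 2L, cand)^2)) > min_sep)) {
        src[i, ] <- cand
        break
      }
    }
    if (anyNA(src[i, ]))
      stop("could not place separated fiducials", call. = FALSE)
  }
  dst <- apply_transform(true_transform, src)
  # unit noise is always drawn, then scaled: identical seeds with different
  # jitter SDs share the same underlying noise realization
  sdj <- config$jitter_sd_px[grader]
  noise_src <- matrix(stats::rnorm(2L * n), n, 2L)
  noise_dst <- matrix(stats::rnorm(2L * n), n, 2L)
  fiducial_set(src + sdj * noise_src, dst + sdj * noise_dst,
               grader_id = paste0("grader", grader), eye_id = eye_id)
}

simulate_true_transform <- function(config) {
  faf <- config$faf_frame; slo <- config$slo_frame
  s0 <- (faf$pixel_dims / faf$field_of_view_deg) /
    (slo$pixel_dims / slo$field_of_view_deg)
  scale <- s0 * exp(stats::rnorm(1L, 0, 0.02))
  rotation <- stats::rnorm(1L, 0, 1.5 * pi / 180)
  target_center <- frame_center_px(faf) + stats::rnorm(2L, 0, 5)
  trans <- target_center -
    scale * as.numeric(rotation_matrix(rotation) %*% frame_center_px(slo))
  similarity_transform(scale, rotation, trans)
}

#' Map fovea-centered stimulus positions to SLO pixel coordinates
#'
#' @param xy_deg n x 2 matrix of fovea-centered degree coordinates.
#' @param slo_frame the SLO [image_frame] (fovea at frame center).
#' @return n x 2 matrix of SLO pixel coordinates.
#' @export
degrees_to_slo_pixels <- function(xy_deg, slo_frame) {
  stopifnot(inherits(slo_frame, "image_frame"))
  xy <- as_xy(xy_deg)
  px_per_deg <- slo_frame$pixel_dims / slo_frame$field_of_view_deg
  ctr <- frame_center_px(slo_frame)
  cbind(ctr[1L] + xy[, 1L] * px_per_deg,
        ctr[2L] - xy[, 2L] * px_per_deg)  # degree y up, pixel y down
}

simulate_eye <- function(config, eye_id) {
  tracing <- simulate_lesion(config, eye_id = eye_id)
  true_tf <- simulate_true_transform(config)
  grid <- mp_grid_10_2()
  slo_px <- degrees_to_slo_pixels(as.matrix(grid[c("x_deg", "y_deg")]),
                                  config$slo_frame)
  faf_px <- apply_transform(true_tf, slo_px)
  faf_um <- faf_px * um_per_pixel(config$faf_frame)
  true_d <- signed_distance(faf_um, tracing,
                            stimulus_id = grid$stimulus_id)
  true_thr <- sensitivity_field(true_d$distance_um, config)
  if (config$staircase) {
    meas <- lapply(true_thr, staircase_4_2,
                   observer_slope = config$observer_slope)
    sens <- vapply(meas, `[[`, numeric(1L), "sensitivity_db")
    not_seen <- vapply(meas, `[[`, logical(1L), "raw_not_seen")
  } else {
    not_seen <- true_thr < 0
    sens <- ifelse(not_seen, -1, pmin(true_thr, 36))
  }
  exam <- mp_exam(data.frame(stimulus_id = grid$stimulus_id,
                             x_deg = grid$x_deg, y_deg = grid$y_deg,
                             sensitivity_db = sens,
                             raw_not_seen = not_seen),
                  eye_id = eye_id, slo_frame = config$slo_frame)
  fid1 <- simulate_grader_fiducials(true_tf, config, 1L, eye_id = eye_id)
  fid2 <- simulate_grader_fiducials(true_tf, config, 2L, eye_id = eye_id)
  list(eye_id = eye_id, exam = exam, tracing = tracing,
       fiducials = list(fid1, fid2),
       truth = list(transform = true_tf,
                    stimulus_faf_um = faf_um,
                    distances = true_d,
                    thresholds_db = true_thr))
}

#' Simulate a complete two-grader repeatability study
#'
#' End-to-end generator: for each eye, a multifocal lesion tracing, a true
#' SLO-to-FAF similarity transform, an MP exam whose sensitivities follow
#' the distance-dependent field (measured through the 4-2 staircase or read
#' directly), and two graders' jittered fiducial sets derived from the same
#' true transform. Ground truth (true transforms, true signed distances,
#' true thresholds) is retained per eye, so every downstream quantity can be
#' recomputed exactly. A fixed seed makes the output fully deterministic.
#'
#' @param config a [sim_config].
#' @return An object of class `ga_study`: `config` plus a list `eyes`, each
#'   with `exam`, `tracing`, `fiducials` (two [fiducial_set]s) and `truth`.
#' @examples
#' study <- simulate_study(sim_config(n_eyes = 2, seed = 7))
#' length(study$eyes)
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  eyes <- lapply(seq_len(config$n_eyes), function(i) simulate_eye(config, i))
  structure(list(config = config, eyes = eyes), class = "ga_study")
}

#' @export
print.ga_study <- function(x, ...) {
  cat(sprintf("synthetic GA study: %d eyes (seed %d, %s measurement)\n",
              length(x$eyes), x$config$seed,
              if (x$config$staircase) "4-2 staircase" else "direct field"))
  invisible(x)
}
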