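test_that("roughness-free foci approximate circles; areas track the size model", {
  cfg <- sim_config(roughness = 0, n_boundary_vertices = 256,
                    radius_sdlog = 0)
  withr::local_seed(1)
  f <- gajunct:::simulate_focus(cfg, c(0, 0), 1L)
  expect_lt(abs(polygon_area(f) * 1e6 - pi * cfg$mean_radius_um^2) /
              (pi * cfg$mean_radius_um^2), 0.01)

  cfg2 <- sim_config()
  withr::local_seed(2)
  areas <- replicate(1000, polygon_area(gajunct:::simulate_focus(
    cfg2, c(0, 0), 1L)))
  expect_lt(abs(mean(areas) - expected_focus_area_mm2(cfg2)) /
              expected_focus_area_mm2(cfg2), 0.10)
})

test_that("every generated lesion is a valid multifocal tracing", {
  cfg <- sim_config()
  withr::local_seed(3)
  for (rep in 1:25) {
    tr <- simulate_lesion(cfg, eye_id = rep)
    expect_s3_class(tr, "lesion_tracing")
    n_foci <- length(tr$foci)
    expect_gte(n_foci, cfg$n_foci_range[1])
    expect_lte(n_foci, cfg$n_foci_range[2])
    for (f in tr$foci) {
      expect_gte(nrow(f$vertices), 64L)
      expect_gt(polygon_area(f), 0)
      # construction through ga_focus implies simplicity; re-check area sign
      expect_gt(gajunct:::shoelace_signed_area(f$vertices), 0)
    }
  }
})

test_that("the sensitivity field is a logistic ramp across the margin", {
  cfg <- sim_config(inside_db = -5, outside_db = 28, half_width_um = 125)
  expect_equal(sensitivity_field(-1e9, cfg), -5)
  expect_equal(sensitivity_field(1e9, cfg), 28)
  expect_equal(sensitivity_field(0, cfg), (28 - 5) / 2)
  d <- seq(-1000, 1000, by = 1)
  expect_true(all(diff(sensitivity_field(d, cfg)) >= 0))
})

test_that("the deterministic 4-2 staircase lands within 2 dB over the range", {
  for (t in seq(2, 34, by = 1)) {
    res <- staircase_4_2(t, observer_slope = Inf)
    expect_false(res$raw_not_seen)
    expect_lte(abs(res$sensitivity_db - t), 2)
    expect_equal(res$sensitivity_db,
                 oracle_staircase_deterministic(t))
  }
  # dense scotoma: never seen at the brightest stimulus
  deep <- staircase_4_2(-10, observer_slope = Inf)
  expect_true(deep$raw_not_seen)
  expect_equal(deep$sensitivity_db, -1)
  # ceiling respected
  top <- staircase_4_2(36, observer_slope = Inf)
  expect_lte(top$sensitivity_db, 36)
  expect_lte(staircase_4_2(40, observer_slope = Inf)$sensitivity_db, 36)
})

test_that("probabilistic observers still terminate and stay in range", {
  withr::local_seed(12)
  for (t in c(-3, 0, 10, 25, 35)) {
    res <- staircase_4_2(t, observer_slope = 1)
    expect_true(res$raw_not_seen || (res$sensitivity_db >= 0 &&
                                       res$sensitivity_db <= 36))
  }
})

test_that("zero-jitter fiducials recover the true transform exactly", {
  cfg <- sim_config(jitter_sd_px = c(0, 0))
  withr::local_seed(6)
  for (rep in 1:10) {
    tf <- gajunct:::simulate_true_transform(cfg)
    fid <- simulate_grader_fiducials(tf, cfg, grader = sample(1:2, 1))
    expect_gte(nrow(fid$src), 3L)
    fit <- fit_similarity(fid)
    expect_equal(fit$scale, tf$scale, tolerance = 1e-9)
    expect_equal(fit$rotation, tf$rotation, tolerance = 1e-9)
    expect_equal(fit$translation, tf$translation, tolerance = 1e-9)
  }
})

test_that("per-eye coordinate differences grow with fiducial jitter", {
  mean_cd <- vapply(c(0.5, 2), function(sdj) {
    cfg <- sim_config(n_eyes = 8, seed = 99, jitter_sd_px = c(sdj, sdj),
                      staircase = FALSE)
    study <- simulate_study(cfg)
    agg <- grader_agreement(study)
    agg$coordinate_difference$pooled_mean_um
  }, numeric(1))
  expect_gt(mean_cd[2], mean_cd[1])
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_study(sim_config(n_eyes = 2, seed = 42))
  s2 <- simulate_study(sim_config(n_eyes = 2, seed = 42))
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("with staircase off and zero jitter the pipeline is an exact function of ground truth", {
  cfg <- sim_config(n_eyes = 2, seed = 5, jitter_sd_px = c(0, 0),
                    staircase = FALSE)
  study <- simulate_study(cfg)
  for (eye in study$eyes) {
    # measured sensitivities are the clamped true field
    truth_thr <- sensitivity_field(eye$truth$distances$distance_um, cfg)
    expect_equal(eye$exam$stimuli$raw_not_seen, truth_thr < 0)
    seen <- !eye$exam$stimuli$raw_not_seen
    expect_equal(eye$exam$stimuli$sensitivity_db[seen],
                 pmin(truth_thr, 36)[seen])
    # grader analyses reproduce the true distances
    a1 <- analyze_exam(eye$exam, eye$tracing, eye$fiducials[[1]],
                       cfg$faf_frame)
    expect_equal(a1$distances$distance_um,
                 eye$truth$distances$distance_um, tolerance = 1e-6)
  }
})
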