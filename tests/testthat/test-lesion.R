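test_that("polygon areas follow the shoelace formula in mm^2", {
  expect_equal(polygon_area(square_focus(1000)), 1.0)
  tri <- ga_focus(rbind(c(0, 0), c(1000, 0), c(0, 1000)))
  expect_equal(polygon_area(tri), 0.5)
  tri_rev <- ga_focus(rbind(c(0, 1000), c(1000, 0), c(0, 0)))
  expect_equal(polygon_area(tri_rev), 0.5)  # orientation invariant
})

test_that("focus construction rejects degenerate or crossing outlines", {
  expect_error(ga_focus(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(ga_focus(rbind(c(0, 0), c(1, 1), c(2, 2))), "zero area")
  bowtie <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(ga_focus(bowtie), "zero area")  # symmetric bowtie cancels
  crossing <- rbind(c(0, 0), c(100, 0), c(0, 100), c(80, 120))
  expect_error(ga_focus(crossing), "self-intersecting")
  # explicit closing vertex accepted and dropped
  f <- ga_focus(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(0, 0)))
  expect_equal(nrow(f$vertices), 4L)
})

test_that("minimum-lesion-size filter retains only foci at or above threshold", {
  small <- square_focus(200, focus_id = "small")    # 0.04 mm^2
  big <- square_focus(sqrt(0.06) * 1000, c(5000, 5000), "big")  # 0.06 mm^2
  tr <- lesion_tracing(list(small, big))
  suppressMessages(kept <- filter_min_area(tr))
  expect_length(kept$foci, 1L)
  expect_equal(kept$foci[[1]]$focus_id, "big")
  expect_equal(attr(kept, "dropped_focus_ids"), "small")

  all_small <- lesion_tracing(list(small))
  suppressMessages(empty <- filter_min_area(all_small))
  expect_length(empty$foci, 0L)
  expect_error(signed_distance(c(0, 0), all_small), "no lesion")

  tr0 <- lesion_tracing(list(small, big), min_focus_area_mm2 = 0)
  expect_length(filter_min_area(tr0)$foci, 2L)
})

test_that("signed distances on a unit square match hand geometry", {
  tr <- lesion_tracing(square_focus(1000))
  expect_equal(signed_distance(c(500, 500), tr)$distance_um, -500)
  expect_equal(signed_distance(c(1500, 500), tr)$distance_um, 500)
  expect_equal(signed_distance(c(1000, 500), tr)$distance_um, 0)
  expect_equal(signed_distance(c(500, 100), tr)$distance_um, -100)
  expect_equal(signed_distance(c(1003, 1004), tr)$distance_um, 5)
})

test_that("multifocal sign uses the even-odd rule and nearest focus is reported", {
  outer <- square_focus(4000, focus_id = "outer")
  island <- square_focus(1000, c(1500, 1500), "island")  # nested: spared retina
  tr <- lesion_tracing(list(outer, island))
  ctr <- signed_distance(c(2000, 2000), tr)  # inside both -> outside lesion
  expect_gt(ctr$distance_um, 0)
  expect_equal(ctr$nearest_focus_id, "island")
  ring_pt <- signed_distance(c(500, 2000), tr)  # inside outer only
  expect_lt(ring_pt$distance_um, 0)
})

test_that("signed distance agrees with the dense-sampling + winding oracle", {
  withr::local_seed(101)
  n_cases <- 150
  worst <- 0
  for (case in seq_len(n_cases)) {
    n_foci <- sample(1:3, 1)
    rings <- lapply(seq_len(n_foci), function(i)
      random_star_polygon(center = runif(2, -800, 800),
                          radius = runif(1, 120, 400),
                          n_vertices = sample(8:24, 1)))
    tr <- lesion_tracing(lapply(seq_along(rings), function(i)
      ga_focus(rings[[i]], i)), min_focus_area_mm2 = 0)
    p <- runif(2, -1200, 1200)
    got <- signed_distance(p, tr)$distance_um
    want <- oracle_signed_distance(p, rings, step = 0.1)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 0.5)
})

test_that("signed distance is homogeneous and bounded by vertex distances", {
  withr::local_seed(55)
  ring <- random_star_polygon(radius = 250)
  tr <- lesion_tracing(ga_focus(ring), min_focus_area_mm2 = 0)
  for (rep in 1:20) {
    p <- runif(2, -600, 600)
    d <- signed_distance(p, tr)$distance_um
    vert_d <- sqrt(rowSums(sweep(ring, 2, p)^2))
    expect_lte(abs(d), min(vert_d) + 1e-9)
    k <- runif(1, 0.5, 3)
    trk <- lesion_tracing(ga_focus(ring * k), min_focus_area_mm2 = 0)
    expect_equal(signed_distance(p * k, trk)$distance_um, k * d,
                 tolerance = 1e-9)
  }
})

test_that("zone membership is an inclusive band on the signed distance", {
  junct <- zone_spec("junctional")
  peri <- zone_spec("perilesional")
  d <- c(-251, -250, 0, 250, 251, 500, 501)
  expect_equal(zone_membership(d, junct),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(zone_membership(d, peri),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # junctional membership is exactly |d| <= 250
  withr::local_seed(9)
  dd <- runif(500, -600, 600)
  expect_equal(zone_membership(dd, junct), abs(dd) <= 250)
  expect_error(zone_spec("custom"), "explicit")
  expect_error(zone_spec("custom", 100, 100), "below")
})
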