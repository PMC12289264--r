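test_that("keratometric power converts to radius and back", {
  expect_equal(diopters_to_radius(45), 7.5)
  expect_equal(diopters_to_radius(67.5), 5.0)
  expect_equal(radius_to_diopters(7.5), 45)
  # alternate conversion constants pass straight through
  expect_equal(diopters_to_radius(50, kindex = 340), 6.8)
  expect_error(diopters_to_radius(0), "positive")
  expect_error(diopters_to_radius(-45), "positive")
  expect_error(diopters_to_radius(45, kindex = 0), "positive")
})

test_that("cornea_model satisfies radius * keratometry == kindex", {
  m <- cornea_model(60)
  expect_s3_class(m, "cornea_model")
  expect_equal(m$radius * m$keratometry, m$kindex, tolerance = 1e-12)
  expect_equal(cornea_model(45)$radius, 7.5)
})

test_that("cosine-rule apex angle matches its closed forms and limits", {
  # chord 6 on radius 7.5: cos(alpha) = 1 - 36/112.5 = 0.68
  a <- apex_angle_from_chord(7.5, 6)
  expect_equal(cos(a), 0.68, tolerance = 1e-15)
  expect_equal(a, 0.823033692134976, tolerance = 1e-12)
  # semicircle: chord equals the diameter
  expect_equal(apex_angle_from_chord(1, 2), pi)
  expect_equal(apex_angle_from_chord(3.25, 6.5), pi)
  # vanishing chord gives vanishing angle
  expect_lt(apex_angle_from_chord(7.5, 1e-8), 1e-7)
  expect_error(apex_angle_from_chord(7.5, 16), "exceeds")
  expect_error(apex_angle_from_chord(7.5, 0), "positive")
  expect_error(apex_angle_from_chord(7.5, -1), "positive")
})

test_that("cosine-rule angle agrees with the half-angle sine oracle", {
  pairs <- random_radius_chord(1000)
  cosine_form <- mapply(apex_angle_from_chord, pairs$radius, pairs$chord)
  sine_form <- 2 * asin(pairs$chord / (2 * pairs$radius))
  expect_lt(max(abs(cosine_form - sine_form)), 1e-10)
})

test_that("arc length is radius times angle, with domain guards", {
  expect_equal(arc_length(7.5, 0.823033692134976), 6.172752691012320,
               tolerance = 1e-12)
  expect_equal(arc_length(3, 0), 0)
  expect_equal(arc_length(1, 2 * pi), 2 * pi)
  expect_error(arc_length(-1, 1), "positive")
  expect_error(arc_length(1, -0.1), "2\\*pi")
  expect_error(arc_length(1, 7), "2\\*pi")
})

test_that("composed DM arc length reproduces tabulated cells", {
  expect_equal(round_half_up(dm_arc_length(45, 6.00), 2), 6.17)
  expect_equal(round_half_up(dm_arc_length(70, 8.00), 2), 9.43)
  expect_equal(round_half_up(dm_arc_length(60, 7.50), 2), 8.21)
  sol <- dm_arc_solution(45, 6)
  expect_s3_class(sol, "arc_solution")
  expect_equal(sol$arc_length, sol$radius * sol$apex_angle)
  expect_gte(sol$arc_length, sol$chord)
})

test_that("DM arc always dominates the trephine chord", {
  set.seed(77)
  for (i in 1:200) {
    k <- runif(1, 45, 70)
    t <- runif(1, 6, 8)
    expect_gt(dm_arc_length(k, t, warn = FALSE), t)
  }
})

test_that("DM arc approaches the chord in the flat-cornea limit", {
  expect_lt(abs(dm_arc_length(0.001, 7, warn = FALSE) - 7), 1e-6)
})

test_that("DM arc increases with curvature and with trephine size", {
  arcs_k <- vapply(seq(45, 70, by = 0.5), dm_arc_length,
                   numeric(1), trephine = 7, warn = FALSE)
  expect_true(all(diff(arcs_k) > 0))
  arcs_t <- vapply(seq(6, 8, by = 0.1), function(t)
    dm_arc_length(60, t, warn = FALSE), numeric(1))
  expect_true(all(diff(arcs_t) > 0))
})

test_that("inputs outside the tabulated envelope warn but still compute", {
  expect_warning(a <- dm_arc_length(80, 7), "envelope")
  expect_gt(a, 7)
  expect_warning(dm_arc_length(60, 9), "envelope")
  expect_silent(dm_arc_length(60, 7))
  expect_silent(dm_arc_length(80, 7, warn = FALSE))
})
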