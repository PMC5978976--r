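test_that("default grid has 1.5-cm neighbor spacing and unit normals", {
  g <- build_grid()
  p <- g$points
  # nearest-neighbor distance between centers is exactly the pitch
  k <- which(p$i == 10 & p$j == 10)
  nb <- which(p$i == 10 & p$j == 11)
  expect_equal(sqrt(sum((p[k, c("x", "y", "z")] -
                           p[nb, c("x", "y", "z")])^2)), 1.5)
  expect_equal(sqrt(p$nx^2 + p$ny^2 + p$nz^2), rep(1, nrow(p)))
  # all points on the face plane and inside the face disc
  expect_true(all(p$y == 0))
  expect_true(all(p$x^2 + p$z^2 <= g$radius^2 + 1e-9))
  expect_error(build_grid(spacing = 20), "spacing")
  expect_error(build_grid(radius = -1), "positive")
})

test_that("grid point count matches the combinatorial disc-filter oracle", {
  r <- 16; s <- 8                      # spacing = radius/2
  g <- build_grid(radius = r, spacing = s)
  n <- floor(r / s)
  cand <- expand.grid(a = (-n:n) * s, b = (-n:n) * s)
  expect_equal(nrow(cand), (2 * n + 1)^2)
  expect_equal(nrow(g$points), sum(cand$a^2 + cand$b^2 <= r^2))
})

test_that("beam construction matches the closed-form geometry", {
  ev <- irradiation_event("e", 100, 80, sod = 75, field_w_iso = 15,
                          field_h_iso = 15)
  b <- beam_from_event(ev)
  expect_equal(b$half_angle_w, atan(7.5 / 75))
  expect_equal(b$central_axis, c(0, 1, 0))
  expect_equal(b$source_position, c(0, -75, 0))
  # secondary angle tilts the axis away from the grid normal
  ev30 <- irradiation_event("e30", 100, 80, gantry_secondary_deg = 30)
  ax <- beam_from_event(ev30)$central_axis
  expect_equal(180 / pi * acos(sum(ax * c(0, 1, 0))), 30,
               tolerance = 1e-12)
})

test_that("a pure table offset translates the field without tilting it", {
  evA <- irradiation_event("A", 100, 80, field_w_iso = 5, field_h_iso = 5)
  evB <- irradiation_event("B", 100, 80, field_w_iso = 5, field_h_iso = 5,
                           table_longitudinal_cm = 6)
  bA <- beam_from_event(evA); bB <- beam_from_event(evB)
  expect_equal(bA$central_axis, bB$central_axis)   # parallel axes
  # field centers on the skin plane (y = 0) are 6 cm apart
  centerA <- bA$source_position + bA$sod * bA$central_axis
  centerB <- bB$source_position + bB$sod * bB$central_axis
  expect_equal(sqrt(sum((centerA - centerB)^2)), 6)
})

test_that("tracing classifies axis and off-field points correctly", {
  g <- build_grid()
  ev <- irradiation_event("e", 100, 80, field_w_iso = 5, field_h_iso = 5)
  tr <- trace_beam(beam_from_event(ev), g)$points
  center <- tr[tr$i == 10 & tr$j == 10, ]
  expect_true(center$in_field)
  expect_equal(center$d_skin, 75)               # point at isocenter
  expect_equal(center$incidence_deg, 0)
  # 9 cm off-axis is outside a 5x5 field at isocenter
  off <- tr[tr$i == 10 & tr$j == 16, ]          # x = 9 cm
  expect_false(off$in_field)
  # triangle inequality on the cylinder: d_skin >= sod - radius
  expect_true(all(tr$d_skin >= 75 - g$radius))
  # inverse-square factor for the axis point is exact
  expect_equal((ev$d_ref / center$d_skin)^2, (60 / 75)^2)
})

test_that("a source inside the phantom is a geometry error", {
  g <- build_grid()
  b <- beam_from_event(irradiation_event("e", 100, 80, sod = 5))
  # force the focal spot into the cylinder body
  b$source_position <- c(0, 5, 0)
  expect_error(trace_beam(b, g), "inside the phantom")
})

test_that("slab path lengths follow the 1/cos law exactly", {
  g <- build_grid()
  slabs <- slab_config(table_present = TRUE, pad_present = TRUE)
  ev0 <- irradiation_event("e0", 100, 80, field_w_iso = 5,
                           field_h_iso = 5)
  tr0 <- trace_beam(beam_from_event(ev0), g, slabs)$points
  c0 <- tr0[tr0$i == 10 & tr0$j == 10, ]
  expect_identical(c0$table_path_mm, 1.5)       # normal incidence
  expect_identical(c0$pad_path_mm, 70)
  ev60 <- irradiation_event("e60", 100, 80, field_w_iso = 5,
                            field_h_iso = 5, gantry_secondary_deg = 60)
  tr60 <- trace_beam(beam_from_event(ev60), g, slabs)$points
  c60 <- tr60[tr60$i == 10 & tr60$j == 10, ]
  expect_equal(c60$table_path_mm, 2 * 1.5, tolerance = 1e-12)
  expect_equal(c60$pad_path_mm, 2 * 70, tolerance = 1e-12)
  expect_equal(c60$incidence_deg, 60, tolerance = 1e-9)
})

test_that("tracing is invariant under a common rigid translation", {
  g <- build_grid()
  ev <- random_event()
  b <- beam_from_event(ev)
  tr1 <- trace_beam(b, g)$points
  shift <- c(0, 0, 4.2)                  # translate along the cylinder axis
  g2 <- g
  g2$points$z <- g2$points$z + shift[3]
  b2 <- b
  b2$source_position <- b2$source_position + shift
  tr2 <- trace_beam(b2, g2)$points
  expect_equal(tr1$in_field, tr2$in_field)
  expect_equal(tr1$d_skin, tr2$d_skin, tolerance = 1e-12)
})

test_that("two-field overlap is the in-field intersection", {
  g <- build_grid()
  ev <- irradiation_event("e", 100, 80, field_w_iso = 5, field_h_iso = 5)
  tr <- trace_beam(beam_from_event(ev), g)
  # identical beams: overlap equals the full in-field set
  expect_equal(nrow(two_field_overlap(tr, tr)), sum(tr$points$in_field))
  # far-displaced beam: empty overlap
  far <- irradiation_event("far", 100, 80, field_w_iso = 5,
                           field_h_iso = 5, table_longitudinal_cm = 30)
  trf <- trace_beam(beam_from_event(far), g)
  expect_equal(nrow(two_field_overlap(tr, trf)), 0)
  # mismatched grids are an error
  expect_error(
    two_field_overlap(tr, trace_beam(beam_from_event(ev),
                                     build_grid(spacing = 1))),
    "same grid")
})

test_that("the two-field scenarios reproduce their displacement geometry", {
  # 6-cm displacement with 5x5 fields: two distinct fields, no overlap,
  # and 6 is an exact multiple of the 1.5-cm pitch so both field
  # centers land on grid points
  sc7 <- make_scenario(scenario_spec("fig7_two_fields"))
  trA <- trace_beam(beam_from_event(sc7$events[[1]]), sc7$grid)
  trB <- trace_beam(beam_from_event(sc7$events[[2]]), sc7$grid)
  expect_gt(sum(trA$points$in_field), 0)
  expect_gt(sum(trB$points$in_field), 0)
  expect_equal(nrow(two_field_overlap(trA, trB)), 0)
  expect_equal(field_alignment_check(6, 1.5), 0)
  # 4-cm displacement: the fields intersect spatially
  sc8 <- make_scenario(scenario_spec("fig8_two_fields"))
  trC <- trace_beam(beam_from_event(sc8$events[[1]]), sc8$grid,
                    slab_config(TRUE, TRUE))
  trD <- trace_beam(beam_from_event(sc8$events[[2]]), sc8$grid,
                    slab_config(TRUE, TRUE))
  expect_gt(nrow(two_field_overlap(trC, trD)), 0)
})
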