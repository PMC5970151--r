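# Offsetting, station planning, cross-section cutting, repair and merging.

test_that("offsetting a sphere grows its radius by the offset distance", {
  s <- make_uv_sphere(r = 30)
  off <- offset_limb(s, 2)
  radii <- sqrt(rowSums(off$vertices^2))
  expect_lt(max(abs(radii - 32)), 0.1)
  expect_identical(offset_limb(s, 0), s)
  expect_error(offset_limb(s, -1), "non-negative")
  expect_error(offset_limb(s, 6), "5 mm")
})

test_that("offsetting an elliptic cylinder grows section extents by ~2d", {
  m <- generate_limb(limb_spec(length_mm = 250, proximal_radii = c(40, 30),
                               distal_radii = c(40, 30)))
  st <- station(1, 0, rbind(c(125, -60), c(125, 60)))
  before <- cut_section(m, st)[[1]]$points
  after <- cut_section(offset_limb(m, 2), st)[[1]]$points
  expect_equal(diff(range(after[, 2])) - diff(range(before[, 2])), 4,
               tolerance = 0.1)
  expect_equal(diff(range(after[, 3])) - diff(range(before[, 3])), 4,
               tolerance = 0.1)
})

test_that("station planning follows the round(L/spacing) - 1 rule", {
  A <- input_curve(rbind(c(175, -50), c(175, 50)), "A")
  B <- input_curve(rbind(c(25, -50), c(25, 50)), "B")
  st <- plan_stations(A, B, 15)
  expect_length(st, 11)  # 150/15 -> 9 interior + A + B
  expect_equal(st[[1]]$blend_t, 0)
  expect_equal(st[[11]]$blend_t, 1)
  expect_true(all(diff(vapply(st, `[[`, 0, "blend_t")) > 0))
  # centroid x decreases monotonically from A (distal) to B (proximal)
  cx <- vapply(st, function(s) mean(s$guide[, 1]), numeric(1))
  expect_true(all(diff(cx) < 0))

  B2 <- input_curve(rbind(c(163, -50), c(163, 50)), "B")
  expect_warning(st2 <- plan_stations(A, B2, 15), "apart")
  expect_length(st2, 2)

  # property: the rule holds across the valid (L, spacing) range
  for (L in c(45, 80, 120, 190)) {
    for (sp in c(10, 15, 20)) {
      Bx <- input_curve(rbind(c(175 - L, -50), c(175 - L, 50)), "B")
      n <- length(plan_stations(A, Bx, sp))
      expect_equal(n, max(2, floor(L / sp + 0.5) + 1))
    }
  }
  expect_error(plan_stations(A, B, 25), "10, 20")
})

test_that("interior stations morph monotonically between a bent A and straight B", {
  A <- input_curve(rbind(c(230, -50), c(230, 0), c(214, 25), c(230, 60)), "A")
  B <- input_curve(rbind(c(25, -55), c(25, 55)), "B")
  st <- plan_stations(A, B, 15)
  dips <- vapply(st, function(s) max(s$guide[, 1]) - min(s$guide[, 1]), numeric(1))
  expect_true(all(diff(dips) <= 1e-9))  # the bend fades out towards B
})

test_that("cutting a closed cylinder gives one loop with analytic perimeter", {
  m <- generate_limb(limb_spec(length_mm = 250, proximal_radii = c(35, 35),
                               distal_radii = c(35, 35)))
  secs <- cut_section(m, station(3, 0.2, rbind(c(100, -60), c(100, 60))))
  expect_length(secs, 1)
  expect_true(secs[[1]]$closed)
  expect_equal(secs[[1]]$components, 1)
  per <- splintforge:::polyline_length(secs[[1]]$points)
  expect_lt(abs(per - 2 * pi * 35) / (2 * pi * 35), 0.005)
  # sections are planar for a straight station
  expect_lt(diff(range(secs[[1]]$points[, 1])), 0.1)
  expect_error(cut_section(m, station(9, 0, rbind(c(500, -60), c(500, 60)))),
               "station 9")
})

test_that("a hole at the station leaves one open chain, which repair closes", {
  m <- quick_limb(length_mm = 250, proximal_radii = c(40, 30),
                  distal_radii = c(40, 30))
  holed <- inject_scan_flaws(m, list(flaw_spec(125, 90, c(20, 40))))
  secs <- cut_section(holed, station(1, 0, rbind(c(125, -60), c(125, 60))))
  open <- Filter(function(s) !s$closed, secs)
  expect_gte(length(open), 1)
  fixed <- splintforge:::resolve_station_sections(secs)
  expect_true(fixed$closed)
  expect_true(fixed$repaired)
})

test_that("periodic repair of a gapped circle stays within 1 mm radially", {
  th <- seq(40 * pi / 180, 2 * pi, length.out = 200)  # 40-degree arc missing
  pts <- cbind(100, 30 * cos(th), 60 + 30 * sin(th))
  sec <- splintforge:::section_curve(pts, closed = FALSE, station_index = 1,
                                     guide = rbind(c(100, -60), c(100, 60)))
  fixed <- close_unclosed_section(sec, n_points = 16)
  expect_true(fixed$closed)
  expect_true(fixed$repaired)
  r <- sqrt(fixed$points[, 2]^2 + (fixed$points[, 3] - 60)^2)
  expect_lt(max(abs(r - 30)), 1.0)
  # surviving path is preserved: points on the kept arc barely move
  kept <- fixed$points[fixed$points[, 3] - 60 < -5, ]
  rk <- sqrt(kept[, 2]^2 + (kept[, 3] - 60)^2)
  expect_lt(max(abs(rk - 30)), 0.25)

  # an already-closed curve passes through unchanged
  circ <- circle_section(30, 0, 60)
  expect_identical(close_unclosed_section(circ), circ)

  # a half circle (gap = diameter) is refused
  th2 <- seq(0, pi, length.out = 100)
  half <- splintforge:::section_curve(cbind(100, 30 * cos(th2), 60 + 30 * sin(th2)),
                                      closed = FALSE, station_index = 7,
                                      guide = rbind(c(100, -60), c(100, 60)))
  expect_error(close_unclosed_section(half), "50%")
})

test_that("dual sections merge into one closed curve with a 10 mm corridor", {
  c1 <- circle_section(25, 0, 40)
  c2 <- circle_section(10, 50, 40)
  merged <- merge_dual_sections(list(c1, c2), side_offset_mm = 5)
  expect_true(merged$closed)
  expect_true(merged$merged)
  expect_equal(merged$components, 1)

  pts <- merged$points[, 2:3]
  # encloses both loops (sampled just inside each circle)
  th <- seq(0, 2 * pi, length.out = 36)
  in1 <- cbind(0 + 24.5 * cos(th), 40 + 24.5 * sin(th))
  in2 <- cbind(50 + 9.5 * cos(th), 40 + 9.5 * sin(th))
  expect_true(all(splintforge:::points_in_polygon(in1, pts)))
  expect_true(all(splintforge:::points_in_polygon(in2, pts)))

  # corridor width at mid-bridge: distance between the two walls
  band <- pts[abs(pts[, 1] - 33) < 1.5, ]   # between the circles (25..40)
  expect_equal(max(band[, 2]) - min(band[, 2]), 10, tolerance = 0.5)

  # pass-through and guarded cases
  expect_identical(merge_dual_sections(list(c1)), c1)
  expect_error(merge_dual_sections(list(c1, c2, circle_section(5, -40, 40))),
               "two")
})

test_that("section sets are seam-anchored, CCW, and reject open sections", {
  loops <- lapply(seq(0, 10, length.out = 5), function(x0)
    circle_section(30, 0, 50, x0 = 100 + x0))
  ss <- build_section_set(loops, n_u = 64)
  expect_equal(dim(ss$grid), c(5, 64, 3))
  # seam at the topmost point of every loop
  expect_true(all(abs(ss$grid[, 1, 3] - 80) < 0.1))
  # CCW viewed from +X
  for (i in 1:5) {
    expect_gt(splintforge:::polygon_area2d(ss$grid[i, , c(2, 3)]), 0)
  }
  # seam invariance under rotation of the input parameterization
  rot_loop <- function(sec, k) {
    p <- sec$points[-nrow(sec$points), ]
    p <- p[c((k + 1):nrow(p), 1:k), ]
    splintforge:::section_curve(rbind(p, p[1, ]), TRUE, sec$station_index,
                                guide = sec$guide)
  }
  ss2 <- build_section_set(lapply(loops, rot_loop, k = 17), n_u = 64)
  expect_equal(ss2$grid, ss$grid, tolerance = 0.15)

  th2 <- seq(0, pi, length.out = 50)
  open <- splintforge:::section_curve(cbind(100, 30 * cos(th2), 50 + 30 * sin(th2)),
                                      closed = FALSE, station_index = 3,
                                      guide = rbind(c(100, -60), c(100, 60)))
  expect_error(build_section_set(c(loops[1:2], list(open)), 64), "3")
})
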