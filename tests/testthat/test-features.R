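# Rim tubes, screw seats, assembly.

test_that("seat frames follow the 0.1/0.9 positions and the 180 mm rule", {
  sh150 <- make_solid_shell(flat_sub_surface(w = 80, l = 150), 3.2)
  expect_length(place_seat_frames(sh150), 4)
  sh200 <- make_solid_shell(flat_sub_surface(w = 80, l = 200), 3.2)
  fr200 <- place_seat_frames(sh200)
  expect_length(fr200, 6)
  sh180 <- make_solid_shell(flat_sub_surface(w = 80, l = 180), 3.2)
  expect_length(place_seat_frames(sh180), 4)   # strict >

  # frames sit at the parametric arc positions of each V edge
  ts <- sort(vapply(Filter(function(f) f$edge == 1, fr200), `[[`, 0, "t"))
  expect_equal(ts, c(0.1, 0.5, 0.9))
  ys <- sort(vapply(Filter(function(f) f$edge == 1, fr200),
                    function(f) f$origin[2], numeric(1)))
  expect_equal(ys, c(20, 100, 180), tolerance = 0.5)
})

test_that("rim tubes are capped sweeps with the specified diameter and trim", {
  sh <- make_solid_shell(flat_sub_surface(w = 100, l = 200), 3.2)
  tubes <- build_edge_tubes(sh)
  expect_length(tubes, 2)
  for (tb in tubes) {
    expect_true(is_watertight(tb))
    expect_true(is_oriented(tb))
    path <- attr(tb, "path")
    plen <- splintforge:::polyline_length(path)
    expect_equal(plen / 100, 0.98, tolerance = 0.005)
    v_expect <- pi * (4.7 / 2)^2 * plen
    expect_lt(abs(mesh_volume(tb) - v_expect) / v_expect, 0.02)
  }

  # diameter - thickness = 1.5 mm exactly under defaults
  spec <- edge_tube_spec(3.2)
  expect_equal(spec$diameter_mm - 3.2, 1.5)

  # a curved rim: the tube centreline stays on the rim isocurve
  shc <- make_solid_shell(cylinder_sub_surface(r = 40, l = 150), 3.0)
  tc <- build_edge_tubes(shc)[[1]]
  path <- attr(tc, "path")
  rim <- splintforge:::resample_polyline(shc$rim_isocurves[[1]], 2000)
  d <- vapply(seq_len(nrow(path)), function(i)
    min(sqrt(colSums((t(rim) - path[i, ])^2))), numeric(1))
  expect_lt(max(d), 0.2)
})

test_that("screw-seat solids satisfy the nut-constraint contract", {
  spec <- seat_spec(boss_h_mm = 5.2)
  fr <- structure(list(origin = c(10, 20, 30), axis = c(0, 0, 1), t = 0.1,
                       edge = 1), class = "seat_frame")
  parts <- build_screw_seat(spec, fr)
  expect_true(all(vapply(parts, is_watertight, TRUE)))
  expect_gt(mesh_volume(parts$partO), mesh_volume(parts$partI))
  # the assembled seat is exactly partO minus partI
  expect_equal(mesh_volume(parts$seat),
               mesh_volume(parts$partO) - mesh_volume(parts$partI),
               tolerance = 0.005)
  # part I stays inside part O's bounding region
  bbO <- apply(parts$partO$vertices, 2, range)
  bbI <- apply(parts$partI$vertices, 2, range)
  expect_true(all(bbI[1, 1:2] >= bbO[1, 1:2] - 1e-6) &&
                all(bbI[2, 1:2] <= bbO[2, 1:2] + 1e-6))

  # hexagon pocket cross-section: regular hexagon closed form (sqrt(3)/2)*AF^2
  phis <- seq(0, 2 * pi, length.out = 25)[-25]
  hexpoly <- cbind(splintforge:::hex_radius(phis, 5.6) * cos(phis),
                   splintforge:::hex_radius(phis, 5.6) * sin(phis))
  expect_equal(splintforge:::polygon_area2d(hexpoly), sqrt(3) / 2 * 5.6^2,
               tolerance = 1e-9)

  # a ray along the frame axis passes the through-hole unobstructed
  hits <- ray_mesh_hits(parts$seat, fr$origin - 10 * fr$axis, fr$axis)
  expect_false(any(hits > 1e-6 & hits < 30))

  expect_error(seat_spec(hole_d_mm = 10), "narrower")
  expect_error(seat_spec(nut_depth_mm = 10), "shallower")
})

test_that("assembled parts are watertight with clear screw corridors", {
  sub <- cylinder_sub_surface(r = 40, l = 200, arc_deg = 150, n_c = 49, n_v = 81)
  sh <- make_solid_shell(sub, 3.2)
  pd <- panel_dimensions(sh)
  eng <- engrave_shell(sh, diamond_pattern(pd[1], pd[2]))
  part <- assemble_features(eng)
  expect_true(is_watertight(part$mesh))
  expect_true(is_oriented(part$mesh))
  expect_gt(mesh_volume(part$mesh), 0)
  expect_length(part$seats, 6)            # 200 mm V edges -> midpoint seats
  expect_length(part$tube_paths, 2)
  for (fr in part$seats) {
    expect_true(seat_corridor_clear(part, fr))
  }

  # seats omitted: shell + tubes only, still watertight
  tubes <- build_edge_tubes(eng)
  bare <- assemble_part(eng, tubes)
  expect_true(is_watertight(bare$mesh))
  expect_length(bare$seats, 0)
})

test_that("mating parts' seat frames coincide so screw holes align", {
  loops <- lapply(seq(200, 50, length.out = 8), function(x)
    circle_section(40, 0, 60, x0 = x))
  cs <- skin_surface(build_section_set(loops, n_u = 96), n_v = 48)
  subs <- divide_surface(cs, division_plan(2))
  shells <- lapply(subs, make_solid_shell, thickness_mm = 3.2)
  fr1 <- place_seat_frames(shells[[1]])
  fr2 <- place_seat_frames(shells[[2]])
  origins <- function(frs) do.call(rbind, lapply(frs, `[[`, "origin"))
  o1 <- origins(fr1); o2 <- origins(fr2)
  # each frame of part 1 has a coincident mate on part 2
  for (i in seq_len(nrow(o1))) {
    expect_lt(min(sqrt(rowSums(sweep(o2, 2, o1[i, ])^2))), 0.2)
  }
})
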