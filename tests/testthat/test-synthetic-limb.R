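# The synthetic limb generator: determinism, analytic fidelity, thumb
# topology, and flaw injection.

test_that("thumbless limbs are closed, on-convention, and deterministic", {
  m1 <- quick_limb(surface_noise_mm = 0.7, seed = 42)
  m2 <- quick_limb(surface_noise_mm = 0.7, seed = 42)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  m3 <- quick_limb(surface_noise_mm = 0.7, seed = 43)
  expect_false(identical(m1$vertices, m3$vertices))

  expect_true(is_watertight(m1))
  expect_true(is_oriented(m1))
  pr <- validate_placement(m1)
  expect_lt(pr$axis_alignment_deg, 1)
  expect_true(pr$on_plane)
})

test_that("constant-radius limb sections match the analytic ellipse", {
  m <- generate_limb(limb_spec(length_mm = 250, proximal_radii = c(40, 30),
                               distal_radii = c(40, 30)))
  exp_per <- ellipse_perimeter(40, 30)
  for (x in c(40, 125, 210)) {
    sec <- cut_section(m, station(1, 0, rbind(c(x, -60), c(x, 60))))
    expect_length(sec, 1)
    expect_true(sec[[1]]$closed)
    per <- splintforge:::polyline_length(sec[[1]]$points)
    expect_lt(abs(per - exp_per) / exp_per, 0.005)
  }
  # volume of the elliptic cylinder, a strong orientation + closure check
  expect_equal(mesh_volume(m), pi * 40 * 30 * 250, tolerance = 0.005)
})

test_that("a thumbed limb yields two section components beyond the branch", {
  m <- generate_limb(limb_spec(thumb = default_thumb(200)), resolution_mm = 3)
  expect_true(is_watertight(m))
  expect_true(is_oriented(m))
  expect_lt(validate_placement(m)$axis_alignment_deg, 1)
  secs <- cut_section(m, station(1, 0, rbind(c(225, -60), c(225, 120))))
  expect_equal(length(secs), 2)
  expect_true(all(vapply(secs, `[[`, TRUE, "closed")))
  expect_error(limb_spec(thumb = default_thumb(400)), "outside")
})

test_that("flaw injection removes faces and adds one loop per flaw", {
  m <- quick_limb()
  expect_identical(inject_scan_flaws(m, list()), m)

  one <- inject_scan_flaws(m, list(flaw_spec(150, 140, c(20, 40))))
  expect_lt(nrow(one$faces), nrow(m$faces))
  loops <- boundary_loops(one)
  expect_length(loops, 1)
  # loop bounding box matches the requested footprint (u along x, v arc)
  lv <- one$vertices[loops[[1]], ]
  expect_equal(diff(range(lv[, 1])), 20, tolerance = 0.2 * 20)

  two <- inject_scan_flaws(m, list(flaw_spec(150, 140, c(20, 40)),
                                   flaw_spec(80, 260, c(15, 20))))
  expect_length(boundary_loops(two), 2)
  expect_lt(nrow(two$faces), nrow(one$faces))

  expect_error(inject_scan_flaws(m, list(flaw_spec(150, 140, c(20, 400)))),
               "half the local circumference")
})

test_that("default curves span the limb and bend only for thumbed meshes", {
  m <- quick_limb()
  cv <- default_input_curves(m)
  expect_equal(cv$A$name, "A"); expect_equal(cv$B$name, "B")
  expect_gt(min(cv$A$points[, 1]), max(cv$B$points[, 1]))  # A distal of B
  yr <- range(m$vertices[, 2])
  expect_lte(min(cv$A$points[, 2]), yr[1])
  expect_gte(max(cv$A$points[, 2]), yr[2])
  expect_warning(cvw <- default_input_curves(m, include_thumb = TRUE),
                 "no thumb")
  expect_false(cvw$A$may_cross_thumb)

  mt <- generate_limb(limb_spec(thumb = default_thumb(200)), resolution_mm = 3)
  cvt <- default_input_curves(mt, include_thumb = TRUE)
  expect_true(cvt$A$may_cross_thumb)
  stns <- plan_stations(cvt$A, cvt$B)
  ncomp <- vapply(stns, function(st) length(cut_section(mt, st)), integer(1))
  expect_true(any(ncomp == 2))
})
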