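# Diamond panel generation and parameter-space engraving.

test_that("panel dimensions come from rim and seam arc lengths", {
  sub <- cylinder_sub_surface(r = 40, l = 150, arc_deg = 120)
  sh <- make_solid_shell(sub, 3.2)
  pd <- panel_dimensions(sh)
  expect_equal(unname(pd[1]), 2 * pi * 40 / 3, tolerance = 0.002)
  expect_equal(unname(pd[2]), 150, tolerance = 1e-6)

  flat <- make_solid_shell(flat_sub_surface(w = 100, l = 200), 3)
  pdf <- panel_dimensions(flat)
  expect_equal(unname(pdf), c(100, 200), tolerance = 1e-9)

  # tapered strip: Ua is the mean of the two rim lengths
  n_c <- 33; n_v <- 41
  g <- array(0, c(n_v, n_c, 3))
  th <- seq(0, 2, length.out = n_c)
  rr <- seq(30, 50, length.out = n_v)
  for (v in seq_len(n_v)) {
    g[v, , 1] <- (v - 1) * 3
    g[v, , 2] <- rr[v] * cos(th)
    g[v, , 3] <- rr[v] * sin(th)
  }
  subt <- structure(list(grid = g, part_index = 1L, u_cols = seq_len(n_c),
                         u_domain = c(0, 1)), class = "sub_surface")
  sht <- make_solid_shell(subt, 3.2)
  expect_equal(unname(panel_dimensions(sht)[1]), 2 * (30 + 50) / 2,
               tolerance = 0.005)
})

test_that("division counts follow Ua/20 and Va/28 with half-up rounding", {
  expect_equal(unname(diamond_pattern(100, 196)$divisions), c(5, 7))
  expect_equal(unname(diamond_pattern(20 + 17, 28 + 17)$divisions), c(2, 2))
  expect_equal(unname(diamond_pattern(90, 150)$divisions), c(5, 5))
  # linear scaling up to rounding
  p1 <- diamond_pattern(100, 196)
  p2 <- diamond_pattern(200, 196)
  expect_equal(unname(p2$divisions[1]), unname(2 * p1$divisions[1]))
  expect_error(diamond_pattern(15, 196), "margin")
})

test_that("the pattern hosts exactly nu x nv disjoint cells inside the frame", {
  pat <- diamond_pattern(100, 196, M = 8, N = 1.6)
  expect_length(pat$cells, 35)
  inner <- pat$inner_rect
  for (cell in pat$cells) {
    expect_true(all(cell[, 1] > inner[1, 1] - 1e-9 &
                      cell[, 1] < inner[2, 1] + 1e-9))
    expect_true(all(cell[, 2] > inner[1, 2] - 1e-9 &
                      cell[, 2] < inner[3, 2] + 1e-9))
  }
  # insetting by N shrinks each diamond by the exact similarity factor
  w <- pat$cell_size[["w"]]; h <- pat$cell_size[["h"]]
  k <- sqrt(1 / (w / 2)^2 + 1 / (h / 2)^2)
  expect_equal(pat$cell_areas_mm2[1], (w * h / 2) * (1 - 1.6 * k)^2,
               tolerance = 1e-9)
  # oversized N collapses the cells with a warning
  expect_warning(pat0 <- diamond_pattern(60, 60, M = 8, N = 12), "collapse")
  expect_length(pat0$cells, 0)
})

test_that("engraving a flat slab cuts matched holes: genus and volume", {
  sub <- flat_sub_surface(w = 100, l = 196, n_c = 51, n_v = 99)
  sh <- make_solid_shell(sub, 3.2)
  pat <- diamond_pattern(100, 196, M = 8, N = 1.6)
  eng <- engrave_shell(sh, pat)
  expect_true(is_watertight(eng$mesh))
  expect_true(is_oriented(eng$mesh))
  expect_equal(eng$hole_count, 35L)
  expect_equal(mesh_genus(eng$mesh), 35)
  v_expect <- (100 * 196 - sum(pat$cell_areas_mm2)) * 3.2
  expect_lt(abs(mesh_volume(eng$mesh) - v_expect) / v_expect, 0.02)
})

test_that("engraving a cylinder strip preserves watertightness and hole count", {
  sub <- cylinder_sub_surface(r = 40, l = 150, arc_deg = 120, n_c = 49, n_v = 81)
  sh <- make_solid_shell(sub, 3.0)
  pd <- panel_dimensions(sh)
  pat <- diamond_pattern(pd[1], pd[2])
  eng <- engrave_shell(sh, pat)
  expect_true(is_watertight(eng$mesh))
  expect_equal(mesh_genus(eng$mesh), length(pat$cells))
  # developable surface: volume drop matches hole prisms within 3%
  v_expect <- mesh_volume(sh$mesh) - sum(pat$cell_areas_mm2) * 3.0
  expect_lt(abs(mesh_volume(eng$mesh) - v_expect) / v_expect, 0.03)
})

test_that("degenerate patterns fall back gracefully", {
  sub <- flat_sub_surface(w = 60, l = 60, n_c = 31, n_v = 31)
  sh <- make_solid_shell(sub, 3)
  expect_warning(pat0 <- diamond_pattern(60, 60, M = 8, N = 12), "collapse")
  expect_warning(out <- engrave_shell(sh, pat0), "unengraved")
  expect_equal(out$hole_count, 0L)
  expect_true(is_watertight(out$mesh))

  # cells smaller than two grid cells: divisions reduced once, then engraved
  coarse <- make_solid_shell(flat_sub_surface(w = 100, l = 196, n_c = 14,
                                              n_v = 21), 3.2)
  pat <- diamond_pattern(100, 196)
  expect_warning(eng <- engrave_shell(coarse, pat), "reduced")
  expect_true(is_watertight(eng$mesh))
  expect_equal(mesh_genus(eng$mesh), eng$hole_count)
})

test_that("the SVG preview lists one polygon per cell plus the frame", {
  pat <- diamond_pattern(100, 196)
  f <- tempfile(fileext = ".svg")
  write_pattern_svg(pat, f)
  svg <- readLines(f)
  expect_equal(sum(grepl("<polygon", svg)), 35 + 2)
})
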