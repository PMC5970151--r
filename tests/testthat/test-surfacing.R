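# Guide extraction, skinning and area measurement.

make_circle_set <- function(radii, xs = NULL, cz = 60, n_u = 64) {
  if (is.null(xs)) xs <- seq(200, 50, length.out = length(radii))
  build_section_set(Map(function(r, x) circle_section(r, 0, cz, x0 = x),
                        radii, xs), n_u = n_u)
}

test_that("guides are the four generatrices of a cylinder", {
  ss <- make_circle_set(rep(40, 6))
  g <- extract_guides(ss)
  expect_true(all(abs(g$z_max[, 3] - 100) < 1e-6))
  expect_true(all(abs(g$z_min[, 3] - 20) < 0.1))
  expect_true(all(abs(g$y_max[, 2] - 40) < 0.1))
  expect_true(all(abs(g$y_min[, 2] + 40) < 0.1))
})

test_that("the z-max guide of a cone is a straight sloped line", {
  radii <- seq(30, 45, length.out = 8)
  ss <- make_circle_set(radii)
  g <- extract_guides(ss)
  # fit z_max(x) linearly; residuals vanish for a straight generatrix
  fit <- stats::lm(g$z_max[, 3] ~ g$z_max[, 1])
  expect_lt(max(abs(stats::residuals(fit))), 0.05)
  expect_equal(unname(stats::coef(fit)[2]), diff(range(radii)) / -150,
               tolerance = 0.01)
})

test_that("skinning identical circles reproduces the cylinder", {
  ss <- make_circle_set(rep(40, 6))
  cs <- skin_surface(ss, extract_guides(ss))
  d <- sqrt(cs$grid[, , 2]^2 + (cs$grid[, , 3] - 60)^2)
  expect_lt(max(abs(d - 40)), 0.2)
  # boundary rows coincide with the input sections
  expect_equal(cs$grid[1, , ], ss$grid[1, , ], tolerance = 1e-9)
  expect_equal(cs$grid[cs$n_v, , ], ss$grid[6, , ], tolerance = 1e-9)
})

test_that("skinning a cone keeps the radius linear in v within 1%", {
  radii <- seq(30, 45, length.out = 8)
  ss <- make_circle_set(radii, xs = seq(200, 50, length.out = 8))
  cs <- skin_surface(ss, extract_guides(ss), n_v = 40)
  r_v <- rowMeans(sqrt(cs$grid[, , 2]^2 + (cs$grid[, , 3] - 60)^2))
  pred <- seq(r_v[1], r_v[40], length.out = 40)
  expect_lt(max(abs(r_v - pred) / pred), 0.01)
})

test_that("three sections suffice; fewer error; twist is detected", {
  ss3 <- make_circle_set(rep(40, 3))
  expect_s3_class(skin_surface(ss3), "covering_surface")
  ss2 <- make_circle_set(rep(40, 2), xs = c(200, 100))
  expect_error(skin_surface(ss2), "3 sections")

  twisted <- make_circle_set(rep(40, 4))
  twisted$grid[3, , ] <- twisted$grid[3, c(33:64, 1:32), ]
  expect_error(skin_surface(twisted), "twist|seam")
})

test_that("surface area matches closed forms and is grid-converged", {
  ss <- make_circle_set(rep(40, 8), xs = seq(200, 50, length.out = 8))
  cs <- skin_surface(ss, n_v = 64)
  expect_equal(surface_area(cs), 2 * pi * 40 * 150 / 100, tolerance = 0.005)

  # refinement study: doubling the sampling changes the area < 0.2%
  ss_f <- make_circle_set(rep(40, 8), xs = seq(200, 50, length.out = 8),
                          n_u = 128)
  cs_f <- skin_surface(ss_f, n_v = 128)
  expect_lt(abs(surface_area(cs_f) - surface_area(cs)) / surface_area(cs),
            0.002)

  # area is invariant under rigid motion and u-seam rotation
  th <- 20 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- cs
  for (c in 1:3) moved$grid[, , c] <- 0
  flat <- matrix(aperm(cs$grid, c(3, 2, 1)), nrow = 3)
  rot <- R %*% flat + c(5, -3, 11)
  moved$grid <- aperm(array(rot, dim = c(3, dim(cs$grid)[2], dim(cs$grid)[1])),
                      c(3, 2, 1))
  expect_equal(surface_area(moved), surface_area(cs), tolerance = 1e-9)
  spun <- cs
  spun$grid <- cs$grid[, c(20:64, 1:19), ]
  expect_equal(surface_area(spun), surface_area(cs), tolerance = 1e-9)
})

test_that("a flat 100 x 260 mm grid measures 260 cm^2", {
  sub <- flat_sub_surface(w = 100, l = 260, n_c = 21, n_v = 53)
  expect_equal(splintforge:::grid_area_mm2(sub$grid, u_periodic = FALSE) / 100,
               260, tolerance = 1e-9)
})
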