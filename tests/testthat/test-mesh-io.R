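# Mesh/curve intake and export, placement validation, topology queries.

test_that("closed solids round-trip through binary STL with exact topology", {
  tet <- make_tetrahedron()
  f <- tempfile(fileext = ".stl")
  write_mesh(tet, f)
  back <- read_mesh(f)
  expect_equal(nrow(back$faces), 4)
  expect_length(boundary_loops(back), 0)
  expect_true(is_watertight(back))

  cube <- make_cube()
  f2 <- tempfile(fileext = ".stl")
  write_mesh(cube, f2)
  back2 <- read_mesh(f2)
  expect_equal(nrow(back2$faces), 12)
  expect_equal(mesh_volume(back2), 1, tolerance = 1e-6)
  # vertex sets agree within the STL float32 tolerance
  sort_rows <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
  expect_equal(sort_rows(back2$vertices), sort_rows(cube$vertices),
               tolerance = 1e-4, ignore_attr = TRUE)
  # read -> write -> read is idempotent on faces
  f3 <- tempfile(fileext = ".stl")
  write_mesh(back2, f3)
  back3 <- read_mesh(f3)
  expect_identical(back3$faces, back2$faces)
})

test_that("write_mesh refuses empty meshes and non-finite coordinates", {
  empty <- trimesh(matrix(0, 0, 3), matrix(integer(0), 0, 3), clean = FALSE)
  expect_error(write_mesh(empty, tempfile()), "empty")
  bad <- make_cube()
  bad$vertices[1, 1] <- NaN
  expect_error(write_mesh(bad, tempfile()), "non-finite")
})

test_that("OBJ and ASCII PLY parse, with fan triangulation of quads", {
  cyl <- make_open_cylinder()
  # write a quad-faced OBJ by hand
  f <- tempfile(fileext = ".obj")
  v <- cyl$vertices
  lines <- c(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]))
  n_theta <- 32
  idx <- function(i, j) (i - 1) * n_theta + ((j - 1) %% n_theta) + 1
  for (i in 1:9) for (j in 1:n_theta) {
    lines <- c(lines, sprintf("f %d %d %d %d", idx(i, j), idx(i + 1, j),
                              idx(i + 1, j + 1), idx(i, j + 1)))
  }
  writeLines(lines, f)
  expect_warning(m <- read_mesh(f), "fan-triangulated")
  expect_equal(nrow(m$faces), 2 * 9 * n_theta)
  expect_length(boundary_loops(m), 2)

  # ASCII PLY of the tetrahedron
  tet <- make_tetrahedron()
  fp <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               sprintf("%g %g %g", tet$vertices[, 1], tet$vertices[, 2],
                       tet$vertices[, 3]),
               sprintf("3 %d %d %d", tet$faces[, 1] - 1, tet$faces[, 2] - 1,
                       tet$faces[, 3] - 1)), fp)
  mp <- read_mesh(fp)
  expect_true(is_watertight(mp))
  expect_equal(abs(mesh_volume(mp)), 1 / 6, tolerance = 1e-9)
})

test_that("unreadable or empty mesh files raise format errors", {
  f <- tempfile(fileext = ".stl")
  file.create(f)
  expect_error(read_mesh(f), "empty")
  writeLines("not a mesh at all", f)
  expect_error(read_mesh(f), "STL")
  expect_error(read_mesh(tempfile(fileext = ".stl")), "not found")
})

test_that("placement report measures axis angle, plane contact and holes", {
  cyl <- quick_limb(length_mm = 200, proximal_radii = c(40, 30),
                    distal_radii = c(40, 30))
  pr <- validate_placement(cyl)
  expect_lt(pr$axis_alignment_deg, 1)
  expect_true(pr$on_plane)
  expect_equal(pr$boundary_loops, 0)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pr30 <- validate_placement(transform_mesh(cyl, rot = R))
  expect_equal(pr30$axis_alignment_deg, 30, tolerance = 0.5)

  holed <- inject_scan_flaws(cyl, list(flaw_spec(100, 90, c(20, 40))))
  prh <- validate_placement(holed)
  expect_equal(prh$boundary_loops, 1)
  expect_true(all(prh$loop_perimeters_mm > 0))
})

test_that("align helper restores the placement convention", {
  cyl <- quick_limb(length_mm = 200, proximal_radii = c(40, 30),
                    distal_radii = c(40, 30))
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- transform_mesh(cyl, rot = R, shift = c(13, -40, 22))
  fixed <- align_to_convention(moved)
  pr <- validate_placement(fixed)
  expect_lt(pr$axis_alignment_deg, 1)
  expect_true(pr$on_plane)
  expect_match(fixed$provenance, "aligned")
})

test_that("curve JSON round-trips; degenerate and crossing curves error", {
  f <- tempfile(fileext = ".json")
  writeLines('{"points": [[10, -40], [10, 40]], "name": "B"}', f)
  cv <- read_curve(f)
  expect_s3_class(cv, "input_curve")
  expect_equal(nrow(cv$points), 2)
  expect_false(cv$may_cross_thumb)

  bent <- input_curve(rbind(c(230, -50), c(230, 0), c(214, 25), c(230, 60)))
  expect_true(bent$may_cross_thumb)

  f1 <- tempfile(fileext = ".json")
  writeLines('{"points": [[5, 5]], "name": "A"}', f1)
  expect_error(read_curve(f1), "at least 2")
  expect_error(input_curve(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersects")

  out <- tempfile(fileext = ".json")
  write_curve(bent, out)
  back <- read_curve(out)
  expect_equal(back$points, bent$points, tolerance = 1e-9)
})

test_that("genus and orientation checks behave on reference solids", {
  cube <- make_cube()
  expect_true(is_oriented(cube))
  expect_equal(mesh_genus(cube), 0)
  two <- merge_meshes(cube, transform_mesh(make_cube(), shift = c(5, 0, 0)))
  expect_true(is_watertight(two))
  expect_equal(mesh_genus(two), 0)
  expect_equal(mesh_volume(two), 2, tolerance = 1e-9)
})
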