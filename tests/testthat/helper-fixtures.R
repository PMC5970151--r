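# Fixture builders shared across the suite. Everything is generated in code;
# no binary data ships with the package.

# closed unit tetrahedron
make_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  trimesh(v, f, clean = FALSE)
}

# axis-aligned unit cube, outward orientation
make_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  trimesh(v, f, clean = FALSE)
}

# open cylinder (no caps) along +X: exactly two boundary loops
make_open_cylinder <- function(r = 10, len = 50, n_theta = 32, n_x = 10) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  xs <- seq(0, len, length.out = n_x)
  v <- cbind(rep(xs, each = n_theta),
             r * cos(rep(th, n_x)), r + r * sin(rep(th, n_x)))
  idx <- function(i, j) (i - 1) * n_theta + ((j - 1) %% n_theta) + 1
  i <- rep(seq_len(n_x - 1), each = n_theta)
  j <- rep(seq_len(n_theta), n_x - 1)
  f <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
             cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  trimesh(v, f, clean = FALSE)
}

# UV sphere centred at the origin
make_uv_sphere <- function(r = 30, n_theta = 48, n_phi = 24) {
  phis <- seq(-pi / 2, pi / 2, length.out = n_phi + 2)
  phis <- phis[2:(n_phi + 1)]
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  v <- do.call(rbind, lapply(phis, function(p)
    cbind(r * cos(p) * cos(th), r * cos(p) * sin(th), r * sin(p))))
  idx <- function(i, j) (i - 1) * n_theta + ((j - 1) %% n_theta) + 1
  i <- rep(seq_len(n_phi - 1), each = n_theta)
  j <- rep(seq_len(n_theta), n_phi - 1)
  f <- rbind(cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1)),
             cbind(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j)))
  s <- nrow(v) + 1; n <- nrow(v) + 2
  v <- rbind(v, c(0, 0, -r), c(0, 0, r))
  j <- seq_len(n_theta)
  f <- rbind(f, cbind(s, idx(1, j + 1), idx(1, j)),
             cbind(n, idx(n_phi, j), idx(n_phi, j + 1)))
  m <- trimesh(v, f, clean = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# analytic perimeter of an ellipse with semi-axes a, b
ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                   0, 2 * pi, rel.tol = 1e-10)$value
}

# a circle in the x = x0 plane as a closed section_curve (first == last point)
circle_section <- function(r, cy, cz, x0 = 100, n = 128,
                           guide = rbind(c(x0, -100), c(x0, 100))) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- cbind(x0, cy + r * cos(th), cz + r * sin(th))
  splintforge:::section_curve(rbind(p, p[1, ]), closed = TRUE,
                              station_index = 1, guide = guide)
}

# flat rectangular sub-surface in the XY plane (covering-surface stand-in)
flat_sub_surface <- function(w = 100, l = 200, n_c = 41, n_v = 81) {
  g <- array(0, c(n_v, n_c, 3))
  xs <- seq(0, w, length.out = n_c)
  ys <- seq(0, l, length.out = n_v)
  g[, , 1] <- matrix(rep(xs, each = n_v), n_v, n_c)
  g[, , 2] <- matrix(rep(ys, times = n_c), n_v, n_c)
  structure(list(grid = g, part_index = 1L, u_cols = seq_len(n_c),
                 u_domain = c(0, 1)), class = "sub_surface")
}

# cylindrical strip sub-surface: arc of angle arc_deg, radius r, length l
cylinder_sub_surface <- function(r = 40, l = 150, arc_deg = 120,
                                 n_c = 33, n_v = 61) {
  th <- seq(0, arc_deg * pi / 180, length.out = n_c)
  xs <- seq(0, l, length.out = n_v)
  g <- array(0, c(n_v, n_c, 3))
  g[, , 1] <- matrix(rep(xs, times = n_c), n_v, n_c)
  g[, , 2] <- matrix(rep(r * cos(th), each = n_v), n_v, n_c)
  g[, , 3] <- matrix(rep(r * sin(th), each = n_v), n_v, n_c)
  structure(list(grid = g, part_index = 1L, u_cols = seq_len(n_c),
                 u_domain = c(0, 1)), class = "sub_surface")
}

# small thumbless limb used where speed matters
quick_limb <- function(...) generate_limb(limb_spec(...), n_x = 80, n_theta = 64)
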