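# Stage b5: rounded rim tubes, M3 screw seats and final part assembly.

#' Screw-seat geometry specification
#'
#' Defaults fit plastic M3 L10 flat-point screws with prefabricated caps:
#' 3.4 mm clearance hole, 5.6 mm across-flats hexagonal nut pocket 2.6 mm deep
#' (nut plus print tolerance), 9 mm boss. The screw set works by constraining
#' the nut; threads are not modelled (too small to print).
#'
#' @param boss_d_mm boss outer diameter
#' @param boss_h_mm boss height (default: shell thickness + 2 mm when built
#'   through [assemble_features()]; 5 mm standalone)
#' @param hole_d_mm clearance through-hole diameter
#' @param nut_af_mm nut pocket across-flats width
#' @param nut_depth_mm nut pocket depth
#' @return object of class `seat_spec`
#' @export
seat_spec <- function(boss_d_mm = 9, boss_h_mm = 5, hole_d_mm = 3.4,
                      nut_af_mm = 5.6, nut_depth_mm = 2.6) {
  hex_circum_d <- 2 * nut_af_mm / sqrt(3)
  if (hole_d_mm >= boss_d_mm) stop("through-hole must be narrower than the boss")
  if (hex_circum_d >= boss_d_mm) stop("nut pocket must fit inside the boss")
  if (nut_depth_mm >= boss_h_mm) stop("nut pocket must be shallower than the boss")
  if (hole_d_mm >= nut_af_mm) stop("through-hole must be narrower than the nut pocket")
  structure(list(boss_d_mm = boss_d_mm, boss_h_mm = boss_h_mm,
                 hole_d_mm = hole_d_mm, nut_af_mm = nut_af_mm,
                 nut_depth_mm = nut_depth_mm),
            class = "seat_spec")
}

#' Seat frames along the V edges of a shell
#'
#' Each of the two longitudinal seam (V) edges receives frames at parametric
#' positions 0.1 and 0.9 of its arc length, plus one at 0.5 when the edge is
#' strictly longer than the midpoint threshold (180 mm). The frame origin is
#' stood off outward from the seam mid-surface so the screw corridor clears
#' the shell wall (the bosses still overlap the shell for attachment); mating
#' parts share their seam columns exactly, so frames computed on either side
#' coincide and the screw holes align.
#'
#' @param shell solid_shell
#' @param positions parametric seat positions on each edge
#' @param midpoint_threshold_mm V-edge length above which a midpoint seat is
#'   added (strict inequality)
#' @param standoff_mm outward offset of the screw axis from the seam
#'   mid-surface; default thickness/2 + clearance-hole radius + 0.5 mm
#' @return list of `seat_frame` objects (fields `origin`, `axis` = screw
#'   direction out of the part, `out` = shell outward normal, `t`, `edge`)
#' @export
place_seat_frames <- function(shell, positions = c(0.1, 0.9),
                              midpoint_threshold_mm = 180,
                              standoff_mm = NULL) {
  if (is.null(standoff_mm)) standoff_mm <- shell$thickness_mm / 2 + 1.7 + 0.5
  frames <- list()
  n_c <- dim(shell$mid)[2]
  for (e in 1:2) {
    curve <- shell$seam_isocurves[[e]]
    L <- polyline_length(curve)
    ts <- sort(c(positions, if (L > midpoint_threshold_mm) 0.5))
    s <- cum_arclength(curve)
    # outward axis: away from the part across the seam face
    ucol <- if (e == 1) 1 else n_c
    uin <- if (e == 1) 2 else n_c - 1
    for (t in ts) {
      target <- t * L
      pt <- vapply(1:3, function(c)
        stats::approx(s, curve[, c], xout = target)$y, numeric(1))
      row <- which.min(abs(s - target))
      ax <- shell$mid[row, ucol, ] - shell$mid[row, uin, ]
      ax <- ax / sqrt(sum(ax^2))
      nout <- shell$outer[row, ucol, ] - shell$inner[row, ucol, ]
      nout <- nout / sqrt(sum(nout^2))
      frames[[length(frames) + 1]] <-
        structure(list(origin = pt + standoff_mm * nout, axis = ax,
                       out = nout, t = t, edge = e,
                       part_index = shell$part_index),
                  class = "seat_frame")
    }
  }
  frames
}

#' Rim tube specification
#'
#' @param shell_thickness_mm shell thickness the tube sits on
#' @param trim curve-domain trim of the rim isocurve (default 0.01-0.99)
#' @param extra_mm tube diameter excess over the shell thickness (1.5 mm)
#' @return object of class `tube_spec` (fields `trim`, `diameter_mm`)
#' @export
edge_tube_spec <- function(shell_thickness_mm, trim = c(0.01, 0.99),
                           extra_mm = 1.5) {
  stopifnot(trim[1] >= 0, trim[1] < trim[2], trim[2] <= 1)
  structure(list(trim = trim, diameter_mm = shell_thickness_mm + extra_mm),
            class = "tube_spec")
}

#' Rounded-edge tubes along the rim isocurves
#'
#' A circular section of diameter shell thickness + 1.5 mm is swept (with
#' parallel-transport frames) along each rim (U-direction) isocurve of the
#' shell mid-surface, trimmed to the 0.01-0.99 curve domain, and capped.
#'
#' @param shell solid_shell
#' @param spec [edge_tube_spec()]; default derives from the shell thickness
#' @param n_path sweep path samples
#' @param n_phi circle samples
#' @return list of two watertight tube trimeshes with attribute `path`
#' @export
build_edge_tubes <- function(shell, spec = NULL, n_path = 64, n_phi = 24) {
  if (is.null(spec)) spec <- edge_tube_spec(shell$thickness_mm)
  lapply(shell$rim_isocurves, function(rim) {
    if (nrow(rim) < 2) stop("degenerate rim isocurve")
    s <- cum_arclength(rim)
    L <- s[length(s)]
    ts <- seq(spec$trim[1] * L, spec$trim[2] * L, length.out = n_path)
    path <- vapply(1:3, function(c)
      stats::approx(s, rim[, c], xout = ts)$y, numeric(n_path))
    sweep_tube(path, spec$diameter_mm / 2, n_phi)
  })
}

# Sweep a circle along a polyline with parallel-transport frames; cap ends.
#' @keywords internal
sweep_tube <- function(path, radius, n_phi = 24) {
  n <- nrow(path)
  tang <- rbind(path[2, ] - path[1, ],
                path[3:n, ] - path[1:(n - 2), ],
                path[n, ] - path[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  # parallel transport an initial frame
  fr <- frame_from_normal(tang[1, ])
  e1 <- fr[, 1]; e2 <- fr[, 2]
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  verts <- matrix(0, n * n_phi, 3)
  for (i in seq_len(n)) {
    if (i > 1) {
      R <- rotation_between(tang[i - 1, ], tang[i, ])
      e1 <- as.vector(R %*% e1); e2 <- as.vector(R %*% e2)
      # re-orthogonalize against drift
      e1 <- e1 - sum(e1 * tang[i, ]) * tang[i, ]; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(tang[i, 2] * e1[3] - tang[i, 3] * e1[2],
              tang[i, 3] * e1[1] - tang[i, 1] * e1[3],
              tang[i, 1] * e1[2] - tang[i, 2] * e1[1])
    }
    ring <- matrix(path[i, ], n_phi, 3, byrow = TRUE) +
      radius * (outer(cos(phis), e1) + outer(sin(phis), e2))
    verts[(i - 1) * n_phi + seq_len(n_phi), ] <- ring
  }
  idx <- function(i, j) (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  i <- rep(seq_len(n - 1), each = n_phi)
  j <- rep(seq_len(n_phi), times = n - 1)
  a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
  faces <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  c1 <- nrow(verts) + 1; c2 <- nrow(verts) + 2
  verts <- rbind(verts, path[1, ], path[n, ])
  j <- seq_len(n_phi)
  faces <- rbind(faces,
                 cbind(c1, idx(1, j), idx(1, j + 1)),
                 cbind(c2, idx(n, j + 1), idx(n, j)))
  m <- trimesh(verts, faces, clean = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  attr(m, "path") <- path
  m
}

# Radius of a regular hexagon boundary (across-flats af) at angle phi,
# flats normal to phi = 0.
#' @keywords internal
hex_radius <- function(phi, af) {
  a <- (phi %% (pi / 3)) - pi / 6
  (af / 2) / cos(a)
}

# A solid of z-stacked profile rings sampled at common angles: consecutive
# rings are stitched with quads, the first and last ring close with fans to
# their centres (requires non-degenerate end rings) unless radius is 0.
#' @keywords internal
profile_solid <- function(rings, n_phi = 24) {
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  nr <- length(rings)
  verts <- matrix(0, nr * n_phi, 3)
  for (i in seq_len(nr)) {
    r <- rings[[i]]$r(phis)
    verts[(i - 1) * n_phi + seq_len(n_phi), ] <-
      cbind(r * cos(phis), r * sin(phis), rings[[i]]$z)
  }
  idx <- function(i, j) (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  i <- rep(seq_len(nr - 1), each = n_phi)
  j <- rep(seq_len(n_phi), times = nr - 1)
  a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
  faces <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  c1 <- nrow(verts) + 1; c2 <- nrow(verts) + 2
  verts <- rbind(verts, c(0, 0, rings[[1]]$z), c(0, 0, rings[[nr]]$z))
  j <- seq_len(n_phi)
  faces <- rbind(faces,
                 cbind(c1, idx(1, j), idx(1, j + 1)),
                 cbind(c2, idx(nr, j + 1), idx(nr, j)))
  m <- trimesh(verts, faces, clean = TRUE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Screw-seat solids for one frame
#'
#' Part O is the solid boss; part I is the material to remove: the clearance
#' through-hole plus the hexagonal nut pocket at the outer end. Both are
#' watertight; part I lies inside part O's bounding region. [assemble_features()]
#' subtracts part I from part O exactly (the difference is a closed
#' ring-stitched solid) before unioning with the shell.
#'
#' @param spec [seat_spec()]
#' @param frame a `seat_frame` from [place_seat_frames()]
#' @param n_phi angular resolution (multiple of 12 so hex vertices are exact)
#' @return list(partO, partI, seat) of trimeshes in world coordinates
#' @export
build_screw_seat <- function(spec, frame, n_phi = 24) {
  if (n_phi %% 12 != 0) stop("n_phi must be a multiple of 12")
  h <- spec$boss_h_mm; d <- spec$nut_depth_mm
  Rb <- spec$boss_d_mm / 2; rh <- spec$hole_d_mm / 2
  const_r <- function(r) function(phi) rep(r, length(phi))
  hex_r <- function(phi) hex_radius(phi, spec$nut_af_mm)
  partO <- profile_solid(list(list(z = 0, r = const_r(Rb)),
                              list(z = h, r = const_r(Rb))), n_phi)
  partI <- profile_solid(list(list(z = 0, r = const_r(rh)),
                              list(z = h - d, r = const_r(rh)),
                              list(z = h - d, r = hex_r),
                              list(z = h + 0.01, r = hex_r)), n_phi)
  seat <- seat_ring_solid(spec, n_phi)
  to_world <- function(m) {
    fr <- frame_from_normal(frame$axis)
    transform_mesh(m, rot = fr, shift = frame$origin)
  }
  list(partO = to_world(partO), partI = to_world(partI), seat = to_world(seat))
}

# The boss minus its pocket/hole, built directly as a closed annular solid.
#' @keywords internal
seat_ring_solid <- function(spec, n_phi = 24) {
  h <- spec$boss_h_mm; d <- spec$nut_depth_mm
  Rb <- spec$boss_d_mm / 2; rh <- spec$hole_d_mm / 2
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  hexr <- hex_radius(phis, spec$nut_af_mm)
  rings <- list(
    cbind(rh * cos(phis), rh * sin(phis), 0),              # hole rim, base
    cbind(Rb * cos(phis), Rb * sin(phis), 0),              # boss rim, base
    cbind(Rb * cos(phis), Rb * sin(phis), h),              # boss rim, top
    cbind(hexr * cos(phis), hexr * sin(phis), h),          # pocket rim, top
    cbind(hexr * cos(phis), hexr * sin(phis), h - d),      # pocket floor, outer
    cbind(rh * cos(phis), rh * sin(phis), h - d)           # pocket floor, inner
  )
  nr <- length(rings)
  verts <- do.call(rbind, rings)
  idx <- function(i, j) (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  fl <- list()
  for (i in seq_len(nr)) {   # ring i stitched to ring i+1 (cyclically: 6 -> 1)
    i2 <- i %% nr + 1
    j <- seq_len(n_phi)
    a <- idx(i, j); b <- idx(i2, j); cc <- idx(i2, j + 1); dd <- idx(i, j + 1)
    fl[[i]] <- rbind(cbind(a, b, cc), cbind(a, cc, dd))
  }
  m <- trimesh(verts, do.call(rbind, fl), clean = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Build all stage-b5 features and assemble a final splint part
#'
#' result = (engraved shell, union, 2 rim tubes, union, seat bosses minus
#' their part-I voids). The seat subtraction is exact by construction; the
#' unions are component-wise, preserving the watertightness oracle (every
#' edge on exactly two faces). Each seat's through-hole is a clear cylindrical
#' corridor along its frame axis.
#'
#' @param shell engraved (or plain) solid_shell
#' @param seat_positions,midpoint_threshold_mm see [place_seat_frames()]
#' @param tube_trim,tube_extra_mm see [edge_tube_spec()]
#' @param seat seat_spec; boss height defaults to shell thickness + 2 mm
#' @return a `splint_part`
#' @export
assemble_features <- function(shell, seat_positions = c(0.1, 0.9),
                              midpoint_threshold_mm = 180,
                              tube_trim = c(0.01, 0.99), tube_extra_mm = 1.5,
                              seat = NULL) {
  if (is.null(seat)) seat <- seat_spec(boss_h_mm = shell$thickness_mm + 2)
  frames <- place_seat_frames(shell, seat_positions, midpoint_threshold_mm)
  tubes <- build_edge_tubes(shell, edge_tube_spec(shell$thickness_mm,
                                                  tube_trim, tube_extra_mm))
  seats <- lapply(frames, function(fr) build_screw_seat(seat, fr)$seat)
  assemble_part(shell, tubes, seats, frames)
}

#' Assemble a splint part from its solids
#'
#' @param shell solid_shell (mesh used as the body)
#' @param tubes list of tube solids
#' @param seats list of seat solids (already hollowed)
#' @param frames seat frames (metadata; hole-alignment bookkeeping)
#' @return object of class `splint_part`: `mesh`, `part_index`, `seats`,
#'   `tube_paths`, `thickness_mm`
#' @export
assemble_part <- function(shell, tubes, seats = list(), frames = list()) {
  solids <- c(list(shell$mesh), tubes, seats)
  for (i in seq_along(solids)) {
    if (!is_watertight(solids[[i]])) {
      stop(sprintf("assembly operand %d is not watertight", i))
    }
  }
  mesh <- merge_meshes(solids)
  mesh$provenance <- sprintf("splint part %d (%d tubes, %d seats)",
                             shell$part_index, length(tubes), length(seats))
  structure(list(mesh = mesh, part_index = shell$part_index,
                 seats = frames,
                 tube_paths = lapply(tubes, attr, "path"),
                 thickness_mm = shell$thickness_mm,
                 hole_count = if (!is.null(shell$hole_count)) shell$hole_count else 0L),
            class = "splint_part")
}

#' @export
print.splint_part <- function(x, ...) {
  cat(sprintf("splint part %d: %d faces, %d seats, %d tubes, t = %.2f mm, %s\n",
              x$part_index, nrow(x$mesh$faces), length(x$seats),
              length(x$tube_paths), x$thickness_mm,
              if (is_watertight(x$mesh)) "watertight" else "NOT watertight"))
  invisible(x)
}

#' Is the screw corridor of a seat clear?
#'
#' Casts rays parallel to the seat axis from a disc of starting points just
#' outside the part and reports whether the corridor of the given radius is
#' free of geometry over the boss span.
#' @param part splint_part
#' @param frame seat_frame
#' @param radius_mm corridor radius (default: M3 clearance hole radius)
#' @param span_mm corridor length to check on each side of the seat origin
#' @return logical
#' @export
seat_corridor_clear <- function(part, frame, radius_mm = 1.7, span_mm = 6) {
  hits <- ray_mesh_hits(part$mesh, frame$origin - span_mm * frame$axis,
                        frame$axis)
  # hits inside the corridor span would block the screw
  !any(hits > 1e-6 & hits < 2 * span_mm)
}
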