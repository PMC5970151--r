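# Stage b2 front half: offset the limb for swelling, plan gradual stations
# between the clinician curves, cut cross-sections, merge dual (palm + thumb)
# sections and repair sections broken by scan holes.

#' Offset a limb mesh along its vertex normals
#'
#' Simulates limb swelling: every vertex is displaced along its area-weighted
#' vertex normal. The default 2 mm matches routine splint practice (2-3 mm).
#'
#' @param mesh closed or holed trimesh
#' @param distance_mm offset distance, 0 to 5 mm
#' @return offset trimesh
#' @export
offset_limb <- function(mesh, distance_mm = 2) {
  if (distance_mm < 0) stop("offset distance must be non-negative")
  if (distance_mm > 5) stop("offset distance above 5 mm is not supported")
  if (distance_mm == 0) return(mesh)
  n <- vertex_normals(mesh)
  out <- mesh
  out$vertices <- mesh$vertices + distance_mm * n
  out$provenance <- paste0(mesh$provenance, sprintf(" | offset %.1f mm", distance_mm))
  attr(out, "limb_spec") <- attr(mesh, "limb_spec")
  out
}

#' A cutting station
#'
#' @param index position in the station list
#' @param blend_t 0 at curve A, 1 at curve B
#' @param guide XY polyline whose vertical (Z) extrusion is the cutting surface
#' @return object of class `station`
#' @export
station <- function(index, blend_t, guide) {
  structure(list(index = index, blend_t = blend_t,
                 guide = matrix(as.numeric(guide), ncol = 2)),
            class = "station")
}

#' Plan gradual cutting stations between curves A and B
#'
#' Interior guide polylines are pointwise linear blends of the two curves
#' after arc-length resampling; their count follows
#' `n_inner = round(L / spacing) - 1` with L the mean distance between the
#' matched curve points. Spacing defaults to 15 mm (practice range 10-20 mm).
#'
#' @param A,B [input_curve] objects (A distal, B proximal)
#' @param spacing_mm target spacing between stations, 10-20 mm
#' @param n_guide number of points per guide polyline
#' @return list of [station], ordered A (t = 0) to B (t = 1)
#' @export
plan_stations <- function(A, B, spacing_mm = 15, n_guide = 64) {
  stopifnot(inherits(A, "input_curve"), inherits(B, "input_curve"))
  if (spacing_mm < 10 || spacing_mm > 20) {
    stop("station spacing must lie in [10, 20] mm")
  }
  if (curves_intersect(A$points, B$points)) stop("curves A and B intersect in XY")
  pa <- resample_polyline(A$points, n_guide)
  pb <- resample_polyline(B$points, n_guide)
  # align traversal directions
  straight <- sum((pa[1, ] - pb[1, ])^2) + sum((pa[n_guide, ] - pb[n_guide, ])^2)
  crossed <- sum((pa[1, ] - pb[n_guide, ])^2) + sum((pa[n_guide, ] - pb[1, ])^2)
  if (crossed < straight) pb <- pb[n_guide:1, , drop = FALSE]
  L <- mean(sqrt(rowSums((pa - pb)^2)))
  if (L < spacing_mm) {
    warning(sprintf("curves are only %.1f mm apart; no interior stations", L))
    return(list(station(1, 0, pa), station(2, 1, pb)))
  }
  n_inner <- round_half_up(L / spacing_mm) - 1
  ts <- seq(0, 1, length.out = n_inner + 2)
  lapply(seq_along(ts), function(i) {
    g <- (1 - ts[i]) * pa + ts[i] * pb
    station(i, ts[i], g)
  })
}

# Drop interior polyline points that are collinear with their neighbours
# (within tol mm of the chord), so straight stations cut as a single plane.
#' @keywords internal
simplify_polyline <- function(g, tol = 1e-6) {
  repeat {
    n <- nrow(g)
    if (n <= 2) return(g)
    keep <- rep(TRUE, n)
    for (i in 2:(n - 1)) {
      a <- g[i - 1, ]; b <- g[i, ]; c <- g[i + 1, ]
      u <- c - a
      L <- sqrt(sum(u^2))
      if (L < 1e-12) next
      dev <- abs((b[1] - a[1]) * u[2] - (b[2] - a[2]) * u[1]) / L
      if (dev < tol) keep[i] <- FALSE
    }
    if (all(keep)) return(g)
    g <- g[keep, , drop = FALSE]
  }
}

#' @keywords internal
curves_intersect <- function(p, q) {
  for (i in seq_len(nrow(p) - 1)) {
    for (j in seq_len(nrow(q) - 1)) {
      if (segments_intersect(p[i, ], p[i + 1, ], q[j, ], q[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' One cross-section curve
#' @keywords internal
section_curve <- function(points, closed, station_index, components = 1,
                          repaired = FALSE, merged = FALSE, guide = NULL) {
  structure(list(points = points, closed = closed,
                 station_index = station_index, components = components,
                 repaired = repaired, merged = merged, guide = guide),
            class = "section_curve")
}

#' @export
print.section_curve <- function(x, ...) {
  cat(sprintf("section @ station %s: %d pts, %s%s%s\n",
              x$station_index, nrow(x$points),
              if (x$closed) "closed" else "OPEN",
              if (x$repaired) ", repaired" else "",
              if (x$merged) ", merged" else ""))
  invisible(x)
}

#' Cut a mesh with a station's vertical cutting surface
#'
#' The guide polyline is extruded along Z; each guide segment contributes the
#' intersection of the mesh with its vertical plane, clipped to the segment
#' extent; the pieces are chained into maximal polylines. A closed chain
#' (endpoints within `closure_tol_mm`) is one loop; scan holes leave open
#' chains; a station across the thumb root yields two closed loops.
#'
#' @param mesh trimesh
#' @param st a [station]
#' @param closure_tol_mm endpoint-coincidence tolerance for the closed flag
#' @param min_length_mm chains shorter than this are numerical debris, dropped
#' @return list of `section_curve`, longest first, each with `components` set
#'   to the number of chains found
#' @export
cut_section <- function(mesh, st, closure_tol_mm = 0.5, min_length_mm = 3) {
  g <- simplify_polyline(st$guide)
  segs3 <- list()
  for (k in seq_len(nrow(g) - 1)) {
    p <- g[k, ]; q <- g[k + 1, ]
    u <- q - p
    len <- sqrt(sum(u^2))
    if (len < 1e-9) next
    u <- u / len
    nrm <- c(-u[2], u[1], 0)
    segs3[[k]] <- plane_strip_cut(mesh, c(p, 0), nrm, c(u, 0), len)
  }
  segs <- do.call(rbind, segs3)
  if (is.null(segs) || nrow(segs) == 0) {
    stop(sprintf("station %s: cutting surface does not intersect the mesh",
                 st$index))
  }
  chains <- chain_segments(segs, tol = 0.05)
  lens <- vapply(chains, polyline_length, numeric(1))
  chains <- chains[lens >= min_length_mm]
  lens <- lens[lens >= min_length_mm]
  if (length(chains) == 0) {
    stop(sprintf("station %s: intersection produced only debris", st$index))
  }
  ord <- order(lens, decreasing = TRUE)
  chains <- chains[ord]
  ncomp <- length(chains)
  lapply(chains, function(ch) {
    gap <- sqrt(sum((ch[1, ] - ch[nrow(ch), ])^2))
    closed <- gap <= closure_tol_mm
    if (closed) ch <- rbind(ch[-nrow(ch), , drop = FALSE], ch[1, ])
    section_curve(ch, closed, st$index, components = ncomp, guide = g)
  })
}

# Intersect mesh triangles with the vertical plane through point p0 (3D) with
# normal nrm, keeping only the part with coordinate s = <pt - p0, u> in
# [0, len]. Returns a 6-column matrix (x1 y1 z1 x2 y2 z2) of segments.
#' @keywords internal
plane_strip_cut <- function(mesh, p0, nrm, u, len) {
  v <- mesh$vertices; f <- mesh$faces
  d <- (v[, 1] - p0[1]) * nrm[1] + (v[, 2] - p0[2]) * nrm[2] + (v[, 3] - p0[3]) * nrm[3]
  d[d == 0] <- 1e-12
  dv <- matrix(d[f], ncol = 3)
  pos <- dv > 0
  np <- rowSums(pos)
  mixed <- which(np == 1 | np == 2)
  if (length(mixed) == 0) return(NULL)
  out <- matrix(0, length(mixed), 6)
  # canonical edge interpolation: lower vertex index first
  edge_cross <- function(i1, i2) {
    sw <- i1 > i2
    tmp <- i1[sw]; i1[sw] <- i2[sw]; i2[sw] <- tmp
    d1 <- d[i1]; d2 <- d[i2]
    t <- d1 / (d1 - d2)
    v[i1, , drop = FALSE] + t * (v[i2, , drop = FALSE] - v[i1, , drop = FALSE])
  }
  fm <- f[mixed, , drop = FALSE]
  pm <- pos[mixed, , drop = FALSE]
  # identify the odd vertex (the one on its own side)
  odd <- integer(length(mixed))
  npm <- np[mixed]
  for (c in 1:3) {
    sel <- (npm == 1 & pm[, c]) | (npm == 2 & !pm[, c])
    odd[sel] <- c
  }
  i_odd <- fm[cbind(seq_len(nrow(fm)), odd)]
  oth1 <- ifelse(odd == 1, fm[, 2], fm[, 1])
  oth2 <- ifelse(odd == 3, fm[, 2], fm[, 3])
  a <- edge_cross(i_odd, oth1)
  b <- edge_cross(i_odd, oth2)
  # clip to s in [0, len]
  sa <- (a[, 1] - p0[1]) * u[1] + (a[, 2] - p0[2]) * u[2]
  sb <- (b[, 1] - p0[1]) * u[1] + (b[, 2] - p0[2]) * u[2]
  lo <- pmin(sa, sb); hi <- pmax(sa, sb)
  keep <- hi > 0 & lo < len
  if (!any(keep)) return(NULL)
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  sa <- sa[keep]; sb <- sb[keep]
  clip_end <- function(pt_from, pt_to, s_from, s_to, bound) {
    t <- (bound - s_from) / (s_to - s_from)
    pt_from + t * (pt_to - pt_from)
  }
  for (r in seq_len(nrow(a))) {
    a0 <- a[r, ]; b0 <- b[r, ]; sa0 <- sa[r]; sb0 <- sb[r]
    if (sa0 < 0) a[r, ] <- clip_end(a0, b0, sa0, sb0, 0)
    else if (sa0 > len) a[r, ] <- clip_end(a0, b0, sa0, sb0, len)
    if (sb0 < 0) b[r, ] <- clip_end(b0, a0, sb0, sa0, 0)
    else if (sb0 > len) b[r, ] <- clip_end(b0, a0, sb0, sa0, len)
  }
  seglen <- sqrt(rowSums((a - b)^2))
  ok <- seglen > 1e-9
  cbind(a, b)[ok, , drop = FALSE]
}

# Chain loose segments into maximal polylines by endpoint proximity.
#' @keywords internal
chain_segments <- function(segs, tol = 0.05) {
  m <- nrow(segs)
  ends <- rbind(segs[, 1:3, drop = FALSE], segs[, 4:6, drop = FALSE])
  used <- rep(FALSE, m)
  chains <- list()
  for (start in seq_len(m)) {
    if (used[start]) next
    used[start] <- TRUE
    chain <- list(segs[start, 1:3], segs[start, 4:6])
    # grow forward then backward
    for (dirn in 1:2) {
      repeat {
        tip <- if (dirn == 1) chain[[length(chain)]] else chain[[1]]
        d2 <- (ends[, 1] - tip[1])^2 + (ends[, 2] - tip[2])^2 + (ends[, 3] - tip[3])^2
        cand <- which(!used[(seq_len(2 * m) - 1) %% m + 1] & d2 < tol^2)
        if (length(cand) == 0) break
        j <- cand[which.min(d2[cand])]
        sid <- (j - 1) %% m + 1
        other <- if (j <= m) segs[sid, 4:6] else segs[sid, 1:3]
        used[sid] <- TRUE
        if (dirn == 1) chain[[length(chain) + 1]] <- other
        else chain <- c(list(other), chain)
      }
    }
    pts <- do.call(rbind, chain)
    chains[[length(chains) + 1]] <- pts
  }
  chains
}

#' Close an unclosed cross-section broken by a scan hole
#'
#' The surviving open path is resampled to `n_points` by arc length and a
#' periodic cubic interpolating curve is fitted through them, bridging the gap
#' smoothly; the result is sampled back to a dense closed loop. Refuses gaps
#' of half the path length or more, where interpolation cannot recreate the
#' original shape and the clinician should move the input curves instead.
#'
#' @param sec a `section_curve`
#' @param n_points number of interpolation points extracted from the path
#' @param n_out number of samples on the regenerated loop
#' @return closed, repaired `section_curve`
#' @export
close_unclosed_section <- function(sec, n_points = 16, n_out = 200) {
  if (sec$closed) return(sec)
  pts <- sec$points
  gap <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  plen <- polyline_length(pts)
  if (gap >= 0.5 * plen) {
    stop(sprintf(
      "station %s: section gap (%.1f mm) is >= 50%% of the path; move the input curves",
      sec$station_index, gap))
  }
  ctrl <- resample_polyline(pts, n_points)
  loop <- periodic_spline_loop(ctrl, n_out = n_out)
  section_curve(rbind(loop, loop[1, ]), closed = TRUE,
                station_index = sec$station_index, components = sec$components,
                repaired = TRUE, merged = sec$merged, guide = sec$guide)
}

#' Merge dual (palm + thumb) cross-sections into one closed curve
#'
#' Exactly two closed loops are joined by a rectangle of width
#' `2 * side_offset_mm` along the centroid-to-centroid line; the outline of
#' the union is smoothed by periodic interpolation. The slim corridor between
#' the loops is what later fixes the thumb. Work happens in the developed
#' coordinates of the station's cutting surface (arc length along the guide,
#' z), which is isometric for a vertical extrusion.
#'
#' @param secs list of `section_curve` from one station
#' @param side_offset_mm per-side corridor half-width (default 5 mm)
#' @param n_ctrl control points for the smoothing interpolation
#' @return a single closed `section_curve` with `merged = TRUE`
#' @export
merge_dual_sections <- function(secs, side_offset_mm = 5, n_ctrl = 120) {
  if (inherits(secs, "section_curve")) return(secs)
  if (length(secs) == 1) return(secs[[1]])
  if (length(secs) > 2) {
    stop("more than two section components; only the dual case is defined")
  }
  if (!all(vapply(secs, `[[`, TRUE, "closed"))) {
    stop("both sections must be closed before merging (repair first)")
  }
  guide <- secs[[1]]$guide
  dev1 <- develop_on_guide(secs[[1]]$points, guide)
  dev2 <- develop_on_guide(secs[[2]]$points, guide)
  l1 <- dev1[-nrow(dev1), , drop = FALSE]
  l2 <- dev2[-nrow(dev2), , drop = FALSE]
  if (polygon_area2d(l1) < 0) l1 <- l1[nrow(l1):1, , drop = FALSE]
  if (polygon_area2d(l2) < 0) l2 <- l2[nrow(l2):1, , drop = FALSE]
  c1 <- polygon_centroid2d(l1); c2 <- polygon_centroid2d(l2)
  d <- c2 - c1
  dl <- sqrt(sum(d^2))
  if (dl < 1e-9) stop("section centroids coincide; cannot bridge")
  d <- d / dl
  pd <- c(-d[2], d[1])
  rect <- rbind(c1 + side_offset_mm * pd, c2 + side_offset_mm * pd,
                c2 - side_offset_mm * pd, c1 - side_offset_mm * pd)
  topoly <- function(m) list(x = m[, 1], y = m[, 2])
  un <- polyclip::polyclip(list(topoly(l1), topoly(l2)), list(topoly(rect)),
                           op = "union")
  if (length(un) == 0) stop("union of dual sections failed")
  areas <- vapply(un, function(p) abs(polygon_area2d(cbind(p$x, p$y))), numeric(1))
  outline <- un[[which.max(areas)]]
  om <- cbind(outline$x, outline$y)
  ctrl <- resample_loop(om, n_ctrl)
  sm <- periodic_spline_loop(ctrl, n_out = 2 * n_ctrl)
  # limit concave corner curvature where the corridor meets the loops, so the
  # skinned surface stays offsetable by the shell thickness without folding
  sm <- fillet_loop(sm, min_radius_mm = 6)
  pts3 <- undevelop_on_guide(sm, guide)
  section_curve(rbind(pts3, pts3[1, ]), closed = TRUE,
                station_index = secs[[1]]$station_index, components = 1,
                repaired = any(vapply(secs, `[[`, TRUE, "repaired")),
                merged = TRUE, guide = guide)
}

# Curvature-limited smoothing of a closed 2D loop: vertices whose local
# circumradius (Menger) falls below min_radius are relaxed toward their
# neighbours until every corner is printable/offsetable.
#' @keywords internal
fillet_loop <- function(pts, min_radius_mm = 6, max_iter = 400) {
  n <- nrow(pts)
  for (it in seq_len(max_iter)) {
    prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
    nxt <- pts[c(2:n, 1), , drop = FALSE]
    a <- sqrt(rowSums((pts - prv)^2))
    b <- sqrt(rowSums((nxt - pts)^2))
    cc <- sqrt(rowSums((nxt - prv)^2))
    cross2 <- (pts[, 1] - prv[, 1]) * (nxt[, 2] - prv[, 2]) -
      (pts[, 2] - prv[, 2]) * (nxt[, 1] - prv[, 1])
    r <- (a * b * cc) / (2 * pmax(abs(cross2), 1e-12))
    sharp <- r < min_radius_mm
    if (!any(sharp)) break
    pts[sharp, ] <- (prv[sharp, , drop = FALSE] + 2 * pts[sharp, , drop = FALSE] +
                       nxt[sharp, , drop = FALSE]) / 4
  }
  pts
}

# 3D variant of fillet_loop (Menger circumradius of consecutive triples).
#' @keywords internal
fillet_loop3d <- function(pts, min_radius_mm = 6, max_iter = 400) {
  n <- nrow(pts)
  for (it in seq_len(max_iter)) {
    prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
    nxt <- pts[c(2:n, 1), , drop = FALSE]
    a <- sqrt(rowSums((pts - prv)^2))
    b <- sqrt(rowSums((nxt - pts)^2))
    cc <- sqrt(rowSums((nxt - prv)^2))
    u <- pts - prv; w <- nxt - prv
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    r <- (a * b * cc) / (2 * pmax(sqrt(rowSums(cr^2)), 1e-12))
    sharp <- r < min_radius_mm
    if (!any(sharp)) break
    pts[sharp, ] <- (prv[sharp, , drop = FALSE] + 2 * pts[sharp, , drop = FALSE] +
                       nxt[sharp, , drop = FALSE]) / 4
  }
  pts
}

# Developed coordinates on a vertical extrusion: (arc length along guide, z).
#' @keywords internal
develop_on_guide <- function(pts3, guide) {
  cs <- cum_arclength(guide)
  s <- numeric(nrow(pts3))
  for (i in seq_len(nrow(pts3))) {
    p <- pts3[i, 1:2]
    best <- Inf; bs <- 0
    for (k in seq_len(nrow(guide) - 1)) {
      a <- guide[k, ]; b <- guide[k + 1, ]
      u <- b - a; L <- sqrt(sum(u^2))
      if (L < 1e-12) next
      t <- clamp(sum((p - a) * u) / L^2, 0, 1)
      proj <- a + t * u
      dd <- sum((p - proj)^2)
      if (dd < best) { best <- dd; bs <- cs[k] + t * L }
    }
    s[i] <- bs
  }
  cbind(s, pts3[, 3])
}

#' @keywords internal
undevelop_on_guide <- function(pts2, guide) {
  cs <- cum_arclength(guide)
  x <- stats::approx(cs, guide[, 1], xout = clamp(pts2[, 1], 0, max(cs)), rule = 2)$y
  y <- stats::approx(cs, guide[, 2], xout = clamp(pts2[, 1], 0, max(cs)), rule = 2)$y
  cbind(x, y, pts2[, 2])
}

#' Section set: aligned closed loops ready for skinning
#'
#' Every station must have contributed exactly one closed loop (after repair
#' and merging). Each loop is resampled to `n_u` points by arc length,
#' oriented counter-clockwise viewed from +X, with its seam (first point)
#' anchored at the loop's topmost (max z) point.
#'
#' @param sections list of single `section_curve` per station, in station order
#' @param n_u points per loop
#' @return object of class `section_set` with `grid` (n_sections x n_u x 3)
#' @export
build_section_set <- function(sections, n_u = 96) {
  bad <- which(vapply(sections, function(s)
    !inherits(s, "section_curve") || !s$closed, TRUE))
  if (length(bad) > 0) {
    stop("stations with open/multiple sections remain: ",
         paste(vapply(sections[bad], function(s)
           if (inherits(s, "section_curve")) s$station_index else NA_integer_,
           numeric(1)), collapse = ", "))
  }
  n_s <- length(sections)
  grid <- array(0, c(n_s, n_u, 3))
  for (i in seq_len(n_s)) {
    pts <- sections[[i]]$points
    if (all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-9)) {
      pts <- pts[-nrow(pts), , drop = FALSE]
    }
    # seam anchor: topmost point
    k <- which.max(pts[, 3])
    pts <- pts[c(k:nrow(pts), seq_len(k - 1)), , drop = FALSE]
    # CCW viewed from +X: positive signed area in (y, z)
    if (polygon_area2d(pts[, c(2, 3)]) < 0) {
      pts <- pts[c(1, nrow(pts):2), , drop = FALSE]
    }
    loop <- resample_loop(pts, n_u)
    # keep every loop offsetable: concave notches (tangential thumb cuts)
    # are relaxed to a printable minimum corner radius
    grid[i, , ] <- fillet_loop3d(loop, min_radius_mm = 6)
  }
  structure(list(grid = grid, n_u = n_u,
                 stations = lapply(sections, `[[`, "station_index"),
                 repaired = vapply(sections, `[[`, TRUE, "repaired"),
                 merged = vapply(sections, `[[`, TRUE, "merged")),
            class = "section_set")
}

#' @export
print.section_set <- function(x, ...) {
  cat(sprintf("section set: %d sections x %d points (%d repaired, %d merged)\n",
              dim(x$grid)[1], dim(x$grid)[2], sum(x$repaired), sum(x$merged)))
  invisible(x)
}

#' Reduce one station's cut to a single closed section
#'
#' The per-station policy of the pipeline: repair open chains caused by scan
#' holes, then merge dual sections; errors out on anything beyond the two
#' defined flaw classes.
#' @param secs list of `section_curve` from [cut_section()]
#' @param repair_points interpolation points used by the repair
#' @param side_offset_mm corridor half-width for the dual merge
#' @return single closed `section_curve`
#' @export
resolve_station_sections <- function(secs, repair_points = 16, side_offset_mm = 5) {
  secs <- lapply(secs, function(s)
    if (s$closed) s else close_unclosed_section(s, n_points = repair_points))
  if (length(secs) == 1) return(secs[[1]])
  merge_dual_sections(secs, side_offset_mm = side_offset_mm)
}
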