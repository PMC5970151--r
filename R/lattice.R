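# Stage b4: the 2D diamond ventilation pattern and parameter-space engraving.
#
# The panel rectangle (Ua x Va, mm) carries an outer frame of margin M and a
# diamond tessellation inside. Holes are the nu x nv whole diamonds of one
# checkerboard family, each inset by the truss margin N; the complementary
# family plus the insets is the printed truss material. Engraving happens in
# panel coordinates: the panel is triangulated analytically around the holes
# (every vertex on the half-cell lattice, so the triangulation is exact and
# conforming), mapped through the shell's (u, v) parameterization onto the
# inner and outer surfaces, and the matched hole rims are stitched with walls.

#' Panel dimensions of a shell part
#'
#' Ua is the mean arc length of the two rim (U-direction) edges of the divided
#' covering surface, Va the mean arc length of its two seam (V-direction)
#' edges; they become the width and length of the 2D pattern rectangle.
#'
#' @param shell a [make_solid_shell()] result
#' @return c(Ua_mm, Va_mm)
#' @export
panel_dimensions <- function(shell) {
  g <- shell$inner
  n_v <- dim(g)[1]; n_c <- dim(g)[2]
  ua <- mean(c(polyline_length(g[1, , ]), polyline_length(g[n_v, , ])))
  va <- mean(c(polyline_length(g[, 1, ]), polyline_length(g[, n_c, ])))
  c(Ua_mm = ua, Va_mm = va)
}

#' Diamond lattice pattern for a panel
#'
#' Division counts follow the panel size: `n_u_div = round(Ua / c_u)` and
#' `n_v_div = round(Va / c_v)` (half up, floored at 1) with the standard
#' coefficients c_u = 20 mm and c_v = 28 mm per division. The inner rectangle
#' (inset by the frame margin M) is tiled by oblique lines into diamonds of
#' size (w, h) = (W/n_u_div, H/n_v_div); the n_u_div x n_v_div whole diamonds
#' become ventilation cells, each inset inward by the truss margin N. A cell
#' whose inset collapses is dropped with a warning (the printed remedy is to
#' enlarge pattern holes by decreasing the divisions).
#'
#' @param Ua,Va panel width and length in mm
#' @param M frame margin in mm (default 8: hosts rim tubes and screw seats)
#' @param N truss margin in mm (default 1.6: about three extrusion widths)
#' @param c_u,c_v mm of panel per division (defaults 20 and 28)
#' @param divisions optional c(nu, nv) overriding the division rule (used by
#'   the engraver's auto-reduction remedy)
#' @return object of class `lattice_pattern`: fields `Ua`, `Va`, `M`, `N`,
#'   `divisions`, `outer_rect`, `inner_rect`, `cells` (list of inset diamond
#'   matrices, CCW), `cell_areas_mm2`, `tile_diamonds`
#' @export
diamond_pattern <- function(Ua, Va, M = 8, N = 1.6, c_u = 20, c_v = 28,
                            divisions = NULL) {
  Ua <- unname(Ua); Va <- unname(Va)
  if (Ua <= 2 * M || Va <= 2 * M) stop("panel smaller than twice the frame margin")
  if (is.null(divisions)) {
    nu <- max(1, round_half_up(Ua / c_u))
    nv <- max(1, round_half_up(Va / c_v))
  } else {
    nu <- max(1, divisions[1]); nv <- max(1, divisions[2])
  }
  W <- Ua - 2 * M; H <- Va - 2 * M
  w <- W / nu; h <- H / nv
  # inward offset of a (w, h) rhombus by N is a scaling about its centre
  k <- sqrt(1 / (w / 2)^2 + 1 / (h / 2)^2)
  scale <- 1 - N * k
  cells <- list(); tiles <- list()
  dropped <- 0
  for (j in seq_len(nv)) {
    for (i in seq_len(nu)) {
      cx <- M + (i - 0.5) * w; cy <- M + (j - 0.5) * h
      tile <- rbind(c(cx + w / 2, cy), c(cx, cy + h / 2),
                    c(cx - w / 2, cy), c(cx, cy - h / 2))
      tiles[[length(tiles) + 1]] <- tile
      if (scale <= 0.05) { dropped <- dropped + 1; next }
      inset <- rbind(c(cx + scale * w / 2, cy), c(cx, cy + scale * h / 2),
                     c(cx - scale * w / 2, cy), c(cx, cy - scale * h / 2))
      cells[[length(cells) + 1]] <- inset
    }
  }
  if (dropped > 0) {
    warning(sprintf("truss margin N = %.2f mm collapses %d cell(s); they stay solid",
                    N, dropped))
  }
  structure(list(Ua = Ua, Va = Va, M = M, N = N,
                 divisions = c(n_u_div = nu, n_v_div = nv),
                 outer_rect = rbind(c(0, 0), c(Ua, 0), c(Ua, Va), c(0, Va)),
                 inner_rect = rbind(c(M, M), c(Ua - M, M), c(Ua - M, Va - M), c(M, Va - M)),
                 cells = cells,
                 cell_areas_mm2 = vapply(cells, function(p) abs(polygon_area2d(p)), numeric(1)),
                 tile_diamonds = tiles,
                 cell_size = c(w = w, h = h), inset_scale = scale),
            class = "lattice_pattern")
}

#' @export
print.lattice_pattern <- function(x, ...) {
  cat(sprintf("diamond pattern: panel %.1f x %.1f mm, divisions %d x %d, %d cells (M = %g, N = %g)\n",
              x$Ua, x$Va, x$divisions[1], x$divisions[2], length(x$cells), x$M, x$N))
  invisible(x)
}

# Conforming triangulation of the panel with diamond holes.
# All vertices live on the half-cell lattice (or are inset-diamond corners),
# generated once each, so the mesh is exact by construction.
# Returns list(pts = 2D vertices, tris = index triples (CCW),
#              hole_loops = list of index vectors (CCW around each hole),
#              outer_loop = index vector CCW around the panel rectangle).
#' @keywords internal
triangulate_panel <- function(pat) {
  nu <- pat$divisions[1]; nv <- pat$divisions[2]
  M <- pat$M
  w <- pat$cell_size[["w"]]; h <- pat$cell_size[["h"]]
  env <- new.env(hash = TRUE)
  pts <- list()
  # lattice points indexed by integer half-steps (i, j): x = M + i*w/2
  lat <- function(i, j) {
    key <- paste0("L", i, "_", j)
    id <- env[[key]]
    if (is.null(id)) {
      pts[[length(pts) + 1]] <<- c(M + i * w / 2, M + j * h / 2)
      id <- length(pts)
      env[[key]] <- id
    }
    id
  }
  free_pt <- function(x, y) {
    pts[[length(pts) + 1]] <<- c(x, y)
    length(pts)
  }
  tris <- list()
  hole_loops <- list()
  # O-family (hole parents): centres at half-odd lattice positions
  s <- pat$inset_scale
  ci <- 0
  for (j in seq_len(nv)) {
    for (i in seq_len(nu)) {
      ci <- ci + 1
      # tile corners (E, N, W, S) on the lattice
      Vo <- c(lat(2 * i, 2 * j - 1), lat(2 * i - 1, 2 * j),
              lat(2 * i - 2, 2 * j - 1), lat(2 * i - 1, 2 * j - 2))
      if (s <= 0.05) {
        # collapsed cell: stays solid, fan the tile
        tris[[length(tris) + 1]] <- rbind(Vo[c(1, 2, 3)], Vo[c(1, 3, 4)])
        next
      }
      cx <- M + (i - 0.5) * w; cy <- M + (j - 0.5) * h
      Vi <- c(free_pt(cx + s * w / 2, cy), free_pt(cx, cy + s * h / 2),
              free_pt(cx - s * w / 2, cy), free_pt(cx, cy - s * h / 2))
      ring <- do.call(rbind, lapply(1:4, function(k) {
        k2 <- k %% 4 + 1
        rbind(c(Vo[k], Vo[k2], Vi[k]), c(Vi[k], Vo[k2], Vi[k2]))
      }))
      tris[[length(tris) + 1]] <- ring
      hole_loops[[length(hole_loops) + 1]] <- Vi
    }
  }
  # E-family (solid diamonds / halves / quarters) at integer lattice positions
  for (j in 0:nv) {
    for (i in 0:nu) {
      east <- i < nu; west <- i > 0; north <- j < nv; south <- j > 0
      pE <- if (east) lat(2 * i + 1, 2 * j) else NULL
      pW <- if (west) lat(2 * i - 1, 2 * j) else NULL
      pN <- if (north) lat(2 * i, 2 * j + 1) else NULL
      pS <- if (south) lat(2 * i, 2 * j - 1) else NULL
      pC <- lat(2 * i, 2 * j)
      quadrant <- function(a, b) {
        if (!is.null(a) && !is.null(b)) tris[[length(tris) + 1]] <<- rbind(c(pC, a, b))
      }
      quadrant(pE, pN); quadrant(pN, pW); quadrant(pW, pS); quadrant(pS, pE)
    }
  }
  # frame: quad strip between the inner-rectangle boundary (with all its
  # lattice points) and the outer rectangle
  inner_ring_keys <- list()
  for (i in 0:(2 * nu)) inner_ring_keys[[length(inner_ring_keys) + 1]] <- c(i, 0)
  for (j in 1:(2 * nv)) inner_ring_keys[[length(inner_ring_keys) + 1]] <- c(2 * nu, j)
  for (i in (2 * nu - 1):0) inner_ring_keys[[length(inner_ring_keys) + 1]] <- c(i, 2 * nv)
  for (j in (2 * nv - 1):1) inner_ring_keys[[length(inner_ring_keys) + 1]] <- c(0, j)
  inner_ring <- vapply(inner_ring_keys, function(ij) lat(ij[1], ij[2]), numeric(1))
  # matching outer points: push the border coordinate out by M
  outer_ring <- vapply(inner_ring, function(id) {
    p <- pts[[id]]
    x <- p[1]; y <- p[2]
    if (abs(y - M) < 1e-9) y <- 0
    if (abs(y - (pat$Va - M)) < 1e-9) y <- pat$Va
    if (abs(x - M) < 1e-9) x <- 0
    if (abs(x - (pat$Ua - M)) < 1e-9) x <- pat$Ua
    free_pt(x, y)
  }, numeric(1))
  nr <- length(inner_ring)
  for (k in seq_len(nr)) {
    k2 <- k %% nr + 1
    a <- inner_ring[k]; b <- inner_ring[k2]
    oa <- outer_ring[k]; ob <- outer_ring[k2]
    pa <- pts[[oa]]; pb <- pts[[ob]]
    if (sum(abs(pa - pb)) < 1e-9) {
      tris[[length(tris) + 1]] <- rbind(c(a, b, oa))       # corner pinch
    } else {
      tris[[length(tris) + 1]] <- rbind(c(a, b, ob), c(a, ob, oa))
    }
  }
  P <- do.call(rbind, pts)
  TR <- do.call(rbind, tris)
  # enforce CCW triangles
  a <- P[TR[, 1], ]; b <- P[TR[, 2], ]; cc <- P[TR[, 3], ]
  cr <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  sw <- cr < 0
  TR[sw, ] <- TR[sw, c(1, 3, 2)]
  list(pts = P, tris = TR, hole_loops = hole_loops, outer_loop = outer_ring)
}

# Bilinear evaluation of a structured grid at panel fractions.
#' @keywords internal
grid_bilinear <- function(g, uf, vf) {
  n_v <- dim(g)[1]; n_c <- dim(g)[2]
  gu <- clamp(uf, 0, 1) * (n_c - 1) + 1
  gv <- clamp(vf, 0, 1) * (n_v - 1) + 1
  i0 <- pmin(floor(gu), n_c - 1); j0 <- pmin(floor(gv), n_v - 1)
  fu <- gu - i0; fv <- gv - j0
  out <- matrix(0, length(uf), 3)
  for (c in 1:3) {
    gc <- g[, , c]
    out[, c] <-
      gc[cbind(j0, i0)] * (1 - fu) * (1 - fv) +
      gc[cbind(j0, i0 + 1)] * fu * (1 - fv) +
      gc[cbind(j0 + 1, i0)] * (1 - fu) * fv +
      gc[cbind(j0 + 1, i0 + 1)] * fu * fv
  }
  out
}

#' Engrave the diamond pattern through a solid shell
#'
#' The panel triangulation is mapped through the shell parameterization onto
#' the inner and outer surfaces, the matched diamond holes are cut, and the
#' hole rims are stitched ("lofted") with wall bands. The outer frame stays
#' solid; the result is watertight with genus equal to the cell count. If any
#' cell spans fewer than two grid cells of the shell parameterization the
#' divisions are reduced by one and the pattern regenerated, once.
#'
#' @param shell solid_shell
#' @param pat lattice_pattern from [diamond_pattern()]
#' @param retry internal: allow one auto-reduction of divisions
#' @return engraved `solid_shell` (fields `pattern`, `hole_count` added)
#' @export
engrave_shell <- function(shell, pat, retry = TRUE) {
  if (length(pat$cells) == 0) {
    warning("pattern has no cells; shell returned unengraved")
    shell$pattern <- pat
    shell$hole_count <- 0L
    return(shell)
  }
  n_v <- dim(shell$inner)[1]; n_c <- dim(shell$inner)[2]
  pitch_u <- pat$Ua / (n_c - 1); pitch_v <- pat$Va / (n_v - 1)
  cw <- pat$cell_size[["w"]] * pat$inset_scale
  ch <- pat$cell_size[["h"]] * pat$inset_scale
  if (cw < 2 * pitch_u || ch < 2 * pitch_v) {
    if (retry) {
      pat2 <- diamond_pattern(pat$Ua, pat$Va, M = pat$M, N = pat$N,
                              divisions = pmax(1, pat$divisions - 1))
      warning("cells too small for the shell grid; divisions reduced by one")
      return(engrave_shell(shell, pat2, retry = FALSE))
    }
    stop("lattice cells remain smaller than two shell grid cells")
  }
  tp <- triangulate_panel(pat)
  uf <- tp$pts[, 1] / pat$Ua
  vf <- tp$pts[, 2] / pat$Va
  Pi <- grid_bilinear(shell$inner, uf, vf)
  Po <- grid_bilinear(shell$outer, uf, vf)
  npan <- nrow(tp$pts)
  V <- rbind(Pi, Po)
  O <- npan
  fl <- list(
    tp$tris[, c(1, 3, 2)],               # inner skin (reversed)
    tp$tris + O                          # outer skin
  )
  band <- function(loop, ccw_material_left) {
    # wall between inner and outer images of a boundary loop
    n <- length(loop)
    a <- loop; b <- loop[c(2:n, 1)]
    if (ccw_material_left) {
      rbind(cbind(a, b, O + b), cbind(a, O + b, O + a))
    } else {
      rbind(cbind(b, a, O + a), cbind(b, O + a, O + b))
    }
  }
  fl[[3]] <- band(tp$outer_loop, TRUE)
  for (hl in tp$hole_loops) fl[[length(fl) + 1]] <- band(hl, FALSE)
  mesh <- trimesh(V, do.call(rbind, fl), clean = TRUE)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  out <- shell
  out$mesh <- mesh
  out$pattern <- pat
  out$hole_count <- length(tp$hole_loops)
  out
}

#' Write a 2D lattice preview as SVG (checkpoint 3)
#'
#' @param pat lattice_pattern
#' @param path output .svg path
#' @export
write_pattern_svg <- function(pat, path) {
  poly_tag <- function(m, fill, stroke) {
    sprintf('  <polygon points="%s" fill="%s" stroke="%s" stroke-width="0.3"/>',
            paste(sprintf("%.3f,%.3f", m[, 1], pat$Va - m[, 2]), collapse = " "),
            fill, stroke)
  }
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.1fmm" height="%.1fmm" viewBox="0 0 %.3f %.3f">',
            pat$Ua, pat$Va, pat$Ua, pat$Va),
    poly_tag(pat$outer_rect, "#d9d9d9", "#555555"),
    poly_tag(pat$inner_rect, "#bfbfbf", "#555555"),
    vapply(pat$cells, poly_tag, "", fill = "#ffffff", stroke = "#333333"),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}
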