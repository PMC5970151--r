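# Stage b3: part-count and thickness rules, circumferential division of the
# covering surface, and watertight solid shell growth.

#' Number of splint parts from the covering-surface area
#'
#' Three equal parts when the area strictly exceeds the reference (260 cm^2,
#' about the covering surface of an adult palm), otherwise the two-part
#' default. The reference is clinician-adjustable; a wrist splint can be
#' forced to the two-part set regardless of area.
#'
#' @param area_cm2 covering-surface area
#' @param reference_area_cm2 division threshold (default 260)
#' @param splint_type "auto" applies the area rule; "wrist_2part" forces 2
#' @return 2 or 3
#' @export
decide_parts <- function(area_cm2, reference_area_cm2 = 260,
                         splint_type = c("auto", "wrist_2part", "forearm")) {
  splint_type <- match.arg(splint_type)
  stopifnot(area_cm2 > 0)
  if (splint_type == "wrist_2part") return(2L)
  if (area_cm2 > reference_area_cm2) 3L else 2L
}

#' Shell thickness from the covering-surface area
#'
#' Linear remap of the supported area domain (150 cm^2, a child's palm, to
#' 600 cm^2, an adult forearm) onto 2.8-4.0 mm of printed thickness, clamped
#' outside the domain. A 300 cm^2 splint gets 3.2 mm.
#'
#' @param area_cm2 covering-surface area
#' @param area_domain_cm2 supported area domain, default c(150, 600)
#' @param thickness_range_mm printed thickness range, default c(2.8, 4.0)
#' @return thickness in mm
#' @export
thickness_from_area <- function(area_cm2, area_domain_cm2 = c(150, 600),
                                thickness_range_mm = c(2.8, 4.0)) {
  stopifnot(all(area_cm2 > 0))
  a <- clamp(area_cm2, area_domain_cm2[1], area_domain_cm2[2])
  t <- (a - area_domain_cm2[1]) / diff(area_domain_cm2)
  thickness_range_mm[1] + t * diff(thickness_range_mm)
}

#' Circumferential division plan
#'
#' Splits the periodic u domain into `n_parts` equal arc-length domains
#' starting at the seam anchor (default: the lateral y-max seam so a two-part
#' split is dorsal/volar).
#'
#' @param n_parts 2 or 3
#' @param seam_anchor_u u fraction in [0, 1) of the first seam
#' @param reference_area_cm2 recorded for provenance
#' @return object of class `division_plan` with `u_domains`
#' @export
division_plan <- function(n_parts, seam_anchor_u = 0, reference_area_cm2 = 260) {
  stopifnot(n_parts %in% c(2L, 3L))
  seam_anchor_u <- seam_anchor_u %% 1
  starts <- (seam_anchor_u + (seq_len(n_parts) - 1) / n_parts) %% 1
  structure(list(n_parts = as.integer(n_parts),
                 u_domains = lapply(seq_len(n_parts), function(i)
                   c(starts[i], starts[i] + 1 / n_parts)),
                 seam_anchor = seam_anchor_u,
                 reference_area_cm2 = reference_area_cm2),
            class = "division_plan")
}

#' Divide a covering surface into isoparametric sub-surfaces
#'
#' Cuts the periodic u direction at the plan's seams. Sections are resampled
#' uniformly by arc length upstream, so equal column counts give equal
#' arc-length extents; adjacent parts share their seam column exactly, which
#' preserves total area and guarantees that mating screw-seat frames coincide.
#'
#' @param cs covering_surface
#' @param plan division_plan
#' @return list of `sub_surface` objects (grid n_v x (n_u/k + 1) x 3)
#' @export
divide_surface <- function(cs, plan) {
  stopifnot(inherits(cs, "covering_surface"), inherits(plan, "division_plan"))
  spans <- vapply(plan$u_domains, function(d) d[2] - d[1], numeric(1))
  if (abs(sum(spans) - 1) > 1e-9) stop("division plan does not partition [0, 1)")
  k <- plan$n_parts
  n_u <- cs$n_u
  if (n_u %% k != 0) stop("n_u must be divisible by the part count")
  s0 <- round(plan$seam_anchor * n_u)
  lapply(seq_len(k), function(i) {
    cols0 <- s0 + (((i - 1) * n_u / k):(i * n_u / k))
    cols <- (cols0 %% n_u) + 1
    # ghost columns let both mating parts evaluate their shared seam normal
    # from the same central stencil, so seat frames coincide exactly
    gp <- ((cols0[1] - 1) %% n_u) + 1
    gn <- ((cols0[length(cols0)] + 1) %% n_u) + 1
    structure(list(grid = cs$grid[, cols, , drop = FALSE],
                   part_index = i, u_cols = cols,
                   ghost_prev = cs$grid[, gp, ], ghost_next = cs$grid[, gn, ],
                   u_domain = plan$u_domains[[i]]),
              class = "sub_surface")
  })
}

#' Area of a sub-surface in cm^2
#' @param sub sub_surface
#' @export
sub_surface_area <- function(sub) grid_area_mm2(sub$grid, u_periodic = FALSE) / 100

#' Grow a watertight solid shell over a sub-surface
#'
#' The outer grid is the inner grid offset along per-point surface normals by
#' the thickness; the four boundary edges are stitched with band surfaces.
#' Inner-surface points keep the swelling clearance because the covering
#' surface was skinned over the offset limb.
#'
#' @param sub sub_surface from [divide_surface()]
#' @param thickness_mm shell thickness (the printable 2.8-4.0 mm range)
#' @return object of class `solid_shell`: fields `mesh` (watertight trimesh),
#'   `inner`, `outer`, `mid` grids, `thickness_mm`, `v_edge_lengths_mm`,
#'   `rim_isocurves`, `seam_isocurves`, `part_index`
#' @export
make_solid_shell <- function(sub, thickness_mm) {
  if (thickness_mm < 2.8 - 1e-9 || thickness_mm > 4.0 + 1e-9) {
    stop("thickness outside the printable 2.8-4.0 mm range")
  }
  g <- sub$grid
  n_v <- dim(g)[1]; n_c <- dim(g)[2]
  raw <- grid_normals(g)
  if (!is.null(sub$ghost_prev)) {
    raw[, 1, ] <- seam_column_normal(g[, 2, ] - sub$ghost_prev, g[, 1, ])
    raw[, n_c, ] <- seam_column_normal(sub$ghost_next - g[, n_c - 1, ],
                                       g[, n_c, ])
  }
  # orient normals away from the limb (outward from the row centroids)
  flip_votes <- 0
  for (v in c(1, n_v)) {
    ctr <- colMeans(g[v, , ])
    d <- g[v, , ] - matrix(ctr, n_c, 3, byrow = TRUE)
    flip_votes <- flip_votes + sum(rowSums(raw[v, , ] * d) < 0)
  }
  nrm <- if (flip_votes > n_c) -raw else raw
  outer <- g + thickness_mm * nrm
  # fold-over check: the offset surface's intrinsic normals must stay parallel
  # (not anti-parallel) to the base surface's, or the offset self-intersected
  no <- grid_normals(outer)
  agree <- rowSums(matrix(no, ncol = 3) * matrix(raw, ncol = 3))
  if (any(agree < 0)) {
    bad <- which(matrix(agree < 0, n_v, n_c), arr.ind = TRUE)[1, ]
    stop(sprintf("normal flip at grid cell (u=%d, v=%d): curvature too high for this thickness",
                 bad[2], bad[1]))
  }
  mesh <- stitch_shell_mesh(g, outer)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mid <- (g + outer) / 2
  v_edges <- list(mid[, 1, ], mid[, n_c, ])
  rims <- list(mid[1, , ], mid[n_v, , ])
  structure(list(mesh = mesh, inner = g, outer = outer, mid = mid,
                 thickness_mm = thickness_mm,
                 v_edge_lengths_mm = vapply(v_edges, polyline_length, numeric(1)),
                 seam_isocurves = v_edges, rim_isocurves = rims,
                 part_index = sub$part_index, u_cols = sub$u_cols),
            class = "solid_shell")
}

#' @export
print.solid_shell <- function(x, ...) {
  cat(sprintf("solid shell part %d: t = %.2f mm, V edges %.1f / %.1f mm, %s\n",
              x$part_index, x$thickness_mm, x$v_edge_lengths_mm[1],
              x$v_edge_lengths_mm[2],
              if (is_watertight(x$mesh)) "watertight" else "NOT watertight"))
  invisible(x)
}

# Normal of one grid column from a supplied u tangent and the column's own
# v tangent (central differences along the rows).
#' @keywords internal
seam_column_normal <- function(tu, col) {
  n_v <- nrow(col)
  tv <- col[c(2:n_v, n_v), ] - col[c(1, 1:(n_v - 1)), ]
  cr <- cbind(tu[, 2] * tv[, 3] - tu[, 3] * tv[, 2],
              tu[, 3] * tv[, 1] - tu[, 1] * tv[, 3],
              tu[, 1] * tv[, 2] - tu[, 2] * tv[, 1])
  len <- sqrt(rowSums(cr^2)); len[len < 1e-12] <- 1
  cr / len
}

# Per-point normals of an open structured grid (central differences inside,
# one-sided at the borders).
#' @keywords internal
grid_normals <- function(g) {
  n_v <- dim(g)[1]; n_c <- dim(g)[2]
  tu <- g[, c(2:n_c, n_c), ] - g[, c(1, 1:(n_c - 1)), ]
  tv <- g[c(2:n_v, n_v), , ] - g[c(1, 1:(n_v - 1)), , ]
  cr <- array(0, dim(g))
  cr[, , 1] <- tu[, , 2] * tv[, , 3] - tu[, , 3] * tv[, , 2]
  cr[, , 2] <- tu[, , 3] * tv[, , 1] - tu[, , 1] * tv[, , 3]
  cr[, , 3] <- tu[, , 1] * tv[, , 2] - tu[, , 2] * tv[, , 1]
  len <- sqrt(cr[, , 1]^2 + cr[, , 2]^2 + cr[, , 3]^2)
  len[len < 1e-12] <- 1
  for (c in 1:3) cr[, , c] <- cr[, , c] / len
  cr
}

# Stitch inner and outer grids plus the four boundary bands into one closed
# triangle mesh.
#' @keywords internal
stitch_shell_mesh <- function(inner, outer) {
  n_v <- dim(inner)[1]; n_c <- dim(inner)[2]
  nv_grid <- n_v * n_c
  vi <- matrix(aperm(inner, c(2, 1, 3)), ncol = 3)  # index = (v-1)*n_c + u
  vo <- matrix(aperm(outer, c(2, 1, 3)), ncol = 3)
  idx <- function(v, u) (v - 1) * n_c + u
  V <- rbind(vi, vo)
  O <- nv_grid
  fl <- list()
  u <- rep(seq_len(n_c - 1), times = n_v - 1)
  v <- rep(seq_len(n_v - 1), each = n_c - 1)
  a <- idx(v, u); b <- idx(v, u + 1); cc <- idx(v + 1, u + 1); d <- idx(v + 1, u)
  # outer skin: one winding; inner skin: the reverse
  fl[[1]] <- rbind(cbind(O + a, O + b, O + cc), cbind(O + a, O + cc, O + d))
  fl[[2]] <- rbind(cbind(a, cc, b), cbind(a, d, cc))
  # rim bands (v = 1 and v = n_v)
  u <- seq_len(n_c - 1)
  a <- idx(1, u); b <- idx(1, u + 1)
  fl[[3]] <- rbind(cbind(a, b, O + b), cbind(a, O + b, O + a))
  a <- idx(n_v, u); b <- idx(n_v, u + 1)
  fl[[4]] <- rbind(cbind(a, O + a, O + b), cbind(a, O + b, b))
  # seam bands (u = 1 and u = n_c)
  v <- seq_len(n_v - 1)
  a <- idx(v, 1); b <- idx(v + 1, 1)
  fl[[5]] <- rbind(cbind(a, O + a, O + b), cbind(a, O + b, b))
  a <- idx(v, n_c); b <- idx(v + 1, n_c)
  fl[[6]] <- rbind(cbind(a, b, O + b), cbind(a, O + b, O + a))
  trimesh(V, do.call(rbind, fl), clean = FALSE)
}
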