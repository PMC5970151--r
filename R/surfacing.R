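# Stage b2 back half: skin the covering surface over the aligned sections and
# measure its area. Sections run along U (circumferential, periodic); the limb
# direction is V (open, curve A to curve B).

#' Longitudinal guide curves through section extremes
#'
#' For each section the four extreme points (max z, min z, max y, min y) are
#' extracted; chained across stations they form the transverse guide family of
#' the skinned surface. Ties break to the smaller u index.
#'
#' @param ss a [build_section_set()] result
#' @return object of class `guide_curves`: list of four n_sections x 3 matrices
#'   `z_max`, `z_min`, `y_max`, `y_min`
#' @export
extract_guides <- function(ss) {
  g <- ss$grid
  n_s <- dim(g)[1]
  pick <- function(fun, col) {
    t(vapply(seq_len(n_s), function(i) {
      vals <- g[i, , col]
      k <- which(vals == fun(vals))[1]
      g[i, k, ]
    }, numeric(3)))
  }
  structure(list(z_max = pick(max, 3), z_min = pick(min, 3),
                 y_max = pick(max, 2), y_min = pick(min, 2)),
            class = "guide_curves")
}

#' Covering surface skinned through the section set
#'
#' Every u column of the section grid is interpolated longitudinally with a
#' natural cubic spline (C1 across stations) and sampled at `n_v` rows; row 1
#' reproduces section A's loop and the last row section B's. The guide curves
#' pass through section extreme points by construction and are reproduced by
#' the surface at the sections; they serve as a QC constraint.
#'
#' @param ss section set (>= 3 sections)
#' @param guides optional [extract_guides()] result, checked for continuity
#' @param n_v number of longitudinal samples (default 8 per section)
#' @return object of class `covering_surface` with `grid` (n_v x n_u x 3);
#'   u is periodic (closed around the limb), v open
#' @export
skin_surface <- function(ss, guides = NULL, n_v = NULL) {
  g <- ss$grid
  n_s <- dim(g)[1]; n_u <- dim(g)[2]
  if (n_s < 3) stop("skinning needs at least 3 sections")
  if (is.null(n_v)) n_v <- 8 * n_s
  check_seam_alignment(ss)
  # longitudinal parameter: normalized mean chord length across stations
  steps <- sqrt(apply((g[-1, , , drop = FALSE] - g[-n_s, , , drop = FALSE])^2,
                      1, sum) / n_u)
  tpar <- c(0, cumsum(steps))
  tpar <- tpar / tpar[length(tpar)]
  vs <- seq(0, 1, length.out = n_v)
  out <- array(0, c(n_v, n_u, 3))
  for (u in seq_len(n_u)) {
    for (c in 1:3) {
      out[, u, c] <- stats::spline(tpar, g[, u, c], xout = vs,
                                   method = "natural")$y
    }
  }
  cs <- structure(list(grid = out, n_u = n_u, n_v = n_v, v_of_section = tpar),
                  class = "covering_surface")
  if (!is.null(guides)) {
    dev <- max(abs(cs$grid[1, , ] - g[1, , ]), abs(cs$grid[n_v, , ] - g[n_s, , ]))
    if (dev > 0.5) stop("surface fails to reproduce its boundary sections")
  }
  cs
}

# The skinned surface is only valid if corresponding points of consecutive
# sections do not wind around each other (no twist). Checked as an angular
# discrepancy about the section centroids.
#' @keywords internal
check_seam_alignment <- function(ss) {
  g <- ss$grid
  n_s <- dim(g)[1]
  for (i in seq_len(n_s - 1)) {
    a <- g[i, , ]; b <- g[i + 1, , ]
    ca <- colMeans(a); cb <- colMeans(b)
    tha <- atan2(a[, 3] - ca[3], a[, 2] - ca[2])
    thb <- atan2(b[, 3] - cb[3], b[, 2] - cb[2])
    dth <- atan2(sin(tha - thb), cos(tha - thb))
    if (stats::median(abs(dth)) > pi / 2) {
      stop(sprintf(
        "twisted correspondence between sections %d and %d; check seam alignment",
        i, i + 1))
    }
  }
  invisible(TRUE)
}

#' @export
print.covering_surface <- function(x, ...) {
  cat(sprintf("covering surface: %d x %d grid, area %.1f cm^2\n",
              x$n_v, x$n_u, surface_area(x)))
  invisible(x)
}

#' Area of a covering surface in cm^2
#'
#' Each grid cell (u periodic, v open) is split into two triangles and the
#' triangle areas are summed.
#' @param cs covering_surface (or a plain n_v x n_u x 3 grid array)
#' @export
surface_area <- function(cs) {
  g <- if (inherits(cs, "covering_surface")) cs$grid else cs
  grid_area_mm2(g, u_periodic = inherits(cs, "covering_surface")) / 100
}

#' @keywords internal
grid_area_mm2 <- function(g, u_periodic = TRUE) {
  n_v <- dim(g)[1]; n_u <- dim(g)[2]
  ui <- if (u_periodic) c(seq_len(n_u), 1) else seq_len(n_u)
  total <- 0
  p00 <- g[-n_v, ui[-length(ui)], , drop = FALSE]
  p01 <- g[-n_v, ui[-1], , drop = FALSE]
  p10 <- g[-1, ui[-length(ui)], , drop = FALSE]
  p11 <- g[-1, ui[-1], , drop = FALSE]
  tri_area <- function(a, b, c) {
    e1 <- b - a; e2 <- c - a
    cr1 <- e1[, , 2] * e2[, , 3] - e1[, , 3] * e2[, , 2]
    cr2 <- e1[, , 3] * e2[, , 1] - e1[, , 1] * e2[, , 3]
    cr3 <- e1[, , 1] * e2[, , 2] - e1[, , 2] * e2[, , 1]
    sum(sqrt(cr1^2 + cr2^2 + cr3^2)) / 2
  }
  tri_area(p00, p10, p11) + tri_area(p00, p11, p01)
}

#' Export a covering surface as a quad-mesh OBJ (checkpoint 2 preview)
#' @param cs covering_surface
#' @param path output .obj path
#' @export
write_surface_obj <- function(cs, path) {
  g <- cs$grid
  n_v <- dim(g)[1]; n_u <- dim(g)[2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# splintforge covering surface (mm)", con)
  idx <- function(v, u) (v - 1) * n_u + ((u - 1) %% n_u) + 1
  for (v in seq_len(n_v)) {
    for (u in seq_len(n_u)) {
      writeLines(sprintf("v %.6f %.6f %.6f", g[v, u, 1], g[v, u, 2], g[v, u, 3]), con)
    }
  }
  for (v in seq_len(n_v - 1)) {
    for (u in seq_len(n_u)) {
      writeLines(sprintf("f %d %d %d %d", idx(v, u), idx(v + 1, u),
                         idx(v + 1, u + 1), idx(v, u + 1)), con)
    }
  }
  invisible(path)
}
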