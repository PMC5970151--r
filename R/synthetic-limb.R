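# Parametric forearm + hand fixture generator.
#
# Stands in for 3D scans: a tapered elliptic loft along +X resting on the XY
# plane, optional thumb branch (capsule blended into the body by a smooth-min
# signed distance field, polygonized by marching tetrahedra so the dual
# cross-section topology near the thumb web-space is real), smooth seeded
# surface noise emulating skin/scan undulation, and injectable scan holes.

#' Specification of a synthetic limb
#'
#' @param length_mm limb length along +X
#' @param proximal_radii c(a, b): ellipse semi-axes (y, z) in mm at x = 0
#'   (body side)
#' @param distal_radii semi-axes at x = length (palm side)
#' @param thumb NULL or list(branch_x_mm, branch_radius_mm, branch_length_mm,
#'   azimuth_deg); azimuth 0 points along +Y, 90 along +Z
#' @param surface_noise_mm amplitude of smooth radial noise (0 = analytic)
#' @param seed integer seed driving the noise field
#' @return object of class `limb_spec`
#' @export
limb_spec <- function(length_mm = 250,
                      proximal_radii = c(45, 34),
                      distal_radii = c(40, 23),
                      thumb = NULL,
                      surface_noise_mm = 0,
                      seed = 1L) {
  stopifnot(length_mm > 0, all(proximal_radii > 0), all(distal_radii > 0),
            surface_noise_mm >= 0)
  if (!is.null(thumb)) {
    need <- c("branch_x_mm", "branch_radius_mm", "branch_length_mm", "azimuth_deg")
    miss <- setdiff(need, names(thumb))
    if (length(miss)) stop("thumb spec lacks: ", paste(miss, collapse = ", "))
    if (thumb$branch_x_mm < 0 || thumb$branch_x_mm > length_mm) {
      stop("thumb branch_x_mm outside [0, length_mm]")
    }
    stopifnot(thumb$branch_radius_mm > 0, thumb$branch_length_mm > 0)
  }
  structure(list(length_mm = length_mm,
                 proximal_radii = as.numeric(proximal_radii),
                 distal_radii = as.numeric(distal_radii),
                 thumb = thumb,
                 surface_noise_mm = surface_noise_mm,
                 seed = as.integer(seed)),
            class = "limb_spec")
}

#' Default thumb branch used by fixtures
#' @param branch_x_mm attachment station along the limb
#' @export
default_thumb <- function(branch_x_mm = 200) {
  list(branch_x_mm = branch_x_mm, branch_radius_mm = 14,
       branch_length_mm = 70, azimuth_deg = 0)
}

# Smoothstep taper between proximal and distal semi-axes.
#' @keywords internal
limb_radii_at <- function(spec, x) {
  t <- clamp(x / spec$length_mm, 0, 1)
  s <- 3 * t^2 - 2 * t^3
  a <- spec$proximal_radii[1] + (spec$distal_radii[1] - spec$proximal_radii[1]) * s
  b <- spec$proximal_radii[2] + (spec$distal_radii[2] - spec$proximal_radii[2]) * s
  cbind(a, b)
}

# Smooth, seeded, low-frequency radial noise field (mm), periodic in theta.
# Returns a function(x, theta) -> delta radius. Low frequency keeps the
# surface self-intersection free, emulating skin/scan undulation rather than
# per-vertex jitter.
#' @keywords internal
limb_noise_field <- function(spec) {
  if (spec$surface_noise_mm <= 0) return(function(x, theta) 0 * x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  nmodes <- 4
  amp <- stats::runif(nmodes, 0.3, 1)
  amp <- amp / sum(amp) * spec$surface_noise_mm
  fx <- sample(1:3, nmodes, replace = TRUE)      # cycles along the limb
  kt <- sample(1:4, nmodes, replace = TRUE)      # lobes around the limb
  phx <- stats::runif(nmodes, 0, 2 * pi)
  pht <- stats::runif(nmodes, 0, 2 * pi)
  L <- spec$length_mm
  function(x, theta) {
    out <- 0
    for (m in seq_len(nmodes)) {
      out <- out + amp[m] * sin(2 * pi * fx[m] * x / L + phx[m]) *
        cos(kt[m] * theta + pht[m])
    }
    out
  }
}

#' Generate a synthetic limb mesh
#'
#' Thumbless specs are lofted analytically (elliptic sections, fan-capped
#' ends), so section perimeters match the analytic ellipse to the mesh
#' discretization error. Specs with a thumb are polygonized from a smooth-min
#' signed distance field by marching tetrahedra, which produces the genuine
#' two-component section topology near the thumb.
#'
#' The mesh is closed, long axis along +X, resting on z = 0; the generating
#' [limb_spec] is attached as attribute `"limb_spec"`.
#'
#' @param spec a [limb_spec]
#' @param n_x number of longitudinal stations (loft path)
#' @param n_theta number of circumferential samples (loft path)
#' @param resolution_mm voxel pitch (marching-tetrahedra path)
#' @return closed [trimesh]
#' @export
generate_limb <- function(spec, n_x = 120, n_theta = 96, resolution_mm = 2.5) {
  mesh <- if (is.null(spec$thumb)) {
    generate_limb_loft(spec, n_x, n_theta)
  } else {
    generate_limb_mt(spec, resolution_mm)
  }
  mesh$vertices[, 3] <- mesh$vertices[, 3] - min(mesh$vertices[, 3])
  mesh$provenance <- "synthetic limb"
  attr(mesh, "limb_spec") <- spec
  mesh
}

#' @keywords internal
generate_limb_loft <- function(spec, n_x, n_theta) {
  noise <- limb_noise_field(spec)
  xs <- seq(0, spec$length_mm, length.out = n_x)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ab <- limb_radii_at(spec, xs)
  X <- matrix(rep(xs, each = n_theta), ncol = 1)
  TH <- rep(th, times = n_x)
  A <- rep(ab[, 1], each = n_theta)
  B <- rep(ab[, 2], each = n_theta)
  dr <- noise(X[, 1], TH)
  bmax <- max(ab[, 2])
  Y <- (A + dr) * cos(TH)
  Z <- bmax + (B + dr) * sin(TH)  # horizontal centreline; rests on z = 0
  v <- cbind(X[, 1], Y, Z)
  # side quads
  fidx <- function(i, j) (i - 1) * n_theta + ((j - 1) %% n_theta) + 1
  i <- rep(seq_len(n_x - 1), each = n_theta)
  j <- rep(seq_len(n_theta), times = n_x - 1)
  q1 <- fidx(i, j); q2 <- fidx(i + 1, j); q3 <- fidx(i + 1, j + 1); q4 <- fidx(i, j + 1)
  faces <- rbind(cbind(q1, q2, q3), cbind(q1, q3, q4))
  # end caps (fans to the section centres)
  c0 <- nrow(v) + 1; cL <- nrow(v) + 2
  v <- rbind(v, c(0, 0, bmax), c(spec$length_mm, 0, bmax))
  j <- seq_len(n_theta)
  capA <- cbind(c0, fidx(1, j), fidx(1, j + 1))
  capB <- cbind(cL, fidx(n_x, j + 1), fidx(n_x, j))
  faces <- rbind(faces, capA, capB)
  m <- trimesh(v, faces, clean = FALSE)
  # orient outward
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Signed distance field of the limb body (+ optional thumb, smooth min).
#' @keywords internal
limb_sdf <- function(spec) {
  noise <- limb_noise_field(spec)
  L <- spec$length_mm
  bmax <- max(spec$proximal_radii[2], spec$distal_radii[2])
  th <- spec$thumb
  seg <- NULL
  if (!is.null(th)) {
    az <- th$azimuth_deg * pi / 180
    ab0 <- limb_radii_at(spec, th$branch_x_mm)
    radial <- c(0, cos(az), sin(az))
    rr <- sqrt((ab0[1] * cos(az))^2 + (ab0[2] * sin(az))^2)
    base <- c(th$branch_x_mm, rr * cos(az), bmax + rr * sin(az))
    dir <- c(1, radial[2], radial[3] + 0.25)
    dir <- (dir / sqrt(sum(dir^2)))
    seg <- list(a = base - 0.6 * th$branch_radius_mm * dir,
                b = base + th$branch_length_mm * dir,
                r = th$branch_radius_mm)
  }
  function(p) {
    x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
    ab <- limb_radii_at(spec, x)
    a <- ab[, 1]; b <- ab[, 2]
    zc <- bmax
    phi <- atan2((z - zc) / b, y / a)
    dr <- noise(x, phi)
    ae <- a + dr; be <- b + dr
    rho <- sqrt((y / ae)^2 + ((z - zc) / be)^2)
    f <- (rho - 1) * pmin(ae, be)
    f <- pmax(f, -x, x - L)          # cap the ends
    if (!is.null(seg)) {
      ab_v <- seg$b - seg$a
      t <- ((x - seg$a[1]) * ab_v[1] + (y - seg$a[2]) * ab_v[2] +
              (z - seg$a[3]) * ab_v[3]) / sum(ab_v^2)
      t <- clamp(t, 0, 1)
      dx <- x - (seg$a[1] + t * ab_v[1])
      dy <- y - (seg$a[2] + t * ab_v[2])
      dz <- z - (seg$a[3] + t * ab_v[3])
      ft <- sqrt(dx^2 + dy^2 + dz^2) - seg$r
      # smooth union
      k <- 6
      h <- clamp(0.5 + 0.5 * (ft - f) / k, 0, 1)
      f <- ft * (1 - h) + f * h - k * h * (1 - h)
    }
    f
  }
}

#' Polygonize an implicit surface by marching tetrahedra
#'
#' Freudenthal 6-tetrahedra decomposition of a regular grid; inside = f < 0.
#' Triangle orientation is fixed per tetrahedron so normals point outward.
#' @param f vectorized function(matrix n x 3) -> signed values
#' @param xr,yr,zr coordinate ranges c(min, max)
#' @param res voxel pitch in mm
#' @return trimesh
#' @export
marching_tetrahedra <- function(f, xr, yr, zr, res = 2.5) {
  xs <- seq(xr[1], xr[2], by = res)
  ys <- seq(yr[1], yr[2], by = res)
  zs <- seq(zr[1], zr[2], by = res)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  P <- cbind(rep(xs, times = ny * nz),
             rep(rep(ys, each = nx), times = nz),
             rep(zs, each = nx * ny))
  F <- f(P)
  F[abs(F) < 1e-9] <- 1e-9  # avoid exactly-zero corners
  lin <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  ci <- rep(seq_len(nx - 1), times = (ny - 1) * (nz - 1))
  cj <- rep(rep(seq_len(ny - 1), each = nx - 1), times = nz - 1)
  ck <- rep(seq_len(nz - 1), each = (nx - 1) * (ny - 1))
  base <- lin(ci, cj, ck)
  o <- c(x = 1, y = nx, z = nx * ny)
  # Freudenthal: six permutations of (x, y, z)
  perms <- list(c("x", "y", "z"), c("x", "z", "y"), c("y", "x", "z"),
                c("y", "z", "x"), c("z", "x", "y"), c("z", "y", "x"))
  # prune to cubes straddling the surface
  c8 <- cbind(base, base + o["x"], base + o["y"], base + o["z"],
              base + o["x"] + o["y"], base + o["x"] + o["z"],
              base + o["y"] + o["z"], base + o["x"] + o["y"] + o["z"])
  neg <- matrix(F[c8] < 0, nrow(c8), 8)
  active <- rowSums(neg) %in% 1:7
  base <- base[active]
  if (length(base) == 0) stop("surface does not intersect the grid")
  all_tri <- vector("list", 6)
  for (pi in seq_along(perms)) {
    pm <- perms[[pi]]
    t1 <- base
    t2 <- t1 + o[pm[1]]
    t3 <- t2 + o[pm[2]]
    t4 <- t3 + o[pm[3]]
    tet <- cbind(t1, t2, t3, t4)
    fv <- matrix(F[tet], ncol = 4)
    inside <- fv < 0
    nin <- rowSums(inside)
    keep <- nin %in% 1:3
    if (!any(keep)) next
    tet <- tet[keep, , drop = FALSE]
    fv <- fv[keep, , drop = FALSE]
    inside <- inside[keep, , drop = FALSE]
    nin <- nin[keep]
    all_tri[[pi]] <- mt_emit(tet, fv, inside, nin, P)
  }
  all_tri <- Filter(Negate(is.null), all_tri)
  V <- do.call(rbind, lapply(all_tri, `[[`, "v"))
  Fc <- do.call(rbind, Map(function(t, off) t$f + off,
                           all_tri,
                           cumsum(c(0, vapply(all_tri, function(t) nrow(t$v), 0)))[seq_along(all_tri)]))
  trimesh(V, Fc, clean = TRUE)
}

# Emit triangles for a batch of straddling tetrahedra (vectorized per case).
# Edge interpolation is canonicalized (lower grid index first) so shared grid
# edges produce bit-identical points in every tetrahedron that touches them.
#' @keywords internal
mt_emit <- function(tet, fv, inside, nin, P) {
  vlist <- list(); flist <- list(); nv <- 0
  push <- function(p1, p2, p3, ins_c, out_c) {
    # orient so normals point from inside to outside
    n <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
               (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
               (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
    flip <- rowSums(n * (out_c - ins_c)) < 0
    tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]
    p3[flip, ] <- tmp
    k <- nrow(p1)
    vlist[[length(vlist) + 1]] <<- rbind(p1, p2, p3)
    flist[[length(flist) + 1]] <<- cbind(nv + seq_len(k), nv + k + seq_len(k),
                                         nv + 2 * k + seq_len(k))
    nv <<- nv + 3 * k
  }
  centil <- function(cols_mask) {
    # centroid of masked corners per tet
    acc <- matrix(0, nrow(tet), 3); cnt <- rowSums(cols_mask)
    for (c in 1:4) {
      idx <- tet[, c]
      w <- cols_mask[, c]
      acc <- acc + P[idx, , drop = FALSE] * w
    }
    acc / cnt
  }
  ci <- centil(inside)
  co <- centil(!inside)
  # case A: exactly one corner on the minority side
  for (corner in 1:4) {
    others <- setdiff(1:4, corner)
    sel1 <- nin == 1 & inside[, corner]             # one inside
    sel3 <- nin == 3 & !inside[, corner]            # one outside
    for (sel in list(sel1, sel3)) {
      if (!any(sel)) next
      sub <- which(sel)
      tt <- tet[sub, , drop = FALSE]; ff <- fv[sub, , drop = FALSE]
      ep <- function(a, b) mt_edge_point(tt, ff, a, b, P)
      p1 <- ep(corner, others[1])
      p2 <- ep(corner, others[2])
      p3 <- ep(corner, others[3])
      push(p1, p2, p3, ci[sub, , drop = FALSE], co[sub, , drop = FALSE])
    }
  }
  # case B: two inside, two outside -> quad (two triangles)
  pairs <- utils::combn(4, 2)
  for (pc in seq_len(ncol(pairs))) {
    aa <- pairs[1, pc]; bb <- pairs[2, pc]
    oo <- setdiff(1:4, c(aa, bb))
    sel <- nin == 2 & inside[, aa] & inside[, bb]
    if (!any(sel)) next
    sub <- which(sel)
    tt <- tet[sub, , drop = FALSE]; ff <- fv[sub, , drop = FALSE]
    ep <- function(a, b) mt_edge_point(tt, ff, a, b, P)
    e1 <- ep(aa, oo[1]); e2 <- ep(aa, oo[2]); e3 <- ep(bb, oo[2]); e4 <- ep(bb, oo[1])
    push(e1, e2, e3, ci[sub, , drop = FALSE], co[sub, , drop = FALSE])
    push(e1, e3, e4, ci[sub, , drop = FALSE], co[sub, , drop = FALSE])
  }
  if (length(vlist) == 0) return(NULL)
  list(v = do.call(rbind, vlist), f = do.call(rbind, flist))
}

# Canonical zero-crossing point on tet edge (a, b): interpolation is always
# evaluated from the lower grid index so coincident edges match exactly.
#' @keywords internal
mt_edge_point <- function(tt, ff, a, b, P) {
  ia <- tt[, a]; ib <- tt[, b]
  fa <- ff[, a]; fb <- ff[, b]
  sw <- ia > ib
  tmp <- ia[sw]; ia[sw] <- ib[sw]; ib[sw] <- tmp
  tmpf <- fa[sw]; fa[sw] <- fb[sw]; fb[sw] <- tmpf
  t <- fa / (fa - fb)
  P[ia, , drop = FALSE] + t * (P[ib, , drop = FALSE] - P[ia, , drop = FALSE])
}

#' @keywords internal
generate_limb_mt <- function(spec, resolution_mm) {
  sdf <- limb_sdf(spec)
  L <- spec$length_mm
  rmax <- max(spec$proximal_radii, spec$distal_radii)
  ext <- 4 * resolution_mm
  th <- spec$thumb
  ymax <- rmax; xmax <- L; zmax <- 2 * rmax
  if (!is.null(th)) {
    reach <- th$branch_length_mm + th$branch_radius_mm
    ymax <- max(ymax, rmax + reach)
    xmax <- max(xmax, th$branch_x_mm + reach)
    zmax <- zmax + reach * 0.5
  }
  marching_tetrahedra(sdf,
                      xr = c(-ext, xmax + ext),
                      yr = c(-ymax - ext, ymax + ext),
                      zr = c(-ext, zmax + ext),
                      res = resolution_mm)
}

#' Specification of one scan flaw (hole)
#'
#' @param center_x_mm longitudinal position of the hole centre
#' @param azimuth_deg circumferential position (0 = +Y, 90 = top)
#' @param extent_mm c(u, v): hole size along the limb and along the
#'   circumference, in mm
#' @param shape "ellipse" or "rect"
#' @export
flaw_spec <- function(center_x_mm, azimuth_deg, extent_mm,
                      shape = c("ellipse", "rect")) {
  shape <- match.arg(shape)
  stopifnot(all(extent_mm > 0), length(extent_mm) == 2)
  structure(list(center_x_mm = center_x_mm, azimuth_deg = azimuth_deg,
                 extent_mm = as.numeric(extent_mm), shape = shape),
            class = "flaw_spec")
}

#' Punch scan holes into a closed mesh
#'
#' Removes the faces whose centroids fall inside each flaw footprint,
#' measured on the surface as (longitudinal mm) x (circumferential arc mm)
#' about the local section centre. Vertex positions are untouched; each flaw
#' adds exactly one boundary loop.
#'
#' @param mesh closed trimesh (limb convention: +X axis, resting on z = 0)
#' @param flaws list of [flaw_spec]
#' @param seed kept for interface stability; flaw footprints are deterministic
#' @return trimesh with holes
#' @export
inject_scan_flaws <- function(mesh, flaws, seed = 1L) {
  if (length(flaws) == 0) return(mesh)
  if (length(boundary_loops(mesh)) > 0) stop("inject_scan_flaws expects a closed mesh")
  v <- mesh$vertices
  f <- mesh$faces
  cent <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
             v[f[, 3], , drop = FALSE]) / 3
  # local section centres by x-binning
  nb <- 24
  br <- seq(min(v[, 1]) - 1e-6, max(v[, 1]) + 1e-6, length.out = nb + 1)
  bin <- cut(v[, 1], br, labels = FALSE)
  ycb <- tapply(v[, 2], bin, mean)
  zcb <- tapply(v[, 3], bin, mean)
  xcb <- tapply(v[, 1], bin, mean)
  yc <- stats::approx(xcb, ycb, xout = cent[, 1], rule = 2)$y
  zc <- stats::approx(xcb, zcb, xout = cent[, 1], rule = 2)$y
  dy <- cent[, 2] - yc; dz <- cent[, 3] - zc
  r <- sqrt(dy^2 + dz^2)
  phi <- atan2(dz, dy)          # 0 = +Y
  drop <- rep(FALSE, nrow(f))
  for (fl in flaws) {
    if (!inherits(fl, "flaw_spec")) stop("flaws must be flaw_spec objects")
    az <- fl$azimuth_deg * pi / 180
    rl <- stats::median(r[abs(cent[, 1] - fl$center_x_mm) < fl$extent_mm[1]])
    if (!is.finite(rl)) stop("flaw footprint misses the mesh in x")
    if (fl$extent_mm[2] > pi * rl) {
      stop("flaw covers more than half the local circumference; unrepairable by design")
    }
    dx <- cent[, 1] - fl$center_x_mm
    dphi <- atan2(sin(phi - az), cos(phi - az))
    darc <- dphi * r
    inside <- if (fl$shape == "ellipse") {
      (dx / (fl$extent_mm[1] / 2))^2 + (darc / (fl$extent_mm[2] / 2))^2 < 1
    } else {
      abs(dx) < fl$extent_mm[1] / 2 & abs(darc) < fl$extent_mm[2] / 2
    }
    if (!any(inside)) stop("flaw footprint contains no faces")
    drop <- drop | inside
  }
  out <- mesh
  out$faces <- f[!drop, , drop = FALSE]
  out <- clean_mesh(out)
  out$provenance <- paste0(mesh$provenance, " + ", length(flaws), " scan flaw(s)")
  attr(out, "limb_spec") <- attr(mesh, "limb_spec")
  out
}

#' Default clinician curves for a synthetic limb
#'
#' Line B sits proximal (body side), line A distal (palm side); both span the
#' mesh's Y extent with margin. With `include_thumb` and a thumbed limb, A
#' bends through the thumb web-space so stations blended near A cut dual
#' (palm + thumb) sections.
#'
#' @param mesh a limb from [generate_limb()]
#' @param include_thumb bend curve A across the thumb web-space
#' @return list(A = input_curve, B = input_curve)
#' @export
default_input_curves <- function(mesh, include_thumb = FALSE) {
  v <- mesh$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  len <- diff(xr)
  ylo <- yr[1] - 5; yhi <- yr[2] + 5
  xB <- xr[1] + 0.10 * len
  xA <- xr[1] + 0.88 * len
  B <- input_curve(rbind(c(xB, ylo), c(xB, yhi)), name = "B")
  spec <- attr(mesh, "limb_spec")
  if (include_thumb && (is.null(spec) || is.null(spec$thumb))) {
    warning("include_thumb requested but the mesh has no thumb; using straight curves")
    include_thumb <- FALSE
  }
  if (!include_thumb) {
    A <- input_curve(rbind(c(xA, ylo), c(xA, yhi)), name = "A")
    return(list(A = A, B = B))
  }
  th <- spec$thumb
  az <- th$azimuth_deg * pi / 180
  sgn <- if (cos(az) >= 0) 1 else -1
  # The straight span of A crosses the web space between the palm edge and the
  # free part of the thumb (producing dual sections); the proximal jog sits on
  # the opposite side, clear of the thumb footprint.
  ys <- if (sgn > 0) c(yhi, 0, -25, -40, ylo) else c(ylo, 0, 25, 40, yhi)
  A <- input_curve(rbind(
    c(xA, ys[1]), c(xA, ys[2]), c(xA - 14, ys[3]), c(xA, ys[4]), c(xA, ys[5])),
    name = "A")
  list(A = A, B = B)
}
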