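# Mesh and curve file intake/export.
#
# Scanned limbs arrive as STL/PLY/OBJ in millimetres. Intake is flaw tolerant:
# holes are reported, never repaired or rejected here — repair happens later at
# the cross-section level.

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Binary and ASCII STL are auto-detected. Duplicate vertices are merged within
#' 1e-6 mm and degenerate faces dropped; boundary loops (scan holes) are kept.
#' Quads and larger polygons in OBJ/PLY are fan-triangulated with a warning.
#'
#' @param path file path
#' @param fmt one of "auto", "stl", "ply", "obj"
#' @return a [trimesh]
#' @export
read_mesh <- function(path, fmt = c("auto", "stl", "ply", "obj")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (file.size(path) == 0) stop("empty mesh file: ", path)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  stl = "stl", ply = "ply", obj = "obj",
                  stop("cannot infer mesh format from extension: ", path))
  }
  m <- switch(fmt,
              stl = read_stl(path),
              ply = read_ply(path),
              obj = read_obj(path))
  m$provenance <- paste0("read from ", basename(path))
  m
}

#' @keywords internal
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsz <- file.size(path)
  is_binary <- length(ntri) == 1 && !is.na(ntri) &&
    fsz == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    raw <- readBin(con, "raw", 50 * ntri)
    idx <- rep(seq_len(ntri) - 1, each = 36) * 50 +
      rep(13:48, times = ntri)  # skip 12 normal bytes, take 36 vertex bytes
    vb <- raw[idx]
    xyz <- readBin(vb, "numeric", n = 9 * ntri, size = 4, endian = "little")
    vm <- matrix(xyz, ncol = 3, byrow = TRUE)
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    return(trimesh(vm, faces))
  }
  # ASCII STL
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex", txt, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop("unreadable STL file: ", path)
  }
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(s) as.numeric(s[2:4]), numeric(3)))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  trimesh(nums, faces)
}

#' @keywords internal
read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) stop("unreadable OBJ file: ", path)
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(s) as.numeric(s[2:4]), numeric(3)))
  polys <- lapply(strsplit(trimws(fl), "\\s+"), function(s) {
    as.integer(vapply(s[-1], function(tok) strsplit(tok, "/")[[1]][1], ""))
  })
  sizes <- lengths(polys)
  if (any(sizes > 3)) warning("non-triangular OBJ faces fan-triangulated")
  tris <- do.call(rbind, lapply(polys, function(p) {
    if (length(p) < 3) return(NULL)
    cbind(p[1], p[2:(length(p) - 1)], p[3:length(p)])
  }))
  trimesh(v, tris)
}

#' @keywords internal
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || txt[1] != "ply") stop("unreadable PLY file: ", path)
  if (!any(grepl("format ascii", txt))) {
    stop("only ASCII PLY is supported: ", path)
  }
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", txt, value = TRUE)[1]))
  hdr_end <- which(txt == "end_header")[1]
  body <- txt[(hdr_end + 1):length(txt)]
  v <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                function(s) as.numeric(s[1:3]), numeric(3)))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  polys <- lapply(fl, function(s) as.integer(s[-1]) + 1L)
  if (any(lengths(polys) > 3)) warning("non-triangular PLY faces fan-triangulated")
  tris <- do.call(rbind, lapply(polys, function(p) {
    if (length(p) < 3) return(NULL)
    cbind(p[1], p[2:(length(p) - 1)], p[3:length(p)])
  }))
  trimesh(v, tris)
}

#' Write a mesh as binary STL
#'
#' @param mesh trimesh with at least one face and finite coordinates
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path) {
  if (!inherits(mesh, "trimesh")) stop("write_mesh expects a trimesh")
  if (nrow(mesh$faces) == 0) stop("refusing to write an empty mesh")
  if (!all(is.finite(mesh$vertices))) stop("mesh has non-finite coordinates")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "splintforge binary STL (mm)"))
  writeBin(hdr[1:80], con)
  ntri <- nrow(mesh$faces)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2)); len[len < 1e-12] <- 1
  nrm <- cr / len
  v <- mesh$vertices; f <- mesh$faces
  # 12 floats + 2-byte attribute per facet
  block <- matrix(0, 12, ntri)
  block[1:3, ] <- t(nrm)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  fbytes <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  fb <- matrix(fbytes, nrow = 48)
  out <- rbind(fb, matrix(as.raw(0), 2, ntri))
  writeBin(as.vector(out), con)
  invisible(path)
}

#' Placement report for an imported limb mesh
#'
#' Checks the input convention — limb long axis along +X, resting on the XY
#' plane — without mutating or rejecting anything. Holes are enumerated, since
#' scan flaws are legitimate input.
#'
#' @param mesh trimesh
#' @param plane_tol_mm tolerance for "resting on the XY plane"
#' @return object of class `placement_report` with fields
#'   `axis_alignment_deg`, `on_plane`, `bbox` (2x3 range matrix),
#'   `boundary_loops` (count) and `loop_perimeters_mm`
#' @export
validate_placement <- function(mesh, plane_tol_mm = 1.0) {
  stopifnot(nrow(mesh$vertices) > 0)
  v <- mesh$vertices
  ax <- robust_principal_axis(v)
  cosang <- abs(ax[1]) / sqrt(sum(ax^2))
  ang <- acos(clamp(cosang, -1, 1)) * 180 / pi
  loops <- boundary_loops(mesh)
  perims <- vapply(loops, function(l) loop_perimeter(mesh, l), numeric(1))
  structure(list(
    axis_alignment_deg = ang,
    on_plane = abs(min(v[, 3])) <= plane_tol_mm,
    bbox = apply(v, 2, range),
    boundary_loops = length(loops),
    loop_perimeters_mm = perims
  ), class = "placement_report")
}

# Robust long axis: an initial PCA axis is refined by fitting a line through
# per-slab medians of the cross-sections, so protruding features (a thumb
# branch) and flaw rims do not skew the estimated limb axis.
#' @keywords internal
robust_principal_axis <- function(v, n_slabs = 20, iters = 3) {
  ax <- stats::prcomp(v, center = TRUE, scale. = FALSE)$rotation[, 1]
  ctr <- colMeans(v)
  basis <- frame_from_normal(ax)  # columns: two transverse axes, then ax
  for (i in seq_len(iters)) {
    rel <- sweep(v, 2, ctr) %*% basis
    along <- rel[, 3]
    br <- seq(min(along) - 1e-9, max(along) + 1e-9, length.out = n_slabs + 1)
    bin <- cut(along, br, labels = FALSE)
    med <- vapply(1:3, function(c)
      tapply(rel[, c], bin, stats::median), numeric(length(unique(bin))))
    med <- med[stats::complete.cases(med), , drop = FALSE]
    if (nrow(med) < 4) break
    # consensus line through the slab medians: slabs contaminated by a
    # protruding branch disagree with the clean majority and are rejected
    ax_local <- consensus_line_direction(med, tol = 2)
    ax <- as.vector(basis %*% ax_local)
    basis <- frame_from_normal(ax)
  }
  ax
}

# Deterministic RANSAC over all point pairs: the direction with the most
# inliers (points within tol of the candidate line), refit on its inliers.
#' @keywords internal
consensus_line_direction <- function(pts, tol = 2) {
  n <- nrow(pts)
  best_in <- NULL; best_cnt <- -1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pts[j, ] - pts[i, ]
      L <- sqrt(sum(d^2))
      if (L < 1e-9) next
      d <- d / L
      rel <- sweep(pts, 2, pts[i, ])
      along <- rel %*% d
      resid <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
      inl <- resid < tol
      if (sum(inl) > best_cnt) { best_cnt <- sum(inl); best_in <- inl }
    }
  }
  sub <- pts[best_in, , drop = FALSE]
  dirn <- stats::prcomp(sub, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (dirn[3] < 0) dirn <- -dirn
  dirn
}

#' @export
print.placement_report <- function(x, ...) {
  cat(sprintf("placement: axis off +X by %.2f deg; on XY plane: %s; %d boundary loop(s)\n",
              x$axis_alignment_deg, x$on_plane, x$boundary_loops))
  if (x$boundary_loops > 0) {
    cat("  loop perimeters (mm):", paste(sprintf("%.1f", x$loop_perimeters_mm),
                                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Optionally align a mesh to the placement convention
#'
#' Rigid transform by principal axes: principal axis to +X, then translated so
#' the bounding box starts at x = 0 and the lowest point sits on z = 0.
#' Logged in the provenance field; never applied implicitly.
#' @param mesh trimesh
#' @return aligned trimesh
#' @export
align_to_convention <- function(mesh) {
  v <- mesh$vertices
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  rot <- t(pc$rotation)
  if (det(rot) < 0) rot[3, ] <- -rot[3, ]
  if (rot[1, 1] < 0) { rot[1, ] <- -rot[1, ]; rot[2, ] <- -rot[2, ] }
  v2 <- sweep(v, 2, colMeans(v)) %*% t(rot)
  v2 <- sweep(v2, 2, c(min(v2[, 1]), 0, min(v2[, 3])))
  mesh$vertices <- v2
  mesh$provenance <- paste0(mesh$provenance, " | aligned to +X / XY plane")
  mesh
}

#' Read a clinician boundary curve from JSON
#'
#' Format: `{"points": [[x, y], ...], "name": "A"}` in millimetres, XY plane.
#' @param path JSON file
#' @return an [input_curve]
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$points)) stop("curve JSON lacks a 'points' field: ", path)
  pts <- obj$points
  if (!is.matrix(pts)) pts <- matrix(as.numeric(unlist(pts)), ncol = 2, byrow = TRUE)
  if (ncol(pts) != 2) stop("curve points must be XY pairs: ", path)
  input_curve(pts, name = if (!is.null(obj$name)) obj$name else "A")
}

#' Construct a boundary curve
#'
#' A curve that bends away from its own chord by more than `bend_tol_mm` is
#' flagged `may_cross_thumb`: a bent distal curve is how the clinician routes
#' line A across the thumb web-space, and stations blended from it can produce
#' dual (palm + thumb) cross-sections downstream.
#'
#' @param points n x 2 matrix of XY points in mm (z = 0 implied), n >= 2
#' @param name "A" (distal, palm side) or "B" (proximal, body side)
#' @param bend_tol_mm chord-deviation threshold for the thumb flag
#' @return object of class `input_curve`
#' @export
input_curve <- function(points, name = c("A", "B"), bend_tol_mm = 10) {
  name <- match.arg(name)
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 2) stop("an input curve needs at least 2 points")
  if (polyline_self_intersects(points)) stop("input curve self-intersects")
  p0 <- points[1, ]; p1 <- points[nrow(points), ]
  ch <- p1 - p0
  chl <- sqrt(sum(ch^2))
  dev <- if (chl < 1e-9) 0 else {
    rel <- sweep(points, 2, p0)
    max(abs(rel[, 1] * ch[2] - rel[, 2] * ch[1]) / chl)
  }
  structure(list(points = points, name = name,
                 may_cross_thumb = dev > bend_tol_mm),
            class = "input_curve")
}

#' Write a curve to JSON
#' @param curve input_curve
#' @param path output path
#' @export
write_curve <- function(curve, path) {
  jsonlite::write_json(list(points = curve$points, name = curve$name),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @export
print.input_curve <- function(x, ...) {
  cat(sprintf("input curve %s: %d points, x span [%.1f, %.1f] mm\n",
              x$name, nrow(x$points), min(x$points[, 1]), max(x$points[, 1])))
  invisible(x)
}
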