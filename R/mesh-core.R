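# Triangle-mesh container and topology queries.
#
# A `trimesh` is the one mesh currency of the whole pipeline: the scanned (or
# synthetic) limb, the offset limb, solid shells, tubes, seats and final parts
# are all trimesh objects in millimetres.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix n x 3, coordinates in millimetres
#' @param faces integer matrix m x 3 of 1-based vertex indices
#' @param provenance free-text note on where the mesh came from
#' @param clean merge duplicate vertices (1e-6 mm) and drop degenerate faces
#' @return object of class `trimesh`
#' @export
trimesh <- function(vertices, faces, provenance = "", clean = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
  }
  m <- structure(list(vertices = vertices, faces = faces, provenance = provenance),
                 class = "trimesh")
  if (clean) m <- clean_mesh(m) else m
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("trimesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox  : [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  nl <- length(boundary_loops(x))
  cat(sprintf("  holes : %d boundary loop(s)%s\n", nl,
              if (x$provenance != "") paste0("  [", x$provenance, "]") else ""))
  invisible(x)
}

#' Merge coincident vertices and drop degenerate faces
#'
#' Vertices closer than `tol` collapse to one; faces with repeated indices or
#' near-zero area are removed. Holes are left untouched.
#' @param mesh trimesh
#' @param tol merge tolerance in mm
#' @return cleaned trimesh
#' @export
clean_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  if (nrow(v) == 0) return(mesh)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f <- mesh$faces
  if (nrow(f) > 0) {
    f <- matrix(map[f], ncol = 3)
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[keep, , drop = FALSE]
    if (nrow(f) > 0) {
      a <- face_areas(list(vertices = v2, faces = f))
      f <- f[a > 1e-10, , drop = FALSE]
    }
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  v3 <- v2[used, , drop = FALSE]
  if (nrow(f) > 0) f <- matrix(match(as.vector(f), used), ncol = 3)
  structure(list(vertices = v3, faces = f, provenance = mesh$provenance),
            class = "trimesh")
}

#' Per-face normal vectors (not normalized; length = 2 * area)
#' @keywords internal
face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Per-face areas in mm^2
#' @param mesh trimesh (or bare list with vertices/faces)
#' @return numeric vector
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  sqrt(rowSums(cr^2)) / 2
}

#' Total surface area in mm^2
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume by the divergence theorem (mm^3)
#'
#' Only meaningful for closed, consistently oriented meshes; sign follows the
#' orientation (outward normals give positive volume).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Area-weighted vertex normals (unit vectors)
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # face normal * 2A: area weighting is built in
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (j in 1:3) {
      acc <- rowsum(cr[, j], mesh$faces[, k])
      n[as.integer(rownames(acc)), j] <- n[as.integer(rownames(acc)), j] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-12] <- 1
  n / len
}

#' All edges of a mesh with face-incidence counts
#'
#' @return list(edges = 2-col matrix of sorted vertex pairs, count = incidences)
#' @keywords internal
edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  es <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(es[, 1], es[, 2])
  tab <- table(key)
  first <- !duplicated(key)
  cnt <- as.integer(tab[match(key[first], names(tab))])
  list(edges = es[first, , drop = FALSE], count = cnt,
       raw = e, key = key, first_key = key[first])
}

#' Is every edge shared by exactly two faces?
#'
#' The watertightness / manifoldness oracle used throughout: a mesh passes iff
#' each undirected edge is incident to exactly 2 faces. A disjoint collection
#' of closed manifolds passes as a whole.
#' @param mesh trimesh
#' @return logical
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  et <- edge_table(mesh)
  all(et$count == 2L)
}

#' Is the mesh consistently oriented?
#'
#' True when no directed edge appears twice (each undirected edge of a closed
#' mesh is traversed once in each direction). Required for signed volumes.
#' @param mesh trimesh
#' @export
is_oriented <- function(mesh) {
  f <- mesh$faces
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  !any(duplicated(paste(de[, 1], de[, 2])))
}

#' Boundary loops of a mesh
#'
#' Boundary edges (incident to exactly one face) are chained into closed
#' loops by walking vertex adjacency. Scan holes appear here.
#'
#' @param mesh trimesh
#' @return list of integer vertex-index cycles (each a loop, first != last)
#' @export
boundary_loops <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(list())
  et <- edge_table(mesh)
  be <- et$edges[et$count == 1L, , drop = FALSE]
  if (nrow(be) == 0) return(list())
  # adjacency among boundary vertices
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (i in seq_len(nrow(be))) {
    a <- be[i, 1]; b <- be[i, 2]
    if (!is.null(visited_edge[[ekey(a, b)]])) next
    loop <- c(a, b)
    visited_edge[[ekey(a, b)]] <- TRUE
    prev <- a; cur <- b
    repeat {
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA
      for (cand in nbrs) {
        if (cand == prev) next
        if (is.null(visited_edge[[ekey(cur, cand)]])) { nxt <- cand; break }
      }
      if (is.na(nxt)) break
      visited_edge[[ekey(cur, nxt)]] <- TRUE
      if (nxt == loop[1]) break
      loop <- c(loop, nxt)
      prev <- cur; cur <- nxt
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Perimeter of a boundary loop in mm
#' @param mesh trimesh
#' @param loop integer vertex cycle as returned by [boundary_loops()]
#' @export
loop_perimeter <- function(mesh, loop) {
  p <- mesh$vertices[c(loop, loop[1]), , drop = FALSE]
  polyline_length(p)
}

#' Connected components of a mesh (by shared vertices)
#' @return integer vector: component id per face
#' @keywords internal
face_components <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(
    rbind(f[, c(1, 2)], f[, c(2, 3)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  comp[f[, 1]]
}

#' Total genus of a closed mesh (summed over components)
#'
#' Uses the Euler characteristic per connected component:
#' genus = (2 - V + E - F) / 2. Only valid for watertight meshes.
#' @param mesh trimesh
#' @return integer total genus
#' @export
mesh_genus <- function(mesh) {
  stopifnot(is_watertight(mesh))
  fc <- face_components(mesh)
  comps <- unique(fc)
  g_tot <- 0
  for (cid in comps) {
    f <- mesh$faces[fc == cid, , drop = FALSE]
    vids <- unique(as.vector(f))
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    es <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    nE <- length(unique(es))
    chi <- length(vids) - nE + nrow(f)
    g_tot <- g_tot + (2 - chi) / 2
  }
  as.integer(round(g_tot))
}

#' Concatenate meshes into one (component-wise union)
#'
#' Vertices are stacked and face indices re-based; no geometric boolean is
#' performed, so overlapping closed solids remain overlapping closed shells
#' (which slicers consume as a union).
#' @param ... trimesh objects (or a single list of them)
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && !inherits(ms[[1]], "trimesh")) ms <- ms[[1]]
  ms <- Filter(function(m) nrow(m$faces) > 0, ms)
  if (length(ms) == 0) stop("no non-empty meshes to merge")
  vs <- lapply(ms, `[[`, "vertices")
  off <- cumsum(c(0, vapply(vs, nrow, 0)))
  fs <- Map(function(m, o) m$faces + o, ms, off[seq_along(ms)])
  structure(list(vertices = do.call(rbind, vs), faces = do.call(rbind, fs),
                 provenance = ms[[1]]$provenance),
            class = "trimesh")
}

#' Rigidly transform a mesh
#' @param mesh trimesh
#' @param rot 3x3 rotation matrix
#' @param shift length-3 translation (mm)
#' @export
transform_mesh <- function(mesh, rot = diag(3), shift = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rot), 2, -shift)
  mesh
}

#' Cast a ray against a mesh
#'
#' Moeller-Trumbore over all faces, vectorized. Used to verify that screw
#' holes are clear corridors.
#' @param mesh trimesh
#' @param origin length-3 ray origin
#' @param dir length-3 ray direction (need not be unit)
#' @return sorted vector of hit parameters t (origin + t * dir), possibly empty
#' @export
ray_mesh_hits <- function(mesh, origin, dir) {
  v <- mesh$vertices; f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  cross_vec <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                    a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                    a[, 1] * b[, 2] - a[, 2] * b[, 1])
  d <- matrix(dir, nrow(f), 3, byrow = TRUE)
  p <- cross_vec(d, e2)
  det <- rowSums(e1 * p)
  ok <- abs(det) > 1e-12
  tvec <- sweep(-v0, 2, -origin)
  u <- rowSums(tvec * p) / det
  q <- cross_vec(tvec, e1)
  vv <- rowSums(d * q) / det
  tt <- rowSums(e2 * q) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt > 1e-9
  sort(tt[hit])
}
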