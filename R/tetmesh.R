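# Tetrahedral part meshes: container, validity checks, boundary extraction,
# patch bookkeeping and penetration checks. All coordinates in mm.

#' Create a tetrahedral part mesh
#'
#' A `tet_part_mesh` is the basic geometric carrier of the pipeline: a named
#' 4-node tetrahedral mesh with named boundary patches (sets of boundary
#' triangles used as muscle attachment areas or coupling surfaces) and named
#' landmarks (femoral-head centre, epicondyles, axis ends, ...).
#'
#' @param name part identifier (e.g. `"femur"`).
#' @param nodes numeric matrix `n x 3` of node coordinates in mm.
#' @param tets integer matrix `m x 4` of tetrahedron connectivity, 1-based.
#'   Every tetrahedron must have positive signed volume.
#' @param patches named list of integer matrices (`k x 3`, 1-based node
#'   triples); every patch facet must be a boundary facet of the mesh.
#' @param landmarks named list of length-3 numeric vectors (mm).
#' @param axis optional list with `origin` and `dir` giving the anatomical
#'   axis of the part; used for cylindrical patch selection.
#' @param validate run full validity checks (positive volumes, patches on
#'   boundary, unique landmark names, finite coordinates).
#' @return an object of class `tet_part_mesh`.
#' @export
tet_part_mesh <- function(name, nodes, tets, patches = list(),
                          landmarks = list(), axis = NULL, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (nrow(tets) > 0L && ncol(tets) != 4L) stop("tets must be an m x 4 matrix")
  mesh <- structure(
    list(name = name, nodes = nodes, tets = tets,
         patches = patches, landmarks = landmarks, axis = axis),
    class = "tet_part_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.tet_part_mesh <- function(x, ...) {
  cat(sprintf("tet_part_mesh '%s': %d nodes, %d tets, %d patches, %d landmarks\n",
              x$name, nrow(x$nodes), nrow(x$tets),
              length(x$patches), length(x$landmarks)))
  invisible(x)
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh a [tet_part_mesh()].
#' @return numeric vector of signed volumes in mm^3.
#' @export
tet_volumes <- function(mesh) {
  if (nrow(mesh$tets) == 0L) return(numeric(0))
  p1 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  a <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - p1
  c_ <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - p1
  # triple product a . (b x c) / 6
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
     a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
     a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# The four facets of tet (n1..n4), each ordered so that its normal points
# outward when the tet volume is positive.
.tet_facet_template <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))

.all_facets <- function(tets) {
  m <- nrow(tets)
  if (m == 0L) return(matrix(integer(0), 0, 3))
  out <- matrix(0L, 4L * m, 3L)
  for (f in 1:4) {
    out[seq.int(f, by = 4L, length.out = m), ] <- tets[, .tet_facet_template[f, ], drop = FALSE]
  }
  out
}

.facet_key <- function(facets) {
  s <- t(apply(facets, 1L, sort))
  paste(s[, 1], s[, 2], s[, 3], sep = "_")
}

#' Boundary facets of a tetrahedral mesh
#'
#' A facet is on the boundary iff it belongs to exactly one tetrahedron.
#' Returned triangles are oriented with outward normals.
#'
#' @param mesh a [tet_part_mesh()].
#' @return integer matrix `k x 3` of boundary triangles.
#' @export
boundary_facets <- function(mesh) {
  facets <- .all_facets(mesh$tets)
  if (nrow(facets) == 0L) return(facets)
  key <- .facet_key(facets)
  counts <- table(key)
  facets[counts[key] == 1L, , drop = FALSE]
}

#' Facet areas, centroids and outward normals
#'
#' @param mesh a [tet_part_mesh()].
#' @param facets integer matrix `k x 3` of node triples.
#' @return list with `area` (mm^2), `centroid` (`k x 3`) and `normal`
#'   (`k x 3`, unit, oriented as given).
#' @export
facet_geometry <- function(mesh, facets) {
  if (nrow(facets) == 0L) {
    return(list(area = numeric(0), centroid = matrix(0, 0, 3), normal = matrix(0, 0, 3)))
  }
  a <- mesh$nodes[facets[, 1], , drop = FALSE]
  b <- mesh$nodes[facets[, 2], , drop = FALSE]
  c_ <- mesh$nodes[facets[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nn <- sqrt(rowSums(n^2))
  list(area = nn / 2, centroid = (a + b + c_) / 3,
       normal = n / pmax(nn, .Machine$double.eps))
}

#' Total area of a named patch
#' @param mesh a [tet_part_mesh()].
#' @param patch patch name.
#' @return area in mm^2.
#' @export
patch_area <- function(mesh, patch) {
  f <- mesh$patches[[patch]]
  if (is.null(f)) stop(sprintf("part '%s' has no patch '%s'", mesh$name, patch))
  sum(facet_geometry(mesh, f)$area)
}

#' Check that the boundary surface is watertight
#'
#' Every edge of the boundary triangulation must be shared by exactly two
#' boundary facets.
#'
#' @param mesh a [tet_part_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  bf <- boundary_facets(mesh)
  if (nrow(bf) == 0L) return(FALSE)
  edges <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}

#' Validate a tet part mesh
#'
#' Checks the container invariants: finite coordinates, positive tet volumes,
#' all patch facets on the boundary, unique landmark names.
#'
#' @param mesh a [tet_part_mesh()].
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_mesh <- function(mesh) {
  if (!all(is.finite(mesh$nodes))) {
    stop(sprintf("part '%s': non-finite node coordinates", mesh$name))
  }
  if (nrow(mesh$tets) > 0L) {
    if (min(mesh$tets) < 1L || max(mesh$tets) > nrow(mesh$nodes)) {
      stop(sprintf("part '%s': connectivity indices out of range", mesh$name))
    }
    v <- tet_volumes(mesh)
    if (any(v <= 0)) {
      stop(sprintf("part '%s': %d tetrahedra with non-positive volume (min %.3g mm^3)",
                   mesh$name, sum(v <= 0), min(v)))
    }
  }
  if (length(mesh$patches)) {
    if (is.null(names(mesh$patches)) || anyDuplicated(names(mesh$patches))) {
      stop(sprintf("part '%s': patches must have unique names", mesh$name))
    }
    bkey <- .facet_key(boundary_facets(mesh))
    for (pn in names(mesh$patches)) {
      pk <- .facet_key(mesh$patches[[pn]])
      if (!all(pk %in% bkey)) {
        stop(sprintf("part '%s': patch '%s' contains non-boundary facets", mesh$name, pn))
      }
    }
  }
  if (length(mesh$landmarks) && anyDuplicated(names(mesh$landmarks))) {
    stop(sprintf("part '%s': duplicate landmark names", mesh$name))
  }
  invisible(TRUE)
}

# Barycentric point-in-tet test for a block of points against one tet.
.points_in_tet <- function(points, verts, tol = 0) {
  T_ <- t(verts[2:4, , drop = FALSE]) - verts[1, ]
  rhs <- t(points) - verts[1, ]
  lam <- solve(T_, rhs)              # 3 x npts barycentric (2..4)
  l1 <- 1 - colSums(lam)
  bar <- rbind(l1, lam)
  apply(bar, 2L, min) > tol
}

#' Points strictly inside a mesh
#'
#' @param mesh a [tet_part_mesh()].
#' @param points `k x 3` matrix.
#' @return logical vector, TRUE where the point lies strictly inside some tet.
#' @export
points_in_mesh <- function(mesh, points) {
  points <- matrix(points, ncol = 3)
  inside <- rep(FALSE, nrow(points))
  if (nrow(points) == 0L || nrow(mesh$tets) == 0L) return(inside)
  bb_lo <- apply(mesh$nodes, 2, min); bb_hi <- apply(mesh$nodes, 2, max)
  cand <- which(points[, 1] >= bb_lo[1] & points[, 1] <= bb_hi[1] &
                  points[, 2] >= bb_lo[2] & points[, 2] <= bb_hi[2] &
                  points[, 3] >= bb_lo[3] & points[, 3] <= bb_hi[3])
  if (!length(cand)) return(inside)
  pts <- points[cand, , drop = FALSE]
  got <- rep(FALSE, length(cand))
  for (e in seq_len(nrow(mesh$tets))) {
    left <- which(!got)
    if (!length(left)) break
    verts <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    hit <- tryCatch(.points_in_tet(pts[left, , drop = FALSE], verts, tol = 1e-12),
                    error = function(e) rep(FALSE, length(left)))
    got[left[hit]] <- TRUE
  }
  inside[cand] <- got
  inside
}

# Distance from points to the boundary surface of a mesh (min distance to
# any boundary triangle), used to measure penetration depth.
.dist_to_boundary <- function(mesh, points) {
  bf <- boundary_facets(mesh)
  d <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(bf))) {
    tri <- mesh$nodes[bf[i, ], , drop = FALSE]
    d <- pmin(d, .point_tri_dist(points, tri))
  }
  d
}

# Vectorised point-to-triangle distance.
.point_tri_dist <- function(points, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c_ <- tri[3, ]
  ab <- b - a; ac <- c_ - a
  ap <- sweep(points, 2, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  abab <- sum(ab * ab); abac <- sum(ab * ac); acac <- sum(ac * ac)
  det <- abab * acac - abac^2
  v <- (acac * d1 - abac * d2) / det
  w <- (abab * d2 - abac * d1) / det
  v <- pmin(pmax(v, 0), 1); w <- pmin(pmax(w, 0), 1)
  s <- v + w
  scale_ <- ifelse(s > 1, 1 / s, 1)
  v <- v * scale_; w <- w * scale_
  proj <- sweep(outer(as.numeric(v), ab) + outer(as.numeric(w), ac), 2, a, `+`)
  # clamped barycentric projection is approximate near edges; refine by also
  # projecting on the three edges
  d <- sqrt(rowSums((points - proj)^2))
  for (seg in list(list(a, b), list(b, c_), list(c_, a))) {
    p0 <- seg[[1]]; e <- seg[[2]] - seg[[1]]
    t_ <- pmin(pmax((sweep(points, 2, p0) %*% e) / sum(e * e), 0), 1)
    pe <- sweep(outer(as.numeric(t_), e), 2, p0, `+`)
    d <- pmin(d, sqrt(rowSums((points - pe)^2)))
  }
  d
}

#' Penetration check between two part meshes
#'
#' Reports nodes of one mesh lying strictly inside the other deeper than
#' `tol`. An empty report means the assembly is acceptable (parts may touch).
#'
#' @param meshA,meshB [tet_part_mesh()] objects.
#' @param tol penetration depth tolerance in mm.
#' @return list with `a_in_b`, `b_in_a` (node index vectors), corresponding
#'   depths, and `ok` (TRUE iff both are empty).
#' @export
check_no_penetration <- function(meshA, meshB, tol = 0.01) {
  one_way <- function(m1, m2) {
    if (nrow(m1$nodes) == 0L || nrow(m2$tets) == 0L) {
      return(list(idx = integer(0), depth = numeric(0)))
    }
    inside <- points_in_mesh(m2, m1$nodes)
    idx <- which(inside)
    if (!length(idx)) return(list(idx = integer(0), depth = numeric(0)))
    depth <- .dist_to_boundary(m2, m1$nodes[idx, , drop = FALSE])
    keep <- depth > tol
    list(idx = idx[keep], depth = depth[keep])
  }
  ab <- one_way(meshA, meshB)
  ba <- one_way(meshB, meshA)
  list(a_in_b = ab$idx, a_depth = ab$depth,
       b_in_a = ba$idx, b_depth = ba$depth,
       ok = length(ab$idx) == 0L && length(ba$idx) == 0L)
}
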