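# Linear-elastic FE solver on 4-node tetrahedra with the boundary machinery
# of the stance model: grounded high-stiffness springs, weak stabilisation
# springs, tendon springs, remote points (distributing or rigid coupling),
# bonded ties by node merging. Units: mm, N, MPa.

#' Tendon spring stiffness from E, A, L
#'
#' `k_total = E * A / L`, split equally over `n_springs` parallel springs
#' (the patellar tendon is modelled with three).
#'
#' @param E Young's modulus (MPa).
#' @param A cross-section area (mm^2).
#' @param L tendon length (mm).
#' @param n_springs number of parallel springs.
#' @return list with `k_total` and `k_per_spring` (N/mm).
#' @export
tendon_spring_stiffness <- function(E, A, L, n_springs = 1L) {
  if (L <= 0) stop("tendon length L must be positive")
  stopifnot(E > 0, A > 0, n_springs >= 1)
  k <- E * A / L
  list(k_total = k, k_per_spring = k / n_springs)
}

# Isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx),
# engineering shear strains.
.elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  G <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * G
  diag(D)[4:6] <- G
  D
}

# Constant strain-displacement matrix of a tet; returns B (6 x 12) and V.
.tet_B <- function(X) {
  A <- cbind(1, X)
  V <- det(A) / 6
  if (!is.finite(V) || abs(V) < 1e-12 * max(abs(X), 1)^3) {
    stop("degenerate tetrahedron (non-positive volume)")
  }
  Cinv <- solve(A)
  g <- Cinv[2:4, , drop = FALSE]   # grad N_i in column i
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    c0 <- 3 * (i - 1)
    b <- g[1, i]; c_ <- g[2, i]; d <- g[3, i]
    B[1, c0 + 1] <- b
    B[2, c0 + 2] <- c_
    B[3, c0 + 3] <- d
    B[4, c0 + 1] <- c_; B[4, c0 + 2] <- b
    B[5, c0 + 2] <- d;  B[5, c0 + 3] <- c_
    B[6, c0 + 1] <- d;  B[6, c0 + 3] <- b
  }
  list(B = B, V = V)
}

#' Element stiffness matrix of a 4-node (constant-strain) tetrahedron
#'
#' @param X `4 x 3` node coordinate matrix (mm).
#' @param material list with `E` (MPa) and `nu`.
#' @return symmetric `12 x 12` matrix (N/mm) with exactly six zero
#'   eigenvalues (rigid-body modes).
#' @export
tet4_stiffness <- function(X, material) {
  bv <- .tet_B(as.matrix(X))
  if (!is.finite(bv$V) || bv$V <= 0) {
    stop("degenerate tetrahedron (non-positive volume)")
  }
  D <- .elastic_D(material$E, material$nu)
  bv$V * t(bv$B) %*% D %*% bv$B
}

# ---------------------------------------------------------------------------
# global assembly

# Weighted least-squares rigid-motion normal matrix of a remote point's
# patch, about the remote location: A = sum_i w_i S_i^T S_i with
# S_i = [I, -skew(r_i)]. The same matrix drives the statically equivalent
# load distribution (its dual), so load transfer and motion recovery are
# energy-consistent.
.remote_A <- function(system, rp) {
  r <- sweep(system$nodes[rp$nodes, , drop = FALSE], 2, rp$location)
  w <- rp$weights
  Swr <- colSums(w * r)
  A22 <- matrix(0, 3, 3)
  for (i in seq_along(w)) {
    A22 <- A22 + w[i] * (sum(r[i, ]^2) * diag(3) - tcrossprod(r[i, ]))
  }
  rbind(cbind(sum(w) * diag(3), -.skew3(Swr)),
        cbind(.skew3(Swr), A22))
}

.endpoint_coef <- function(system, ep, axis) {
  # sparse coefficient vector picking up the endpoint displacement along axis
  if (identical(ep, "ground")) return(list(i = integer(0), x = numeric(0)))
  if (!is.null(ep$remote)) {
    rp <- system$remotes[[ep$remote]]
    if (is.null(rp)) stop(sprintf("unknown remote point '%s'", ep$remote))
    if (identical(rp$coupling, "rigid")) {
      i <- rp$dofs[1:3]
      return(list(i = i, x = axis))
    }
    # distributing coupling: the remote point moves with the weighted
    # least-squares rigid motion of the patch evaluated at the remote
    # location, so springs at an offset remote also feel patch rotation
    q <- solve(.remote_A(system, rp), c(axis, 0, 0, 0))
    qt <- q[1:3]; qw <- q[4:6]
    r <- sweep(system$nodes[rp$nodes, , drop = FALSE], 2, rp$location)
    nodes <- rp$nodes
    i <- as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))
    cf <- t(vapply(seq_along(nodes), function(k) {
      rp$weights[k] * (qt + .cross3(qw, r[k, ]))
    }, numeric(3)))
    return(list(i = i, x = as.vector(t(cf))))
  }
  g <- .global_node(system, ep)
  list(i = 3 * g - 2:0, x = axis[c(1, 2, 3)])
}

.global_node <- function(system, ep) {
  if (!is.null(ep$global)) return(ep$global)
  sel <- system$node_map$part == ep$part & system$node_map$local == ep$node
  g <- system$node_map$global[sel]
  if (length(g) != 1L) stop(sprintf("cannot resolve node %s/%s", ep$part, ep$node))
  g
}

.endpoint_pos <- function(system, ep) {
  if (identical(ep, "ground")) return(NULL)
  if (!is.null(ep$remote)) return(system$remotes[[ep$remote]]$location)
  system$nodes[.global_node(system, ep), ]
}

# Coefficient rows of a spring (one per axis; isotropic springs carry three).
.spring_rows <- function(system, sp, si) {
  axes <- if (sp$type == "isotropic") {
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (!is.null(sp$axis)) {
    list(sp$axis / .norm3(sp$axis))
  } else {
    pa <- .endpoint_pos(system, sp$a); pb <- .endpoint_pos(system, sp$b)
    if (is.null(pa) || is.null(pb)) {
      stop(sprintf("spring %d: axis must be given for grounded springs", si))
    }
    list((pb - pa) / .norm3(pb - pa))
  }
  lapply(axes, function(ax) {
    ca <- .endpoint_coef(system, sp$a, ax)
    cb <- .endpoint_coef(system, sp$b, ax)
    list(i = c(ca$i, cb$i), x = c(ca$x, -cb$x), axis = ax)
  })
}

# Full stiffness = element/base stiffness + rank-one spring terms.
.system_K <- function(system) {
  K <- system$K_base
  ti <- list(); tj <- list(); tx <- list()
  for (sp in system$springs) {
    for (r in sp$rows) {
      ti[[length(ti) + 1L]] <- rep(r$i, length(r$i))
      tj[[length(tj) + 1L]] <- rep(r$i, each = length(r$i))
      tx[[length(tx) + 1L]] <- sp$k * as.vector(outer(r$x, r$x))
    }
  }
  if (length(ti)) {
    K <- K + Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                                  dims = dim(K))
  }
  K
}

#' Move a remote point and refresh the dependent boundary terms
#'
#' Updates the remote location and recomputes the coefficient rows of any
#' spring attached to it (a distributing remote's motion-recovery operator
#' depends on the location), rebuilding the stiffness and invalidating the
#' cached factorisation.
#'
#' @param system an `fe_system`.
#' @param name remote-point name.
#' @param location new location (mm).
#' @return modified system.
#' @export
place_remote <- function(system, name, location) {
  if (is.null(system$remotes[[name]])) stop(sprintf("unknown remote point '%s'", name))
  system$remotes[[name]]$location <- location
  touched <- FALSE
  uses_rp <- function(ep) is.list(ep) && identical(ep$remote, name)
  for (si in seq_along(system$springs)) {
    sp <- system$springs[[si]]
    if (uses_rp(sp$a) || uses_rp(sp$b)) {
      system$springs[[si]]$rows <- .spring_rows(system, sp, si)
      touched <- TRUE
    }
  }
  if (touched) {
    system$K <- Matrix::forceSymmetric(.system_K(system))
    system$cache <- new.env(parent = emptyenv())
  }
  system
}

#' Assemble the global FE system
#'
#' Parts are stacked into one global node set; bonded interfaces are
#' realised by merging coincident nodes of tied part pairs (conforming
#' meshes). Remote points couple a location to a surface patch: a
#' `distributing` remote transfers statically equivalent loads and reads
#' back the area-weighted mean patch displacement (no artificial
#' stiffening); a `rigid` remote constrains the patch to move as a rigid
#' body with 6 auxiliary degrees of freedom. Springs (uniaxial or
#' isotropic) connect nodes, remote points and the ground and add rank-1 or
#' rank-3 stiffness terms.
#'
#' @param parts named list of [tet_part_mesh()] objects.
#' @param materials named list part -> list(E, nu).
#' @param ties list of bonded interfaces: `list(a =, b =, a_patch = NULL,
#'   tol = 1e-6)`. Coincident nodes of parts `a` and `b` (optionally
#'   restricted to patch `a_patch` of `a`) are merged; if `a_patch` is given
#'   and some of its nodes find no partner within `tol`, an error lists the
#'   orphan nodes.
#' @param springs list of spring specs: `list(a =, b =, k =, type =
#'   c("uniaxial", "isotropic"), axis = NULL, group = "", label = "")` where
#'   endpoints are `list(part=, node=)`, `list(remote=)` or `"ground"`.
#'   `axis` defaults to the line between the endpoint positions.
#' @param remote_points named list: `list(location =, part =, patch =,
#'   coupling = "distributing")`.
#' @param fixed list of `list(part =, nodes =)` giving nodes with all three
#'   displacement components prescribed to zero.
#' @return object of class `fe_system`.
#' @export
assemble_system <- function(parts, materials, ties = list(), springs = list(),
                            remote_points = list(), fixed = list()) {
  stopifnot(length(parts) > 0, !is.null(names(parts)))
  offsets <- cumsum(c(0, utils::head(vapply(parts, function(p) nrow(p$nodes), 0), -1)))
  names(offsets) <- names(parts)
  nodes <- do.call(rbind, lapply(parts, function(p) p$nodes))
  ntot <- nrow(nodes)
  parent <- seq_len(ntot)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  for (tie in ties) {
    tol <- tie$tol %||% 1e-6
    ia <- offsets[[tie$a]] + seq_len(nrow(parts[[tie$a]]$nodes))
    ib <- offsets[[tie$b]] + seq_len(nrow(parts[[tie$b]]$nodes))
    if (!is.null(tie$a_patch)) {
      pa <- parts[[tie$a]]$patches[[tie$a_patch]]
      if (is.null(pa)) stop(sprintf("tie: part '%s' has no patch '%s'", tie$a, tie$a_patch))
      ia <- offsets[[tie$a]] + sort(unique(as.vector(pa)))
    }
    keyb <- paste(round(nodes[ib, 1] / tol), round(nodes[ib, 2] / tol),
                  round(nodes[ib, 3] / tol))
    keya <- paste(round(nodes[ia, 1] / tol), round(nodes[ia, 2] / tol),
                  round(nodes[ia, 3] / tol))
    hit <- match(keya, keyb)
    if (!is.null(tie$a_patch) && anyNA(hit)) {
      orphans <- ia[is.na(hit)] - offsets[[tie$a]]
      stop(sprintf("tie %s-%s: non-conforming interface; orphan nodes of '%s': %s",
                   tie$a, tie$b, tie$a, paste(utils::head(orphans, 20), collapse = ", ")))
    }
    ok <- !is.na(hit)
    if (!any(ok)) {
      stop(sprintf("tie %s-%s: no coincident nodes within tolerance %g", tie$a, tie$b, tol))
    }
    for (j in which(ok)) parent[find(ib[hit[j]])] <- find(ia[j])
  }
  root <- vapply(seq_len(ntot), function(i) as.integer(find(i)), 0L)
  glob <- match(root, sort(unique(root)))      # compact global ids
  nglob <- max(glob)
  gnodes <- matrix(0, nglob, 3)
  gnodes[glob, ] <- nodes                      # representatives (coincident anyway)
  node_map <- data.frame(
    part = rep(names(parts), vapply(parts, function(p) nrow(p$nodes), 0)),
    local = unlist(lapply(parts, function(p) seq_len(nrow(p$nodes)))),
    global = glob, row.names = NULL)

  # element stiffness assembly (triplets)
  ndof <- 3 * nglob
  trip_i <- vector("list", length(parts)); trip_j <- trip_i; trip_x <- trip_i
  parts_el <- list()
  for (pn in names(parts)) {
    p <- parts[[pn]]
    mat <- materials[[pn]]
    if (is.null(mat)) stop(sprintf("no material for part '%s'", pn))
    tets_g <- matrix(glob[offsets[[pn]] + p$tets], ncol = 4)
    nel <- nrow(tets_g)
    ii <- matrix(0L, nel, 144); jj <- ii; xx <- matrix(0, nel, 144)
    for (e in seq_len(nel)) {
      X <- gnodes[tets_g[e, ], , drop = FALSE]
      Ke <- tryCatch(tet4_stiffness(X, mat),
                     error = function(err) stop(sprintf(
                       "part '%s', element %d: %s", pn, e, conditionMessage(err))))
      dofs <- as.vector(rbind(3 * tets_g[e, ] - 2, 3 * tets_g[e, ] - 1, 3 * tets_g[e, ]))
      ii[e, ] <- rep(dofs, times = 12)
      jj[e, ] <- rep(dofs, each = 12)
      xx[e, ] <- as.vector(Ke)
    }
    trip_i[[pn]] <- as.vector(ii); trip_j[[pn]] <- as.vector(jj); trip_x[[pn]] <- as.vector(xx)
    parts_el[[pn]] <- list(tets = tets_g, material = mat)
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(ndof, ndof))

  system <- list(nodes = gnodes, node_map = node_map, parts_el = parts_el,
                 ndof = ndof, remotes = list(), springs = list(),
                 fixed_dofs = integer(0))

  # remote points: resolve patch nodes and area weights
  for (rn in names(remote_points)) {
    rp <- remote_points[[rn]]
    mesh <- parts[[rp$part]]
    facets <- mesh$patches[[rp$patch]]
    if (is.null(facets) || nrow(facets) == 0) {
      stop(sprintf("remote point '%s': patch '%s' on part '%s' is empty",
                   rn, rp$patch, rp$part))
    }
    geo <- facet_geometry(mesh, facets)
    lnodes <- sort(unique(as.vector(facets)))
    w <- numeric(length(lnodes))
    rowmap <- match(as.vector(facets), lnodes)
    w <- as.numeric(rowsum(rep(geo$area / 3, 3), rowmap, reorder = TRUE))
    w <- w / sum(w)
    gn <- glob[offsets[[rp$part]] + lnodes]
    system$remotes[[rn]] <- list(location = rp$location, part = rp$part,
                                 patch = rp$patch,
                                 coupling = rp$coupling %||% "distributing",
                                 nodes = gn, weights = w)
  }
  # rigid remotes append 6 dofs each (3 translation + 3 rotation)
  for (rn in names(system$remotes)) {
    if (identical(system$remotes[[rn]]$coupling, "rigid")) {
      system$remotes[[rn]]$dofs <- system$ndof + 1:6
      system$ndof <- system$ndof + 6L
    }
  }
  if (system$ndof > ndof) {
    K <- Matrix::bdiag(K, Matrix::Diagonal(system$ndof - ndof, 0))
  }

  # springs
  system$K_base <- K
  for (si in seq_along(springs)) {
    sp <- springs[[si]]
    sp$type <- sp$type %||% "uniaxial"
    sp$label <- sp$label %||% sprintf("spring_%d", si)
    sp$group <- sp$group %||% ""
    sp$grounded <- identical(sp$a, "ground") || identical(sp$b, "ground")
    sp$rows <- .spring_rows(system, sp, si)
    system$springs[[si]] <- sp
  }
  K <- .system_K(system)

  # rigid-coupling transformation (identity when no rigid remotes)
  rigid <- Filter(function(r) identical(r$coupling, "rigid"), system$remotes)
  if (length(rigid)) {
    slave <- unlist(lapply(rigid, function(r) as.vector(rbind(3 * r$nodes - 2, 3 * r$nodes - 1, 3 * r$nodes))))
    master <- setdiff(seq_len(system$ndof), slave)
    ti <- list(); tj <- list(); tx <- list()
    red_of <- match(seq_len(system$ndof), master)      # full dof -> reduced col
    ti[[1]] <- master; tj[[1]] <- red_of[master]; tx[[1]] <- rep(1, length(master))
    for (r in rigid) {
      for (nn in seq_along(r$nodes)) {
        g <- r$nodes[nn]
        rel <- system$nodes[g, ] - r$location
        Tn <- cbind(diag(3), -.skew3(rel))            # u = uR + theta x rel
        ti[[length(ti) + 1L]] <- rep(3 * g - 2:0, 6)
        tj[[length(tj) + 1L]] <- rep(red_of[r$dofs], each = 3)
        tx[[length(tx) + 1L]] <- as.vector(Tn)
      }
    }
    system$T <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                                     dims = c(system$ndof, length(master)))
    system$master <- master
  }

  for (fx in fixed) {
    gn <- glob[offsets[[fx$part]] + fx$nodes]
    system$fixed_dofs <- union(system$fixed_dofs,
                               as.vector(rbind(3 * gn - 2, 3 * gn - 1, 3 * gn)))
  }
  system$K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  system$cache <- new.env(parent = emptyenv())
  class(system) <- "fe_system"
  system
}

#' @export
print.fe_system <- function(x, ...) {
  cat(sprintf("fe_system: %d nodes, %d dofs (%d fixed), %d springs, %d remote points\n",
              nrow(x$nodes), x$ndof, length(x$fixed_dofs), length(x$springs),
              length(x$remotes)))
  invisible(x)
}

#' Zero nodal load vector for a system
#' @param system an `fe_system`.
#' @return numeric vector of length `ndof`.
#' @export
node_loads <- function(system) numeric(system$ndof)

#' Add a patch traction load
#'
#' Distributes `force` as uniform traction over a patch of a part (see
#' [distribute_traction()]) and accumulates the nodal loads.
#'
#' @param system an `fe_system`.
#' @param loads load vector from [node_loads()].
#' @param part,patch patch identification; the patch must exist on the part
#'   mesh that was assembled.
#' @param mesh the part mesh carrying the patch (meshes are not stored in
#'   the system).
#' @param force length-3 force (N).
#' @return updated load vector.
#' @export
add_patch_load <- function(system, loads, mesh, part, patch, force) {
  dt <- distribute_traction(mesh, patch, force)
  off <- system$node_map$global[system$node_map$part == part]
  gn <- off[dt$nodes]
  for (c_ in 1:3) {
    loads[3 * (gn - 1) + c_] <- loads[3 * (gn - 1) + c_] + dt$loads[, c_]
  }
  loads
}

#' Add a load at a remote point
#'
#' For a distributing remote the force (acting at the remote location) is
#' transferred to the coupled patch as the statically equivalent nodal load
#' set: nodal loads `f_i = w_i (lambda + mu x r_i)` with the six Lagrange
#' parameters chosen so total force and total moment about the remote
#' location are exact. For a rigid remote the load is applied to the remote
#' degrees of freedom directly.
#'
#' @param system an `fe_system`.
#' @param loads load vector.
#' @param remote remote-point name.
#' @param force length-3 force (N).
#' @param moment length-3 moment about the remote location (N mm).
#' @return updated load vector.
#' @export
add_remote_load <- function(system, loads, remote, force, moment = c(0, 0, 0)) {
  rp <- system$remotes[[remote]]
  if (is.null(rp)) stop(sprintf("unknown remote point '%s'", remote))
  if (identical(rp$coupling, "rigid")) {
    loads[rp$dofs] <- loads[rp$dofs] + c(force, moment)
    return(loads)
  }
  r <- sweep(system$nodes[rp$nodes, , drop = FALSE], 2, rp$location)
  w <- rp$weights
  lam_mu <- solve(.remote_A(system, rp), c(force, moment))
  lam <- lam_mu[1:3]; mu <- lam_mu[4:6]
  for (i in seq_along(w)) {
    fi <- w[i] * (lam + .cross3(mu, r[i, ]))
    g <- rp$nodes[i]
    loads[3 * g - 2:0] <- loads[3 * g - 2:0] + fi
  }
  loads
}

#' Displacement of a remote point from a solved field
#' @param system an `fe_system`.
#' @param u full displacement vector.
#' @param remote remote-point name.
#' @return length-3 displacement (mm).
#' @export
remote_displacement <- function(system, u, remote) {
  rp <- system$remotes[[remote]]
  if (identical(rp$coupling, "rigid")) return(u[rp$dofs[1:3]])
  # weighted least-squares rigid motion of the patch, evaluated at the
  # remote location
  U <- matrix(u[as.vector(rbind(3 * rp$nodes - 2, 3 * rp$nodes - 1, 3 * rp$nodes))],
              ncol = 3, byrow = TRUE)
  r <- sweep(system$nodes[rp$nodes, , drop = FALSE], 2, rp$location)
  b <- numeric(6)
  for (k in seq_along(rp$weights)) {
    S <- cbind(diag(3), -.skew3(r[k, ]))
    b <- b + rp$weights[k] * as.numeric(t(S) %*% U[k, ])
  }
  as.numeric(solve(.remote_A(system, rp), b))[1:3]
}

#' Solve the static problem
#'
#' Direct sparse symmetric factorisation of the free-free-reduced system;
#' the relative residual must stay below `tol`. Recovers per-node
#' displacements, per-element strain tensors (with max principal and max
#' component summaries per part), per-spring forces, grounded reactions by
#' spring group, and reactions at fixed nodes.
#'
#' @param system an `fe_system`.
#' @param loads nodal load vector (full dof space).
#' @param tol relative residual tolerance.
#' @return object of class `fe_result`.
#' @export
solve_static <- function(system, loads, tol = 1e-10) {
  Kf <- system$K
  f <- loads
  if (!is.null(system$T)) {
    Kf <- Matrix::forceSymmetric(Matrix::t(system$T) %*% Kf %*% system$T)
    f <- as.numeric(Matrix::t(system$T) %*% f)
    fixed <- match(intersect(system$fixed_dofs, system$master), system$master)
  } else {
    fixed <- system$fixed_dofs
  }
  free <- setdiff(seq_len(nrow(Kf)), fixed)
  Kff <- Kf[free, free, drop = FALSE]
  fac <- system$cache$fac
  if (is.null(fac) || !identical(system$cache$free, free)) {
    fac <- tryCatch(
      suppressWarnings(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)),
      error = function(e) stop(
        "system stiffness is singular or indefinite (unconstrained rigid-body modes?)"))
    system$cache$fac <- fac
    system$cache$free <- free
  }
  uf <- as.numeric(Matrix::solve(fac, f[free]))
  # normwise backward error ||Ku - f|| / (||K|| ||u|| + ||f||); iterative
  # refinement pushes stiff bending-dominated systems to solver accuracy
  Knorm <- max(abs(Kff))
  back_err <- function(uf) {
    .norm3c(Kff %*% uf - f[free]) /
      max(Knorm * .norm3c(uf) + .norm3c(f[free]), .Machine$double.xmin)
  }
  for (it in 1:5) {
    if (back_err(uf) <= tol) break
    uf <- uf + as.numeric(Matrix::solve(fac, f[free] - as.numeric(Kff %*% uf)))
  }
  resid <- back_err(uf)
  if (resid > tol) {
    stop(sprintf("linear solve backward error %.3g exceeds tolerance %.3g", resid, tol))
  }
  ured <- numeric(nrow(Kf)); ured[free] <- uf
  u <- if (!is.null(system$T)) as.numeric(system$T %*% ured) else ured
  # reactions at fixed nodes: R = K u - f on the fixed rows (reduced space)
  fixed_reactions <- if (length(fixed)) {
    as.numeric((Kf %*% ured)[fixed]) - f[fixed]
  } else numeric(0)

  # spring forces: elongation e = a . u; force on endpoint A = -k e axis
  spring_forces <- lapply(system$springs, function(sp) {
    fvec <- c(0, 0, 0); es <- numeric(0)
    for (r in sp$rows) {
      e <- sum(r$x * u[r$i])
      fvec <- fvec - sp$k * e * r$axis
      es <- c(es, e)
    }
    list(label = sp$label, group = sp$group, grounded = sp$grounded,
         force_on_model = fvec, elongation = es,
         magnitude = .norm3(fvec))
  })
  groups <- unique(vapply(system$springs, function(s) s$group, ""))
  grounded_reactions <- list()
  for (g in groups) {
    sel <- vapply(system$springs, function(s) s$group == g && s$grounded, TRUE)
    if (any(sel)) {
      grounded_reactions[[g]] <- Reduce(`+`, lapply(spring_forces[sel],
                                                    function(s) s$force_on_model))
    }
  }

  # per-part strains
  strains <- list()
  un <- matrix(u[seq_len(3 * nrow(system$nodes))], ncol = 3, byrow = TRUE)
  for (pn in names(system$parts_el)) {
    pe <- system$parts_el[[pn]]
    nel <- nrow(pe$tets)
    eps <- matrix(0, nel, 6)
    for (e in seq_len(nel)) {
      X <- system$nodes[pe$tets[e, ], , drop = FALSE]
      bv <- .tet_B(X)
      ue <- as.vector(t(un[pe$tets[e, ], , drop = FALSE]))
      eps[e, ] <- bv$B %*% ue
    }
    colnames(eps) <- c("xx", "yy", "zz", "xy", "yz", "zx")
    maxp <- vapply(seq_len(nel), function(e) {
      m <- matrix(c(eps[e, 1], eps[e, 4] / 2, eps[e, 6] / 2,
                    eps[e, 4] / 2, eps[e, 2], eps[e, 5] / 2,
                    eps[e, 6] / 2, eps[e, 5] / 2, eps[e, 3]), 3, 3)
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      ev[which.max(abs(ev))]
    }, 0)
    strains[[pn]] <- list(tensor = eps, max_principal = maxp,
                          max_abs_principal = max(abs(maxp), 0),
                          max_abs_component = max(abs(eps), 0))
  }

  disp_norm <- sqrt(rowSums(un^2))
  structure(list(
    u = u, displacements = un, node_disp_norm = disp_norm,
    max_total_deformation = max(disp_norm, 0),
    strains = strains, spring_forces = spring_forces,
    grounded_reactions = grounded_reactions,
    fixed_reactions = fixed_reactions, fixed_dofs_reduced = fixed,
    residual = resid), class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("fe_result: max deformation %.3g mm, %d spring forces, residual %.2g\n",
              x$max_total_deformation, length(x$spring_forces), x$residual))
  invisible(x)
}

#' Global equilibrium check
#'
#' Sums the applied nodal loads, the reactions at fixed nodes, and the
#' forces exerted on the model by grounded springs; the first law requires
#' the total to vanish.
#'
#' @param system an `fe_system`.
#' @param result a solved [solve_static()] result.
#' @param loads the applied load vector used in the solve.
#' @param tol relative tolerance.
#' @return list with `residual_N`, `relative`, `ok`, `total_applied`.
#' @export
global_equilibrium_check <- function(system, result, loads, tol = 1e-6) {
  napp <- 3 * nrow(system$nodes)
  lm <- matrix(loads[seq_len(napp)], ncol = 3, byrow = TRUE)
  total_applied <- colSums(lm)
  if (length(loads) > napp) {   # rigid-remote loads (translation slots)
    for (rp in system$remotes) {
      if (identical(rp$coupling, "rigid")) {
        total_applied <- total_applied + loads[rp$dofs[1:3]]
      }
    }
  }
  total <- total_applied
  for (sf in result$spring_forces) if (sf$grounded) total <- total + sf$force_on_model
  if (length(result$fixed_reactions)) {
    # R = (K u - f) on the fixed rows is the support force applied to the model
    fr <- result$fixed_reactions
    idx <- (system$fixed_dofs - 1) %% 3 + 1
    for (c_ in 1:3) total[c_] <- total[c_] + sum(fr[idx == c_])
  }
  res <- .norm3(total)
  list(residual_N = res,
       relative = res / max(1, .norm3(total_applied)),
       ok = res <= tol * max(1, .norm3(total_applied)),
       total_applied = total_applied)
}
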