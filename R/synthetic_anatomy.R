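# Synthetic lower-limb anatomy: parameterised tube/frustum bone meshes,
# attachment patches, and gait-position tables. Units: mm, N, kg, m/s^2.
#
# Coordinate convention (pipeline-wide): y vertical (distal-proximal, up
# positive), z postero-anterior (anterior positive), x medio-lateral
# (lateral positive for a right limb).

# Orthonormal frame for a part axis: returns e1, e2 with u x e1 = e2 ... such
# that a point at angle theta is origin + s*u + r*(cos(theta)*e1 + sin(theta)*e2).
.axis_frame <- function(dir) {
  u <- dir / sqrt(sum(dir^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Point on (or inside) a tube part in cylindrical coordinates
#'
#' Helper to express attachment points on the synthetic bones. `s` is the
#' axial coordinate from the part base, `theta` the angle in degrees in the
#' part's cross-section frame, `r` the radius (defaults to the outer surface
#' radius at `s`).
#'
#' @param spec a part spec as given to [gen_bone_mesh()].
#' @param s axial coordinate mm.
#' @param theta angle degrees.
#' @param r radius mm or `NULL` for the outer surface.
#' @return length-3 point.
#' @export
cyl_point <- function(spec, s, theta, r = NULL) {
  fr <- .axis_frame(spec$axis_dir %||% c(0, 1, 0))
  tfrac <- s / spec$length
  r_out <- .interp_radius(spec$r_out, tfrac)
  if (is.null(r)) r <- r_out
  th <- theta * pi / 180
  (spec$origin %||% c(0, 0, 0)) + s * fr$u + r * (cos(th) * fr$e1 + sin(th) * fr$e2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.interp_radius <- function(r, tfrac) {
  if (length(r) == 1L) r else r[1] + (r[2] - r[1]) * tfrac
}

#' Generate a capped-tube (hollow cylinder / frustum) bone mesh
#'
#' Bones are modelled as hollow cortical shells: a tube between an inner and
#' an outer radius, capped by annular end faces. Radii may differ between the
#' two ends (frustum). The mesh is a structured hex grid split into 6
#' tetrahedra per hex with a fixed template, so regeneration with the same
#' spec and seed is bit-identical and two coaxial tubes generated with the
#' same cross-section discretisation have conforming end annuli.
#'
#' @param part_spec list with `name`, `length` (mm), `r_out`, `r_in` (scalar
#'   or length-2 `c(base, tip)` mm), `element_size` (mm), optional `origin`
#'   (default `c(0,0,0)`), `axis_dir` (default `+y`), `n_theta`, `n_axial`,
#'   `n_radial` overrides, `jitter` (mm axial jitter of interior rings,
#'   default 0) and `landmarks` (named list of cylindrical triples
#'   `c(s, theta_deg, r)`; `r = NA` means on-axis).
#' @param seed integer seed controlling the (optional) jitter.
#' @return a [tet_part_mesh()] with landmarks `<name>_base`, `<name>_tip`
#'   (axis ends) plus any requested ones, and the axis stored for patch
#'   selection.
#' @export
gen_bone_mesh <- function(part_spec, seed = 1L) {
  sp <- part_spec
  stopifnot(is.character(sp$name), sp$length > 0, all(sp$r_out > 0),
            all(sp$r_in >= 0), sp$element_size > 0)
  if (any(.interp_radius(sp$r_in, c(0, 1)) >= .interp_radius(sp$r_out, c(0, 1)))) {
    stop(sprintf("part '%s': inner radius must be smaller than outer radius", sp$name))
  }
  origin <- sp$origin %||% c(0, 0, 0)
  fr <- .axis_frame(sp$axis_dir %||% c(0, 1, 0))
  h <- sp$element_size
  r_out_max <- max(sp$r_out)
  n_ax <- sp$n_axial %||% max(2L, ceiling(sp$length / h))
  n_th <- sp$n_theta %||% max(8L, ceiling(2 * pi * r_out_max / h))
  n_ra <- sp$n_radial %||% max(1L, round((max(sp$r_out) - min(sp$r_in)) / h))

  # node grid: layers j = 0..n_ax, radial k = 0..n_ra, sector i = 0..n_th-1
  idx <- function(j, k, i) {
    i <- i %% n_th
    1L + i + n_th * (k + (n_ra + 1L) * j)
  }
  nnod <- (n_ax + 1L) * (n_ra + 1L) * n_th
  nodes <- matrix(0, nnod, 3)
  s_layers <- seq(0, sp$length, length.out = n_ax + 1L)
  if (!is.null(sp$jitter) && sp$jitter > 0 && n_ax > 2L) {
    set.seed(seed)
    jit <- stats::runif(n_ax - 1L, -sp$jitter, sp$jitter)
    s_layers[2:n_ax] <- s_layers[2:n_ax] + jit
  }
  th <- 2 * pi * (0:(n_th - 1L)) / n_th
  for (j in 0:n_ax) {
    tfrac <- s_layers[j + 1L] / sp$length
    ri <- .interp_radius(sp$r_in, tfrac)
    ro <- .interp_radius(sp$r_out, tfrac)
    for (k in 0:n_ra) {
      r <- ri + (ro - ri) * k / n_ra
      ring <- outer(cos(th), fr$e1) + outer(sin(th), fr$e2)
      pts <- sweep(r * ring, 2, origin + s_layers[j + 1L] * fr$u, `+`)
      nodes[idx(j, k, 0:(n_th - 1L)), ] <- pts
    }
  }

  # fixed 6-tet split of each hex (all hexes share handedness in (s, r, theta))
  split6 <- rbind(c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
                  c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))
  ntet <- n_ax * n_ra * n_th * 6L
  tets <- matrix(0L, ntet, 4L)
  row <- 1L
  for (j in 1:n_ax) for (k in 1:n_ra) for (i in 0:(n_th - 1L)) {
    corner <- c(idx(j - 1L, k - 1L, i),     idx(j - 1L, k - 1L, i + 1L),
                idx(j - 1L, k,      i + 1L), idx(j - 1L, k,      i),
                idx(j,      k - 1L, i),     idx(j,      k - 1L, i + 1L),
                idx(j,      k,      i + 1L), idx(j,      k,      i))
    tets[row:(row + 5L), ] <- matrix(corner[t(split6)], 6L, 4L, byrow = TRUE)
    row <- row + 6L
  }
  # fix any template-inverted tets (cannot happen for right-handed hexes,
  # but guard against exotic axis choices)
  mesh0 <- tet_part_mesh(sp$name, nodes, tets, validate = FALSE)
  v <- tet_volumes(mesh0)
  if (any(v < 0)) tets[v < 0, c(3, 4)] <- tets[v < 0, c(4, 3)]

  lms <- list()
  lms[[paste0(sp$name, "_base")]] <- origin
  lms[[paste0(sp$name, "_tip")]] <- origin + sp$length * fr$u
  for (ln in names(sp$landmarks %||% list())) {
    cylc <- sp$landmarks[[ln]]
    r <- if (is.na(cylc[3])) 0 else cylc[3]
    lms[[ln]] <- cyl_point(sp, cylc[1], cylc[2], r)
  }
  mesh <- tet_part_mesh(sp$name, nodes, tets, landmarks = lms,
                        axis = list(origin = origin, dir = fr$u,
                                    e1 = fr$e1, e2 = fr$e2),
                        validate = TRUE)
  attr(mesh, "spec") <- sp
  mesh
}

# Cylindrical coordinates of points w.r.t. a mesh axis.
.cyl_coords <- function(mesh, points) {
  ax <- mesh$axis
  if (is.null(ax)) stop(sprintf("part '%s' has no stored axis", mesh$name))
  rel <- sweep(points, 2, ax$origin)
  s <- rel %*% ax$dir
  a1 <- rel %*% ax$e1
  a2 <- rel %*% ax$e2
  list(s = as.numeric(s), theta = atan2(as.numeric(a2), as.numeric(a1)),
       r = sqrt(as.numeric(a1)^2 + as.numeric(a2)^2))
}

# Connected components of a facet set via shared edges.
.facet_components <- function(facets) {
  k <- nrow(facets)
  if (k <= 1L) return(rep(1L, k))
  edges_of <- function(f) paste(pmin(f[c(1, 2, 3)], f[c(2, 3, 1)]),
                                pmax(f[c(1, 2, 3)], f[c(2, 3, 1)]))
  ekeys <- lapply(seq_len(k), function(i) edges_of(facets[i, ]))
  edge_map <- new.env(hash = TRUE)
  for (i in seq_len(k)) for (e in ekeys[[i]]) {
    edge_map[[e]] <- c(edge_map[[e]], i)
  }
  comp <- integer(k); cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      f <- queue[[1]]; queue <- queue[-1]
      if (comp[f] != 0L) next
      comp[f] <- cur
      for (e in ekeys[[f]]) {
        nb <- edge_map[[e]]
        queue <- c(queue, nb[comp[nb] == 0L])
      }
    }
  }
  comp
}

#' Add named attachment patches to a mesh
#'
#' Each patch spec selects boundary facets in a cylindrical window around a
#' centre point: axial extent along the part axis, angular extent around it,
#' optionally restricted to a surface class (`outer` wall, `inner` wall,
#' `cap` annular ends). The largest edge-connected component of the selection
#' is stored, so every patch is a non-empty connected facet set.
#'
#' @param mesh a [tet_part_mesh()] with a stored axis.
#' @param patch_specs list of lists with `name`, `centre` (length-3, must lie
#'   within the mesh bounding box), `half_axial` (mm), `half_angle`
#'   (degrees), optional `surface` (`"outer"`, `"inner"`, `"cap"`, `"any"`;
#'   default `"outer"`).
#' @return the mesh with patches added.
#' @export
gen_attachment_patches <- function(mesh, patch_specs) {
  bf <- boundary_facets(mesh)
  geo <- facet_geometry(mesh, bf)
  cc <- .cyl_coords(mesh, geo$centroid)
  ax <- mesh$axis
  # surface classification by outward normal
  ncap <- abs(geo$normal %*% ax$dir) > 0.7
  radial <- cbind(cos(cc$theta), sin(cc$theta)) %*% rbind(ax$e1, ax$e2)
  router <- rowSums(geo$normal * radial) > 0
  surf_class <- ifelse(ncap, "cap", ifelse(router, "outer", "inner"))
  # margin absorbs the sagitta of the polygonal discretisation: analytic
  # surface points may lie slightly outside the faceted hull
  margin <- 0.05 * sqrt(sum((apply(mesh$nodes, 2, max) - apply(mesh$nodes, 2, min))^2))
  bb_lo <- apply(mesh$nodes, 2, min) - margin
  bb_hi <- apply(mesh$nodes, 2, max) + margin
  for (ps in patch_specs) {
    centre <- ps$centre
    if (any(centre < bb_lo) || any(centre > bb_hi)) {
      stop(sprintf("patch '%s': centre lies outside the bounding box of part '%s'",
                   ps$name, mesh$name))
    }
    ctr <- .cyl_coords(mesh, matrix(centre, 1))
    surface <- ps$surface %||% "outer"
    dtheta <- abs(((cc$theta - ctr$theta + pi) %% (2 * pi)) - pi) * 180 / pi
    sel <- abs(cc$s - ctr$s) <= ps$half_axial & dtheta <= ps$half_angle
    if (surface != "any") sel <- sel & surf_class == surface
    if (!any(sel)) {
      stop(sprintf("patch '%s': selection is empty on part '%s'", ps$name, mesh$name))
    }
    sub <- bf[sel, , drop = FALSE]
    comp <- .facet_components(sub)
    biggest <- which.max(tabulate(comp))
    mesh$patches[[ps$name]] <- sub[comp == biggest, , drop = FALSE]
  }
  validate_mesh(mesh)
  mesh
}

#' Default gait-table inputs
#'
#' The five stance positions emulate the study conditions: beginning and end
#' of stance plus the three extrema of the knee joint force. GRF magnitudes
#' default to (253, 592, 483, 644, 15) N — first peak of the order of body
#' weight for a 62 kg subject, near-zero at the end of stance. Knee flexion
#' is 14 deg at position 4 and 38 deg at position 5; positions 1-3 are free
#' choices of typical gait values. Segment inertial forces are of the order
#' of tens of newtons so the quasi-static premise (inertia/GRF <= 0.10 over
#' positions 1-4) holds by construction.
#' @return list of gait defaults (part of [default_config()]).
#' @export
default_gait <- function() {
  list(
    pct_gait = c(2, 13, 31, 50, 62),
    knee_flexion_deg = c(5, 20, 10, 14, 38),
    grf_magnitudes_N = c(253, 592, 483, 644, 15),
    # unit-ish direction before normalisation: mostly vertical, braking then
    # propulsive antero-posterior component, small mediolateral component;
    # the load line passes near the pelvis as in upright stance, so joint
    # moments (and hence muscle and joint forces) stay in a physiological range
    grf_dir = rbind(c(0.02, 1, -0.02), c(0.03, 1, -0.04), c(0.02, 1, 0.00),
                    c(0.03, 1, 0.05), c(0.02, 1, 0.08)),
    cop_x = c(0, 2, 4, 5, 5),
    cop_z = c(-30, -10, 10, 40, 70),
    # inertial force components m*a [N] per segment (rows = positions)
    inertial_thigh = rbind(c(12, 20, 8), c(-12, -4, -7), c(-3, -11, -2),
                           c(12, 9, -7), c(-15, 8, 2)),
    inertial_legfoot = rbind(c(17, 13, -3), c(-41, -10, 9), c(4, -3, -4),
                             c(16, -1, -7), c(30, -8, 2))
  )
}

#' Generate the five-position gait table
#'
#' @param config pipeline config (see [default_config()]); `config$gait`
#'   entries override the defaults, `config$body_mass_kg` must be positive.
#' @param seed integer; kept for interface symmetry (the default table is
#'   deterministic).
#' @param muscle_names character vector for the per-position active-muscle
#'   sets; defaults to all muscles of [default_muscle_defs()]. The
#'   recruitment stage derives which are actually active.
#' @return list of `gait_position` lists with fields `index`, `pct_gait`,
#'   `knee_flexion`, `grf` (3D N), `cop` (3D mm), `segment_accel`
#'   (list thigh/leg_foot, m/s^2), `active_muscles`.
#' @export
gen_gait_table <- function(config = default_config(), seed = 1L,
                           muscle_names = NULL) {
  if (is.null(config$body_mass_kg) || config$body_mass_kg <= 0) {
    stop("body mass must be positive")
  }
  g <- utils::modifyList(default_gait(), config$gait %||% list())
  if (is.null(muscle_names)) muscle_names <- unique(default_muscle_defs()$muscle)
  masses <- c(thigh = config$segment_masses_kg[["thigh"]],
              leg_foot = config$segment_masses_kg[["leg_foot"]])
  lapply(1:5, function(i) {
    dir <- g$grf_dir[i, ]
    grf <- dir / sqrt(sum(dir^2)) * g$grf_magnitudes_N[i]
    structure(list(
      index = i,
      pct_gait = g$pct_gait[i],
      knee_flexion = g$knee_flexion_deg[i],
      grf = grf,
      cop = c(g$cop_x[i], 0, g$cop_z[i]),
      segment_accel = list(
        thigh = g$inertial_thigh[i, ] / masses[["thigh"]],
        leg_foot = g$inertial_legfoot[i, ] / masses[["leg_foot"]]),
      active_muscles = muscle_names
    ), class = "gait_position")
  })
}
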