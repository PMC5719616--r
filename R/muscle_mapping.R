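# From recruitment output to FE loads: recombination of muscle elements,
# action-reaction pairing, patch traction distribution, rigid 3-point
# registration, frontal-plane axis check.

#' Recombine muscle-element forces into applied muscle forces
#'
#' Element forces (magnitude times unit line of action, evaluated at the
#' insertion) are summed vectorially per output slot. With the standard
#' grouping — three subdivisions each for the adductor magnus and adductor
#' brevis, one slot for each of the other 27 muscles — the 122 elements
#' recombine into 33 applied muscle forces. Slots whose elements cancel are
#' retained with zero force.
#'
#' @param elements element table (see [gen_lower_limb()]`$elements`) with
#'   columns `slot`, `origin_part`, `ox oy oz`, `insertion_part`,
#'   `ix iy iz`.
#' @param forces numeric vector of recruited force magnitudes, one per row
#'   of `elements`.
#' @param grouping optional named character vector mapping element group
#'   labels (the `slot` column) to output slots; defaults to the identity.
#'   Unknown labels are an error.
#' @return data.frame of class `applied_muscle_forces`: one row per slot
#'   with the summed force vector (`fx fy fz`, the force exerted on the
#'   insertion), attachment parts and mean attachment points.
#' @export
recombine_elements <- function(elements, forces, grouping = NULL) {
  stopifnot(nrow(elements) == length(forces))
  labels <- elements$slot
  if (is.null(grouping)) {
    grouping <- stats::setNames(unique(labels), unique(labels))
  }
  unknown <- setdiff(labels, names(grouping))
  if (length(unknown)) {
    stop(sprintf("unknown group label%s: %s",
                 if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", ")))
  }
  out_slot <- unname(grouping[labels])
  ins <- as.matrix(elements[, c("ix", "iy", "iz")])
  org <- as.matrix(elements[, c("ox", "oy", "oz")])
  line <- org - ins
  len <- sqrt(rowSums(line^2))
  if (any(len < 1e-9)) stop("zero-length muscle element line of action")
  u <- line / len
  fvec <- u * forces
  slots <- unique(out_slot)
  rows <- lapply(slots, function(s) {
    sel <- out_slot == s
    stopifnot(length(unique(elements$origin_part[sel])) == 1L,
              length(unique(elements$insertion_part[sel])) == 1L)
    w <- forces[sel]
    wn <- if (sum(w) > 0) w / sum(w) else rep(1 / sum(sel), sum(sel))
    data.frame(slot = s,
               fx = sum(fvec[sel, 1]), fy = sum(fvec[sel, 2]), fz = sum(fvec[sel, 3]),
               origin_part = elements$origin_part[sel][1],
               insertion_part = elements$insertion_part[sel][1],
               ox = sum(org[sel, 1] * wn), oy = sum(org[sel, 2] * wn), oz = sum(org[sel, 3] * wn),
               ix = sum(ins[sel, 1] * wn), iy = sum(ins[sel, 2] * wn), iz = sum(ins[sel, 3] * wn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("applied_muscle_forces", class(out))
  out
}

#' Build action-reaction load pairs
#'
#' For every applied muscle force whose origin and insertion both lie on
#' modelled parts, two loads of equal magnitude and opposite direction are
#' emitted (third law); muscles originating off-model (pelvis) contribute
#' their insertion load only — their reaction enters the model through the
#' hip joint in the rigid-body stage.
#'
#' @param applied an `applied_muscle_forces` table ([recombine_elements()]).
#' @param modelled_parts character vector of part names whose attachments
#'   are load-bearing in the FE model (a remote-point part such as the
#'   calcaneus counts as modelled).
#' @return data.frame of loads: `slot`, `part`, `end` ("origin"/
#'   "insertion"), application point `px py pz`, force `fx fy fz`, `paired`.
#' @export
build_action_reaction <- function(applied, modelled_parts) {
  rows <- list()
  for (i in seq_len(nrow(applied))) {
    a <- applied[i, ]
    F <- c(a$fx, a$fy, a$fz)             # force on the insertion
    paired <- a$origin_part %in% modelled_parts
    if (a$insertion_part %in% modelled_parts) {
      rows[[length(rows) + 1L]] <- data.frame(
        slot = a$slot, part = a$insertion_part, end = "insertion",
        px = a$ix, py = a$iy, pz = a$iz,
        fx = F[1], fy = F[2], fz = F[3], paired = paired)
    }
    if (paired) {
      rows[[length(rows) + 1L]] <- data.frame(
        slot = a$slot, part = a$origin_part, end = "origin",
        px = a$ox, py = a$oy, pz = a$oz,
        fx = -F[1], fy = -F[2], fz = -F[3], paired = TRUE)
    }
  }
  do.call(rbind, rows)
}

#' Distribute a force as uniform traction over an attachment patch
#'
#' The force divided by the patch area gives a uniform traction; integrating
#' it against the linear shape functions assigns each facet one third of its
#' share to each of its three nodes. The nodal loads sum exactly to the
#' input force.
#'
#' @param mesh a [tet_part_mesh()].
#' @param patch patch name.
#' @param force length-3 force vector (N).
#' @return list with `nodes` (indices into the mesh), `loads`
#'   (`k x 3`, N), `traction` (N/mm^2) and `area` (mm^2).
#' @export
distribute_traction <- function(mesh, patch, force) {
  facets <- mesh$patches[[patch]]
  if (is.null(facets)) stop(sprintf("part '%s' has no patch '%s'", mesh$name, patch))
  geo <- facet_geometry(mesh, facets)
  A <- sum(geo$area)
  if (A <= 0) stop(sprintf("patch '%s' has zero area", patch))
  nodes <- sort(unique(as.vector(facets)))
  loads <- matrix(0, length(nodes), 3)
  rowmap <- match(as.vector(facets), nodes)
  share <- rep(geo$area / (3 * A), 3L)        # each facet node gets area/3 / A
  for (c_ in 1:3) {
    contrib <- share * force[c_]
    loads[, c_] <- as.numeric(rowsum(contrib, rowmap, reorder = TRUE))
  }
  # rowsum reorders by group id; rowmap groups are 1..length(nodes)
  list(nodes = nodes, loads = loads, traction = force / A, area = A)
}

#' Rigid 3-point landmark registration
#'
#' Least-squares rigid transform (rotation + translation, no scaling)
#' mapping three source landmarks onto three target markers, as used to
#' position the FE geometry on the rigid-body model's femur markers
#' (femoral-head centre, middle of the transepicondylar axis, medial
#' epicondyle). Exact when the triples are congruent.
#'
#' @param source,target `3 x 3` matrices, one landmark per row.
#' @return object of class `rigid_transform`: `R` (3 x 3, proper
#'   orthonormal), `t` (length-3), `residual` (RMS mm).
#' @export
register_3pt <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(all(dim(source) == c(3, 3)), all(dim(target) == c(3, 3)))
  check_collinear <- function(P, what) {
    v1 <- P[2, ] - P[1, ]; v2 <- P[3, ] - P[1, ]
    if (.norm3(.cross3(v1, v2)) < 1e-9 * max(.norm3(v1) * .norm3(v2), 1)) {
      stop(sprintf("%s landmarks are collinear; registration is degenerate", what))
    }
  }
  check_collinear(source, "source"); check_collinear(target, "target")
  cs <- colMeans(source); ct <- colMeans(target)
  S <- sweep(source, 2, cs); T_ <- sweep(target, 2, ct)
  H <- t(S) %*% T_
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t_ <- ct - as.numeric(R %*% cs)
  mapped <- sweep(source %*% t(R), 2, t_, `+`)
  structure(list(R = R, t = t_,
                 residual = sqrt(mean(rowSums((mapped - target)^2)))),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points `k x 3` matrix or length-3 vector.
#' @return transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) {
    as.numeric(transform$R %*% points + transform$t)
  } else {
    sweep(as.matrix(points) %*% t(transform$R), 2, transform$t, `+`)
  }
}

#' Angle between two tibia axes in the frontal plane
#'
#' Projects both axes onto the frontal (x-y) plane and returns the angle
#' between the projections in degrees, with an acceptance flag at the
#' configured limit (default 3 degrees): the residual malalignment allowed
#' after the femur-based registration.
#'
#' @param axis_fe,axis_rb length-3 direction vectors.
#' @param limit_deg flag threshold.
#' @return list with `angle_deg` and `ok`.
#' @export
frontal_axis_angle <- function(axis_fe, axis_rb, limit_deg = 3) {
  proj <- function(v) {
    p <- c(v[1], v[2])
    n <- sqrt(sum(p^2))
    if (n < 1e-12 * max(.norm3(v), 1)) {
      stop("axis has zero projection onto the frontal plane")
    }
    p / n
  }
  a <- proj(axis_fe); b <- proj(axis_rb)
  ang <- acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
  ang <- min(ang, 180 - ang)     # direction-insensitive
  list(angle_deg = ang, ok = ang < limit_deg)
}
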