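# Per-position static analysis of the three-segment linkage (pelvis ground,
# hip spherical, knee revolute, rigid ankle): equilibrium assembly, min/max
# muscle recruitment, joint-reaction extraction.

.norm3 <- function(v) sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Inertial force of a body segment
#'
#' The inertial force is the product of the segment mass and its
#' acceleration; the magnitude is additionally reported rounded to integer
#' newtons for table comparisons.
#'
#' @param segment list with `mass` (kg) and `accel` (length-3, m/s^2).
#' @return list with `force` (3D, N), `magnitude` (N) and
#'   `magnitude_rounded`.
#' @export
inertial_force <- function(segment) {
  stopifnot(segment$mass > 0, length(segment$accel) == 3)
  f <- segment$mass * segment$accel
  list(force = f, magnitude = .norm3(f), magnitude_rounded = round(.norm3(f)))
}

#' Quasi-static ratio of inertial to ground-reaction forces
#'
#' For each gait position, the largest segment inertial-force magnitude is
#' divided by the GRF magnitude. The stance analysis is treated as
#' quasi-static when every ratio over positions carrying substantial load
#' (GRF > `grf_floor`) is at most `limit`.
#'
#' @param gait_table list of gait positions (see [gen_gait_table()]).
#' @param segment_masses named list `thigh`, `leg_foot` (kg).
#' @param limit negligibility threshold on the ratio (default 0.10).
#' @param grf_floor positions with GRF magnitude below this are excluded
#'   from the global flag (default 100 N).
#' @return data.frame with per-position ratios, plus attribute
#'   `negligible` (logical flag).
#' @export
quasi_static_ratio <- function(gait_table, segment_masses, limit = 0.10,
                               grf_floor = 100) {
  stopifnot(length(gait_table) > 0)
  rows <- lapply(gait_table, function(pos) {
    in_max <- max(
      inertial_force(list(mass = segment_masses$thigh,
                          accel = pos$segment_accel$thigh))$magnitude,
      inertial_force(list(mass = segment_masses$leg_foot,
                          accel = pos$segment_accel$leg_foot))$magnitude)
    grf <- .norm3(pos$grf)
    data.frame(position = pos$index, inertial_N = in_max, grf_N = grf,
               ratio = if (grf > 0) in_max / grf else Inf,
               considered = grf > grf_floor)
  })
  out <- do.call(rbind, rows)
  attr(out, "negligible") <- all(out$ratio[out$considered] <= limit)
  out
}

#' Assemble the static equilibrium system of the two-segment limb
#'
#' Unknowns are the muscle-element force magnitudes (columns of `C`) and the
#' joint reactions (columns of `B`): hip force (3, spherical joint), knee
#' force (3) and knee constraint moment perpendicular to the flexion axis
#' (2, revolute joint). Rows are the force and moment balances of the
#' leg+foot segment (moments about the knee centre) and of the thigh
#' (moments about the hip centre); the knee-axis moment row of the leg
#' carries no reaction, so muscles alone must balance it. The load vector
#' `d` carries the GRF applied at the COP; gravity and inertial terms are
#' excluded (static stance analysis).
#'
#' @param linkage list with `hip_centre`, `knee_centre`, `knee_axis`
#'   (unit), `segment_of_part` (named map part -> "thigh"/"leg_foot").
#'   A [gen_lower_limb()] object works directly.
#' @param position a gait position (needs `grf`, `cop`, `active_muscles`).
#' @param muscles element table with columns `element`, `muscle`,
#'   `origin_part`, `ox oy oz`, `insertion_part`, `ix iy iz`, `strength_N`.
#' @return list with `C` (12 x n), `B` (12 x 8), `d` (12), `elements`
#'   (the active subset, same row order as columns of `C`), `rows`
#'   (row labels), `strengths`.
#' @export
assemble_equilibrium <- function(linkage, position, muscles) {
  act <- muscles[muscles$muscle %in% position$active_muscles, , drop = FALSE]
  n <- nrow(act)
  H <- linkage$hip_centre; K <- linkage$knee_centre
  ax <- linkage$knee_axis / .norm3(linkage$knee_axis)
  # orthonormal complement of the knee axis for the constraint moment
  e1 <- .axis_frame(ax)$e1; e2 <- .axis_frame(ax)$e2
  seg_of <- function(part) {
    if (part == "pelvis") return(NA_character_)
    s <- linkage$segment_of_part[[part]]
    if (is.null(s)) stop(sprintf("no segment mapping for part '%s'", part))
    s
  }
  rows <- c(paste0("leg_force_", c("x", "y", "z")),
            paste0("leg_moment_", c("x", "y", "z")),
            paste0("thigh_force_", c("x", "y", "z")),
            paste0("thigh_moment_", c("x", "y", "z")))
  C <- matrix(0, 12, max(n, 0))
  add_wrench <- function(col, seg, point, dir) {
    # accumulate force dir at point onto segment seg rows of column col
    if (is.na(seg)) return(invisible())
    if (seg == "leg_foot") {
      C[1:3, col] <<- C[1:3, col] + dir
      C[4:6, col] <<- C[4:6, col] + .cross3(point - K, dir)
    } else {
      C[7:9, col] <<- C[7:9, col] + dir
      C[10:12, col] <<- C[10:12, col] + .cross3(point - H, dir)
    }
  }
  for (i in seq_len(n)) {
    o <- c(act$ox[i], act$oy[i], act$oz[i])
    ins <- c(act$ix[i], act$iy[i], act$iz[i])
    line <- o - ins
    len <- .norm3(line)
    if (len < 1e-9) stop(sprintf("muscle element '%s' has zero-length line of action",
                                 act$element[i]))
    u <- line / len
    add_wrench(i, seg_of(act$insertion_part[i]), ins, u)     # pull at insertion
    add_wrench(i, seg_of(act$origin_part[i]), o, -u)         # reaction at origin
  }
  # reactions: hip force (on thigh at H), knee force R_k (on leg at K, minus
  # on thigh), knee constraint moment (2 components perpendicular to axis)
  B <- matrix(0, 12, 8)
  B[7:9, 1:3] <- diag(3)                              # hip force, thigh force rows
  B[1:3, 4:6] <- diag(3)                              # knee force on leg
  B[7:9, 4:6] <- -diag(3)                             # reaction on thigh
  B[10:12, 4:6] <- -.skew3(K - H)                     # moment of -R_k at K about H
  B[4:6, 7] <- e1;  B[4:6, 8] <- e2                   # knee moment on leg
  B[10:12, 7] <- -e1; B[10:12, 8] <- -e2              # reaction on thigh
  d <- numeric(12)
  d[1:3] <- -position$grf
  d[4:6] <- -.cross3(position$cop - K, position$grf)
  list(C = C, B = B, d = d, elements = act, rows = rows,
       strengths = act$strength_N)
}

.skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Min/max muscle recruitment
#'
#' Solves the static muscle-recruitment problem with the min/max criterion:
#' minimise the peak activation `beta = max_i f_i / N_i` subject to
#' equilibrium `C f + B r = d`, non-negative muscle forces `0 <= f_i <=
#' beta N_i`, and free joint reactions `r`. Among beta-optimal solutions the
#' returned one also minimises the total muscle force (fixed secondary
#' tie-break, so results are reproducible across solvers).
#'
#' @param C coefficient matrix (rows = equilibrium equations, columns =
#'   muscle elements).
#' @param d load vector.
#' @param strengths element strengths `N_i` (N).
#' @param B reaction matrix (columns = free reaction slots); may have zero
#'   columns for fully determined toys.
#' @param tie_break also minimise the total force among optima.
#' @param tol equilibrium residual tolerance, relative to `max(1, |d|)`.
#' @return object of class `recruitment`: `forces`, `activations`, `beta`,
#'   `reactions` (vector, one per column of `B`), `residual`.
#' @export
recruit_minmax <- function(C, d, strengths, B = NULL, tie_break = TRUE,
                           tol = 1e-8) {
  C <- as.matrix(C); n <- ncol(C); m <- nrow(C)
  if (is.null(B)) B <- matrix(0, m, 0)
  B <- as.matrix(B); nr <- ncol(B)
  stopifnot(length(strengths) == n, all(strengths > 0), length(d) == m)
  # project the free reactions out: rows of the equilibrium system reached
  # by reaction columns are always satisfiable, so the muscle forces are
  # constrained only through the null space of B^T
  if (nr > 0) {
    Q <- qr.Q(qr(B), complete = TRUE)
    rank_B <- qr(B)$rank
    Z <- Q[, setdiff(seq_len(m), seq_len(rank_B)), drop = FALSE]
    Cr <- t(Z) %*% C
    dr <- as.numeric(t(Z) %*% d)
  } else {
    Cr <- C
    dr <- d
  }
  recover_reactions <- function(f) {
    if (nr == 0) return(numeric(0))
    as.numeric(qr.coef(qr(B), d - as.numeric(C %*% f)))
  }
  if (n == 0L) {
    r <- recover_reactions(numeric(0))
    resid <- .norm3c((if (nr) B %*% r else 0) - d)
    if (resid > tol * max(1, .norm3c(d))) {
      stop("recruitment infeasible: no muscles and reactions cannot balance the load")
    }
    return(structure(list(forces = numeric(0), activations = numeric(0),
                          beta = 0, reactions = r, residual = resid),
                     class = "recruitment"))
  }
  # row scaling for simplex conditioning (moment rows are O(1e5) N mm)
  sc <- pmax(apply(cbind(Cr, dr), 1, function(r) max(abs(r))), 1e-12)
  Cs <- Cr / sc; ds <- dr / sc
  coef_mag <- apply(abs(Cs), 1, max)
  bad <- which(coef_mag < 1e-12 & abs(ds) > 1e-9)
  if (length(bad)) {
    stop(sprintf("recruitment infeasible: reduced row %d carries load but no muscle term",
                 bad[1]))
  }
  keep <- coef_mag >= 1e-12
  Cs <- Cs[keep, , drop = FALSE]; ds <- ds[keep]
  # the simplex implementation requires non-negative right-hand sides
  flip <- ds < 0
  Cs[flip, ] <- -Cs[flip, , drop = FALSE]
  ds[flip] <- -ds[flip]
  me <- length(ds)
  # variables x = (f, beta)
  A3 <- if (me) cbind(Cs, 0) else NULL
  A1 <- cbind(diag(n), -strengths)
  s <- boot::simplex(a = c(rep(0, n), 1), A1 = A1, b1 = rep(0, n),
                     A3 = A3, b3 = if (me) ds else NULL, maxi = FALSE,
                     n.iter = 100 * (n + me + 1))
  if (s$solved != 1) {
    ls <- pracma::lsqnonneg(rbind(Cs, 0), c(ds, 0))
    lres <- abs(as.numeric(Cs %*% ls$x) - ds)
    worst <- if (length(lres)) which.max(lres) else 1L
    stop(sprintf(
      "recruitment infeasible or unbounded (simplex code %d); worst-balanced reduced row %d (scaled residual %.3g)",
      s$solved, worst, if (length(lres)) lres[worst] else 0))
  }
  x <- s$soln
  beta <- x[n + 1]
  if (tie_break && n > 0 && me > 0) {
    # second LP: fix beta (tiny relaxation guards degenerate vertices),
    # minimise total muscle force
    bnd <- beta * (1 + 1e-9) + 1e-12
    s2 <- boot::simplex(a = rep(1, n), A1 = diag(n), b1 = bnd * strengths,
                        A3 = Cs, b3 = ds, maxi = FALSE,
                        n.iter = 100 * (n + me))
    if (s2$solved == 1) {
      f2 <- s2$soln[seq_len(n)]
      res2 <- .norm3c(Cr %*% f2 - dr)
      # keep the tie-broken vertex only if it is genuinely feasible
      if (res2 <= tol * max(1, .norm3c(dr))) x <- c(f2, beta)
    }
  }
  f <- unname(x[seq_len(n)])
  r <- recover_reactions(f)
  resid <- .norm3c(C %*% f + (if (nr) B %*% r else 0) - d)
  if (resid > tol * max(1, .norm3c(d))) {
    stop(sprintf("recruitment equilibrium residual %.3g exceeds tolerance", resid))
  }
  activ <- f / strengths
  structure(list(forces = f, activations = activ,
                 beta = if (n > 0) max(activ) else 0,
                 reactions = r, residual = resid), class = "recruitment")
}

.norm3c <- function(v) sqrt(sum(as.numeric(v)^2))

#' @export
print.recruitment <- function(x, ...) {
  cat(sprintf("recruitment: %d elements, %d active, beta = %.4f, residual %.2g\n",
              length(x$forces), sum(x$forces > 1e-9), x$beta, x$residual))
  invisible(x)
}

#' Solve the recruitment problem for one gait position of a limb
#'
#' Convenience wrapper: assembles the equilibrium system of the limb and
#' solves the min/max recruitment.
#'
#' @param limb a [gen_lower_limb()] object.
#' @param position gait position.
#' @param ... passed to [recruit_minmax()].
#' @return `recruitment` object with the assembled system attached
#'   (`$system`), reactions labelled (`$hip`, `$knee_force`,
#'   `$knee_moment`).
#' @export
recruit_position <- function(limb, position, ...) {
  linkage <- list(hip_centre = limb$hip_centre,
                  knee_centre = (limb$rb %||% list())$knee_centre %||% limb$knee_centre,
                  knee_axis = limb$knee_axis,
                  segment_of_part = limb$segment_of_part)
  sys <- assemble_equilibrium(linkage, position, limb$elements)
  sol <- recruit_minmax(sys$C, sys$d, sys$strengths, B = sys$B, ...)
  sol$system <- sys
  sol$hip <- sol$reactions[1:3]
  sol$knee_force <- sol$reactions[4:6]
  sol$knee_moment <- sol$reactions[7:8]
  sol
}

#' Hip joint reaction of a recruitment solution
#'
#' @param solution a solved `recruitment` from [recruit_position()] (or any
#'   with a `hip` slot).
#' @return list with `force` (3D N) and `magnitude` (N).
#' @export
hip_reaction <- function(solution) {
  if (is.null(solution$hip)) stop("solution carries no hip reaction slot")
  list(force = solution$hip, magnitude = .norm3(solution$hip))
}
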