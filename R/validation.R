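# Validation metrics: resultants, relative differences, rigid-rotation
# decomposition, the three-criterion model check, and re-derivation of the
# reference worked-example tables.

#' Resultant magnitude of a force vector
#'
#' @param v length-3 force (N).
#' @param rounded also return the integer-rounded value used for table
#'   comparisons.
#' @return magnitude (N), or list with `value` and `rounded`.
#' @export
resultant_magnitude <- function(v, rounded = FALSE) {
  stopifnot(all(is.finite(v)))
  m <- .norm3(v)
  if (rounded) list(value = m, rounded = round(m)) else m
}

#' Relative difference against a reference magnitude
#'
#' `100 * |val - ref| / ref`, the hip-reaction comparison metric (the
#' rigid-body magnitude is the reference value).
#'
#' @param ref reference (must be positive).
#' @param val compared value.
#' @return percentage.
#' @export
relative_difference <- function(ref, val) {
  if (ref <= 0) stop("reference magnitude must be positive")
  100 * abs(val - ref) / ref
}

#' Least-squares rigid rotation about a centre
#'
#' Fits a small-rotation vector `omega` such that `u_i ~ omega x (x_i - c)`
#' in the least-squares sense; used to split displacement fields into the
#' rigid rotation about the femoral-head centre plus an elastic remainder.
#'
#' @param points `n x 3` node positions.
#' @param disp `n x 3` displacements.
#' @param centre rotation centre.
#' @return list with `omega` (radians), `predict(points)` closure.
#' @export
fit_rigid_rotation <- function(points, disp, centre) {
  r <- sweep(as.matrix(points), 2, centre)
  A <- matrix(0, 3, 3); b <- numeric(3)
  # u = -[r]x omega; normal equations sum [r]x^T [r]x omega = -sum [r]x^T u
  for (i in seq_len(nrow(r))) {
    S <- .skew3(r[i, ])
    A <- A + crossprod(S)
    b <- b - as.numeric(t(S) %*% disp[i, ])
  }
  omega <- as.numeric(solve(A, b))
  list(omega = omega,
       predict = function(p) {
         p <- matrix(p, ncol = 3)
         t(apply(p, 1, function(x) .cross3(omega, x - centre)))
       })
}

#' Run the FE analysis of one gait position and compare with the RB stage
#'
#' Maps the recruited muscle forces to FE loads (recombination,
#' action-reaction pairing, patch tractions, remote-point transfer of the
#' calcaneus insertions and the GRF at the COP), solves the FE system, and
#' extracts the validation quantities: femoral-head reaction (grounding
#' springs), stabilisation-spring resultant, distal-tibia displacement with
#' its rigid-rotation/elastic split, maximum deformation and per-part
#' maximum strain.
#'
#' @param limb a [gen_lower_limb()] object.
#' @param system the assembled `fe_system` of the limb
#'   ([assemble_limb_fe()]).
#' @param position gait position.
#' @param recruitment solved [recruit_position()] for the same position.
#' @return list of class `position_report`.
#' @export
run_position <- function(limb, system, position, recruitment) {
  system <- place_remote(system, "cop", position$cop)
  loads <- build_position_loads(limb, system, position, recruitment)
  res <- solve_static(system, loads$vector)
  equil <- global_equilibrium_check(system, res, loads$vector)

  fe_hip <- res$grounded_reactions$grounding
  stab <- res$grounded_reactions$stabilisation %||% c(0, 0, 0)
  rb_hip <- hip_reaction(recruitment)
  rb_mag <- rb_hip$magnitude
  fe_mag <- .norm3(fe_hip)

  u_cop <- remote_displacement(system, res$u, "cop")
  tib_glob <- system$node_map$global[system$node_map$part == "tibia"]
  dist_nodes <- tib_glob[sort(unique(as.vector(limb$parts$tibia$patches$distal_tibia_cap)))]
  u_dist <- colMeans(res$displacements[dist_nodes, , drop = FALSE])
  p_dist <- colMeans(system$nodes[dist_nodes, , drop = FALSE])
  # fit the limb rotation on the femur-tibia chain (the patella and fibula
  # hang off it through interface springs and would only add noise)
  chain <- system$node_map$global[system$node_map$part %in% c("femur", "tibia")]
  fit <- fit_rigid_rotation(system$nodes[chain, , drop = FALSE],
                            res$displacements[chain, , drop = FALSE],
                            limb$hip_centre)
  u_rigid <- as.numeric(fit$predict(p_dist))
  elastic <- u_dist - u_rigid
  total <- .norm3(u_dist)

  max_strain <- lapply(res$strains, function(s) s$max_abs_principal)
  muscle_max <- max(sqrt(rowSums(as.matrix(loads$applied[, c("fx", "fy", "fz")])^2)), 0)

  structure(list(
    position = position$index,
    rb_hip = rb_hip$force, rb_hip_magnitude = rb_mag,
    fe_hip = fe_hip, fe_hip_magnitude = fe_mag,
    relative_difference_pct = if (rb_mag > 0) relative_difference(rb_mag, fe_mag) else NA_real_,
    stab_spring_force = stab, stab_spring_resultant = .norm3(stab),
    grf_magnitude = .norm3(position$grf),
    max_applied_muscle_force = muscle_max,
    distal_tibia_disp = u_dist, distal_tibia_total = total,
    cop_disp = u_cop,
    rigid_rotation_omega = fit$omega,
    elastic_remainder = elastic,
    elastic_remainder_norm = .norm3(elastic),
    elastic_fraction = if (total > 0) .norm3(elastic) / total else 0,
    max_total_deformation = res$max_total_deformation,
    max_strain_per_part = max_strain,
    equilibrium = equil,
    fe_result = res), class = "position_report")
}

#' Build the FE load vector of a gait position
#'
#' @param limb limb object.
#' @param system assembled `fe_system` (with `cop` remote already placed at
#'   the position's COP).
#' @param position gait position.
#' @param recruitment recruitment solution for the position.
#' @return list with `vector` (nodal loads) and `applied` (the recombined
#'   applied-force table).
#' @export
build_position_loads <- function(limb, system, position, recruitment) {
  act <- recruitment$system$elements
  applied <- recombine_elements(act, recruitment$forces)
  pair_loads <- build_action_reaction(
    applied, modelled_parts = c(names(limb$parts), "calcaneus"))
  loads <- node_loads(system)
  slot_tab <- limb$slots
  for (i in seq_len(nrow(pair_loads))) {
    ld <- pair_loads[i, ]
    F <- c(ld$fx, ld$fy, ld$fz)
    if (.norm3(F) < 1e-12) next
    if (ld$part == "calcaneus") {
      loads <- add_remote_load(system, loads, "calcaneus", F)
    } else {
      srow <- slot_tab[slot_tab$slot == ld$slot, ]
      patch <- if (ld$end == "origin") srow$origin_patch else srow$insertion_patch
      loads <- add_patch_load(system, loads, limb$parts[[ld$part]], ld$part, patch, F)
    }
  }
  loads <- add_remote_load(system, loads, "cop", position$grf)
  list(vector = loads, applied = applied)
}

#' Apply the three validation criteria
#'
#' A position passes when (1) the elastic (rigid-rotation-removed)
#' displacement of the distal tibia is a small fraction of the total
#' displacement (the total itself is dominated by rigid rotation about the
#' femoral head), (2) the stabilisation-spring resultant is negligible
#' against the larger of the GRF magnitude and the RB hip-reaction
#' magnitude, and (3) the FE femoral-head reaction matches the RB hip
#' reaction within the relative-difference threshold. The model is valid
#' when all positions pass all three criteria.
#'
#' @param reports list of `position_report`s.
#' @param thresholds list with `elastic_frac_pct`, `spring_frac_pct`,
#'   `rel_diff_pct` (defaults from [default_config()]).
#' @return object of class `stance_validation`: per-position table and
#'   overall flag.
#' @export
validate <- function(reports, thresholds = default_config()$thresholds) {
  stopifnot(length(reports) >= 1)
  th <- utils::modifyList(default_config()$thresholds, thresholds)
  rows <- lapply(reports, function(r) {
    spring_ref <- max(r$grf_magnitude, r$rb_hip_magnitude)
    c1 <- r$elastic_fraction * 100 <= th$elastic_frac_pct ||
      r$elastic_remainder_norm <= th$elastic_abs_mm
    c2 <- if (spring_ref > 0) {
      r$stab_spring_resultant <= th$spring_frac_pct / 100 * spring_ref
    } else r$stab_spring_resultant <= 1e-6
    c3 <- if (is.na(r$relative_difference_pct)) TRUE else
      r$relative_difference_pct <= th$rel_diff_pct
    ce <- r$equilibrium$ok
    data.frame(position = r$position,
               rb_hip_N = r$rb_hip_magnitude, fe_hip_N = r$fe_hip_magnitude,
               rel_diff_pct = r$relative_difference_pct,
               spring_N = r$stab_spring_resultant,
               distal_disp_mm = r$distal_tibia_total,
               elastic_pct = 100 * r$elastic_fraction,
               max_deform_mm = r$max_total_deformation,
               equilibrium = ce, c1_deformation = c1,
               c2_springs = c2, c3_reaction = c3,
               pass = ce && c1 && c2 && c3)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, thresholds = th, pass = all(tab$pass)),
            class = "stance_validation")
}

#' @export
print.stance_validation <- function(x, ...) {
  cat("Stance-phase model validation\n")
  cat(sprintf("  thresholds: elastic <= %.3g%% of total, springs <= %.3g%% of ref, rel diff <= %.3g%%\n",
              x$thresholds$elastic_frac_pct, x$thresholds$spring_frac_pct,
              x$thresholds$rel_diff_pct))
  tab <- x$table
  tab[, sapply(tab, is.numeric)] <- round(tab[, sapply(tab, is.numeric)], 2)
  print(tab, row.names = FALSE)
  cat(if (x$pass) "  => model VALID at all positions\n" else "  => model NOT valid\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# reference worked-example tables

.reference_path <- function(file) {
  system.file("extdata", "stance_reference", file, package = "stancelimb",
              mustWork = TRUE)
}

#' Recompute the derivable cells of the reference tables
#'
#' The package ships the published five-position reference dataset of a
#' lower-limb stance validation study (inertial-force components, femoral
#' head reactions and stabilisation-spring forces, RB/FE hip-reaction
#' magnitude pairs) as plain CSV. Every derivable cell — resultants of
#' printed component triples, relative differences of printed magnitude
#' pairs — is recomputed here and printed next to the printed value.
#'
#' @param print print the comparison tables.
#' @return list of data.frames `inertial`, `reactions`, `hip_comparison`
#'   with `computed` columns alongside the printed values.
#' @export
tables_demo <- function(print = TRUE) {
  inertial <- utils::read.csv(.reference_path("inertial_forces.csv"))
  inertial$computed <- round(sqrt(inertial$fx^2 + inertial$fy^2 + inertial$fz^2))
  reactions <- utils::read.csv(.reference_path("femoral_head_forces.csv"))
  reactions$computed <- round(sqrt(reactions$fx^2 + reactions$fy^2 + reactions$fz^2))
  hip <- utils::read.csv(.reference_path("hip_comparison.csv"))
  hip$computed_rel_diff_pct <- round(mapply(relative_difference, hip$rb_N, hip$fe_N), 1)
  out <- list(inertial = inertial, reactions = reactions, hip_comparison = hip)
  if (print) {
    cat("Inertial-force magnitudes [N] (computed from printed components):\n")
    print(inertial, row.names = FALSE)
    cat("\nFemoral-head reaction / stabilisation-spring resultants [N]:\n")
    print(reactions, row.names = FALSE)
    cat("\nRB vs FE hip-reaction relative differences [%]:\n")
    print(hip, row.names = FALSE)
  }
  invisible(out)
}
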