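# Orchestration: FE assembly of the synthetic limb with its boundary
# machinery, and the five-position end-to-end analysis.

# Pick n well-separated node pairs between two patches of two parts for
# node-to-node springs. With n_neighbors > 1 each picked a-node connects to
# its several nearest b-nodes, giving a web of axial members whose angled
# lines also transmit shear. Every member is a central-force (collinear)
# pair, so the interface adds no spurious internal moment.
.spring_pairs <- function(parts, part_a, patch_a, part_b, patch_b, n,
                          n_neighbors = 1L) {
  ma <- parts[[part_a]]; mb <- parts[[part_b]]
  na_ <- sort(unique(as.vector(ma$patches[[patch_a]])))
  nb <- sort(unique(as.vector(mb$patches[[patch_b]])))
  pa <- ma$nodes[na_, , drop = FALSE]
  pb <- mb$nodes[nb, , drop = FALSE]
  # spread the a-side picks: greedy farthest-point sampling
  picked <- integer(0)
  picked[1] <- 1L
  while (length(picked) < min(n, length(na_))) {
    d2 <- rep(Inf, nrow(pa))
    for (p in picked) d2 <- pmin(d2, rowSums(sweep(pa, 2, pa[p, ])^2))
    picked <- c(picked, which.max(d2))
  }
  out <- list()
  for (i in picked) {
    ord <- order(rowSums(sweep(pb, 2, pa[i, ])^2))
    for (j in ord[seq_len(min(n_neighbors, length(ord)))]) {
      out[[length(out) + 1L]] <- list(a = list(part = part_a, node = na_[i]),
                                      b = list(part = part_b, node = nb[j]))
    }
  }
  out
}

#' Assemble the FE system of the synthetic lower limb
#'
#' Bonds the femur and tibia to the soft knee layer by node merging, grounds
#' the femoral head with three orthogonal high-stiffness springs (spherical
#' joint), attaches the three weak stabilisation springs at the COP remote
#' point on the distal tibia end, strings the patellar tendon as three
#' parallel springs between the patellar base and the tibial tuberosity
#' (`k = E A / L / 3` each), and joins the patella and fibula to their
#' neighbours with stiff isotropic interface springs. The COP and calcaneus
#' are distributing remote points coupled to the distal tibia end; the
#' femoral head remote point is coupled to the proximal femur cap.
#'
#' @param limb a [gen_lower_limb()] object.
#' @param k_stab stabilisation-spring stiffness (N/mm); default from config.
#' @param coupling remote-point coupling type, `"distributing"` (default)
#'   or `"rigid"`.
#' @return an `fe_system`.
#' @export
assemble_limb_fe <- function(limb, k_stab = NULL, coupling = "distributing") {
  cfg <- limb$config
  k_stab <- k_stab %||% cfg$springs$stabilisation_N_mm
  k_ground <- cfg$springs$grounding_N_mm
  tq <- cfg$springs$tendon
  k_tendon <- tendon_spring_stiffness(tq$E, tq$A, tq$L, tq$n)$k_per_spring
  k_int <- cfg$springs$interface_N_mm

  materials <- list(femur = cfg$materials$bone, tibia = cfg$materials$bone,
                    fibula = cfg$materials$bone, patella = cfg$materials$bone,
                    knee_layer = cfg$materials$cartilage)
  springs <- list()
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    springs[[length(springs) + 1L]] <- list(
      a = list(remote = "femoral_head"), b = "ground", k = k_ground,
      type = "uniaxial", axis = ax, group = "grounding",
      label = sprintf("grounding_%s", paste(ax, collapse = "")))
    # weak springs at both distal remote points (COP and calcaneus): two
    # separated anchors are needed so no rotation axis through the femoral
    # head escapes them and the stabilised system is positive definite
    for (rp in c("cop", "calcaneus")) {
      springs[[length(springs) + 1L]] <- list(
        a = list(remote = rp), b = "ground", k = k_stab,
        type = "uniaxial", axis = ax, group = "stabilisation",
        label = sprintf("stabilisation_%s_%s", rp, paste(ax, collapse = "")))
    }
  }
  for (pr in .spring_pairs(limb$parts, "patella", "patella_base_cap",
                           "tibia", "tibial_tuberosity", tq$n)) {
    springs[[length(springs) + 1L]] <- c(pr, list(k = k_tendon, type = "uniaxial",
                                                  group = "tendon", label = "patellar_tendon"))
  }
  iface <- c(.spring_pairs(limb$parts, "patella", "patella_facet", "femur", "trochlea", 10, 6),
             .spring_pairs(limb$parts, "fibula", "fibula_head", "tibia", "tibia_fibula_prox", 6, 5),
             .spring_pairs(limb$parts, "fibula", "fibula_distal", "tibia", "tibia_fibula_dist", 6, 5))
  for (pr in iface) {
    # axial members along their own lines: central-force pairs carry no
    # net moment; the angled members of the web transmit shear and torsion
    springs[[length(springs) + 1L]] <- c(pr, list(k = k_int / 5, type = "uniaxial",
                                                  group = "interface", label = "interface"))
  }
  assemble_system(
    parts = limb$parts,
    materials = materials,
    ties = list(list(a = "femur", b = "knee_layer"),
                list(a = "tibia", b = "knee_layer")),
    springs = springs,
    remote_points = list(
      femoral_head = list(location = limb$hip_centre, part = "femur",
                          patch = "femoral_head_cap", coupling = coupling),
      cop = list(location = c(0, 0, 0), part = "tibia",
                 patch = "distal_tibia_cap", coupling = coupling),
      calcaneus = list(location = limb$calcaneus, part = "tibia",
                       patch = "distal_tibia_cap", coupling = coupling)))
}

#' Change the stabilisation-spring stiffness of an assembled system
#'
#' Rebuilds only the rank-one stabilisation terms (used by the
#' spring-stiffness sweep of the validation study), invalidating the cached
#' factorisation.
#'
#' @param system an `fe_system` from [assemble_limb_fe()].
#' @param k_new new stiffness (N/mm).
#' @return modified system.
#' @export
set_stabilisation_stiffness <- function(system, k_new) {
  for (si in seq_along(system$springs)) {
    if (system$springs[[si]]$group == "stabilisation") {
      system$springs[[si]]$k <- k_new
    }
  }
  system$K <- Matrix::forceSymmetric(.system_K(system))
  system$cache <- new.env(parent = emptyenv())
  system
}

#' Run the full five-position stance analysis
#'
#' Generates (or takes) the synthetic limb, builds the gait table, solves
#' the min/max recruitment per position, registers the FE geometry on the
#' rigid-body markers (three-point registration on the femoral-head centre,
#' the middle of the transepicondylar axis and the medial epicondyle —
#' an identity check here because both stages share the synthetic
#' geometry), runs the FE solve per position and applies the three
#' validation criteria.
#'
#' @param config pipeline config ([stance_config()]).
#' @param seed integer seed (drives the synthetic attachment scatter).
#' @param limb optionally a pre-built limb.
#' @param positions subset of positions to run (default all five).
#' @return list of class `stance_analysis`: `limb`, `gait`, `recruitments`,
#'   `reports`, `validation`, `registration`, `quasi_static`, `system`.
#' @export
run_stance_analysis <- function(config = stance_config(), seed = 1L,
                                limb = NULL, positions = 1:5) {
  if (is.null(limb)) limb <- gen_lower_limb(config, seed = seed)
  gait <- gen_gait_table(config, seed = seed)[positions]
  qs <- quasi_static_ratio(gait, config$segment_masses_kg)

  # position the FE femur on the RB femur markers (head centre, middle of
  # the transepicondylar axis, medial epicondyle); the residual tibia-axis
  # mismatch in the frontal plane must stay under the configured limit
  fl <- limb$parts$femur$landmarks
  src <- rbind(fl$femoral_head_centre,
               (fl$lateral_epicondyle + fl$medial_epicondyle) / 2,
               fl$medial_epicondyle)
  reg <- register_3pt(src, limb$rb$femur_markers)
  tib_axis_fe <- as.numeric(reg$R %*% limb$parts$tibia$axis$dir)
  frontal <- frontal_axis_angle(tib_axis_fe, limb$rb$tibia_axis,
                                limit_deg = config$thresholds$frontal_angle_deg)

  system <- assemble_limb_fe(limb)
  recruitments <- list(); reports <- list()
  for (i in seq_along(gait)) {
    pos <- gait[[i]]
    recruitments[[i]] <- recruit_position(limb, pos)
    reports[[i]] <- run_position(limb, system, pos, recruitments[[i]])
  }
  val <- validate(reports, config$thresholds)
  structure(list(limb = limb, gait = gait, quasi_static = qs,
                 registration = reg, frontal_angle = frontal,
                 recruitments = recruitments, reports = reports,
                 validation = val, system = system, config = config,
                 seed = seed), class = "stance_analysis")
}

#' @export
print.stance_analysis <- function(x, ...) {
  cat(sprintf("stance_analysis (seed %d): %d positions\n", x$seed, length(x$reports)))
  print(x$validation)
  invisible(x)
}

#' Stabilisation-spring stiffness sweep
#'
#' Re-solves the positions at decreasing stabilisation-spring stiffnesses;
#' with consistent RB/FE geometry the FE-vs-RB hip-reaction discrepancy is
#' expected to decrease monotonically as the springs soften.
#'
#' @param analysis a [run_stance_analysis()] result.
#' @param k_levels stiffness levels (N/mm), decreasing.
#' @param position which position to sweep (default 4, the highest-load
#'   one).
#' @return data.frame with `k`, `rel_diff_pct`, `spring_N`.
#' @export
sweep_stabilisation <- function(analysis, k_levels = c(1, 0.1, 0.01),
                                position = 4L) {
  idx <- which(vapply(analysis$reports, function(r) r$position, 0L) == position)
  stopifnot(length(idx) == 1L)
  pos <- analysis$gait[[idx]]
  rec <- analysis$recruitments[[idx]]
  rows <- lapply(k_levels, function(k) {
    sys <- set_stabilisation_stiffness(analysis$system, k)
    rep_ <- run_position(analysis$limb, sys, pos, rec)
    data.frame(k = k, rel_diff_pct = rep_$relative_difference_pct,
               spring_N = rep_$stab_spring_resultant,
               fe_hip_N = rep_$fe_hip_magnitude,
               rb_hip_N = rep_$rb_hip_magnitude)
  })
  do.call(rbind, rows)
}
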