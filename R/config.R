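# Pipeline configuration: defaults carry the study constants (materials,
# spring stiffnesses, segment masses, thresholds); YAML round-trip in io.R.

#' Default pipeline configuration
#'
#' Houses the pipeline constants: Young's moduli 17000 MPa (cortical bone),
#' 120 MPa (menisci), 15 MPa (articular cartilage), 900 MPa (tendon);
#' Poisson ratios 0.3 (bone) and 0.45 (soft tissue); grounding springs
#' 1e9 N/mm, stabilisation springs 1 N/mm; patellar tendon E*A/L stiffness
#' split over 3 parallel springs; segment masses 6.22 kg (thigh) and 3.8 kg
#' (leg + foot); body mass 62 kg; validation thresholds (stabilisation-spring
#' resultant <= 5% of the reference force, hip-reaction relative difference
#' <= 16%, elastic share of the distal-tibia displacement <= 5%, frontal
#' tibia-axis angle < 3 degrees).
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    body_mass_kg = 62,
    segment_masses_kg = list(thigh = 6.22, leg_foot = 3.8),
    materials = list(
      bone      = list(E = 17000, nu = 0.3),
      menisci   = list(E = 120,   nu = 0.45),
      cartilage = list(E = 15,    nu = 0.45),
      tendon    = list(E = 900,   nu = 0.3)
    ),
    springs = list(
      grounding_N_mm = 1e9,
      stabilisation_N_mm = 1,
      tendon = list(E = 900, A = 160, L = 50, n = 3),
      interface_N_mm = 1e5   # fibula/patella bonded-interface stand-ins
    ),
    thresholds = list(
      spring_frac_pct = 5,
      rel_diff_pct = 16,
      elastic_frac_pct = 5,
      elastic_abs_mm = 5,    # "nearly zero" at limb scale (~0.6% of length)
      frontal_angle_deg = 3
    ),
    gait = list(),           # overrides of default_gait()
    geometry = list(
      element_size = 10,
      # frustum bones: wide metaphyses at the knee (r ~ 26 mm), slimmer
      # diaphyses/epiphyses away from it, hollow cortical wall
      femur      = list(length = 390, r_out = c(26, 16), r_in = c(18, 10), origin = c(0, 400, 0)),
      knee_layer = list(length = 10,  r_out = 26, r_in = 18, origin = c(0, 390, 0)),
      tibia      = list(length = 380, r_out = c(12, 26), r_in = c(7, 18), origin = c(0, 10, 0)),
      fibula     = list(length = 340, r_out = 6,  r_in = 3.5, origin = c(38, 30, 0)),
      patella    = list(length = 28,  r_out = 9,  r_in = 5,  origin = c(0, 400, 40)),
      hip_centre = c(0, 790, 0),
      knee_centre = c(0, 395, 0),
      calcaneus = c(0, 5, -45),
      # residual mismatch between the RB-model geometry and the FE geometry
      # (two donors, aligned by 3-point registration on the femur): a small
      # residual rotation of the RB attachment frame about the femoral-head
      # centre, and an antero-posterior offset of the leg-segment
      # attachments (the two tibiae differ in form, so the malleoli do not
      # align even after the femur-based registration)
      donor = list(rotation_deg = 0.5, leg_offset = c(0, 0, 12)),
      attachment = list(half_axial = 10, half_angle = 50,
                        jitter_axial = 6, jitter_angle = 2, jitter_pelvis = 4)
    ),
    seed = 1L
  )
}

# Structural + range validation of a config list against the defaults.
.validate_config <- function(cfg) {
  defaults <- default_config()
  check_keys <- function(x, ref, path = "") {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown)) {
      stop(sprintf("unknown config key%s: %s",
                   if (length(unknown) > 1) "s" else "",
                   paste0(path, unknown, collapse = ", ")))
    }
    for (k in names(x)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && k != "gait" &&
          !k %in% c("femur", "knee_layer", "tibia", "fibula", "patella")) {
        if (!is.list(x[[k]])) stop(sprintf("config key '%s%s' must be a list", path, k))
        check_keys(x[[k]], ref[[k]], paste0(path, k, "$"))
      }
    }
  }
  check_keys(cfg, defaults)
  if (cfg$body_mass_kg <= 0) stop("body_mass_kg must be positive")
  for (m in names(cfg$materials)) {
    mat <- cfg$materials[[m]]
    if (mat$E <= 0) stop(sprintf("material '%s': E must be positive", m))
    if (mat$nu < 0 || mat$nu >= 0.5) stop(sprintf("material '%s': nu must be in [0, 0.5)", m))
  }
  sp <- cfg$springs
  if (sp$grounding_N_mm <= 0 || sp$stabilisation_N_mm <= 0 || sp$interface_N_mm <= 0) {
    stop("spring stiffnesses must be positive")
  }
  with(sp$tendon, if (E <= 0 || A <= 0 || L <= 0 || n < 1) {
    stop("tendon spring parameters must be positive (and n >= 1)")
  })
  th <- cfg$thresholds
  for (k in c("spring_frac_pct", "rel_diff_pct", "elastic_frac_pct")) {
    if (th[[k]] <= 0 || th[[k]] > 100) stop(sprintf("threshold '%s' must be in (0, 100]", k))
  }
  invisible(cfg)
}

#' Merge user configuration over the defaults and validate
#'
#' @param config partial configuration list (possibly empty).
#' @return complete, validated configuration.
#' @export
stance_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  .validate_config(cfg)
  cfg
}
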