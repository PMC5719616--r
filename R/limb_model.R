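# Assembly of the synthetic lower limb: bone meshes, muscle table with
# element subdivisions, attachment patches, landmarks.

# Rotation closure: rotates point rows about `centre` around unit `axis` by
# `deg` degrees (Rodrigues).
.rot_about <- function(centre, axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  S <- .skew3(u)
  R <- diag(3) + sin(th) * S + (1 - cos(th)) * (S %*% S)
  function(points) {
    sweep(sweep(as.matrix(points), 2, centre) %*% t(R), 2, centre, `+`)
  }
}

# Angular conventions for parts whose axis is +y with the default frame
# (theta = 0 lateral +x, theta = -90 anterior +z, 180 medial, +90 posterior).
.TH_LAT <- 0; .TH_ANT <- -90; .TH_MED <- 180; .TH_POST <- 90

#' Muscle definition table of the synthetic lower limb
#'
#' One row per applied-force slot. The 29 muscles that bridge the hip and
#' knee joints are subdivided into 122 line elements; the adductor magnus
#' and adductor brevis carry three slots each (distal/mid/proximal) and the
#' other 27 muscles one slot each, so recombination yields 33 applied
#' forces. Attachments are expressed in part-local cylindrical coordinates
#' (`s` mm from the part base, `theta` degrees) for modelled bones, and as
#' absolute points for the pelvis (off-model origin) and the calcaneus
#' (remote-point insertion). `strength_N` is the whole-muscle strength; each
#' element of a muscle receives an equal share.
#'
#' @return data.frame with one row per slot (33 rows, 122 elements in total).
#' @export
default_muscle_defs <- function() {
  L <- list()
  slot <- function(muscle, slot_name, n_el, o_part, o1, o2, o3,
                   i_part, i1, i2, i3, strength) {
    data.frame(muscle = muscle, slot = slot_name, n_elements = n_el,
               origin_part = o_part, o1 = o1, o2 = o2, o3 = o3,
               insertion_part = i_part, i1 = i1, i2 = i2, i3 = i3,
               strength_N = strength, stringsAsFactors = FALSE)
  }
  # pelvis-origin hip muscles (origin = absolute pelvis point, insertion on femur)
  L <- c(L, list(
    slot("GluteusMaximus", "GluteusMaximus", 5, "pelvis", 40, 840, -40, "femur", 330, 45, NA, 1200),
    slot("GluteusMedius",  "GluteusMedius",  5, "pelvis", 50, 845, -20, "femur", 370, .TH_LAT, NA, 1000),
    slot("GluteusMinimus", "GluteusMinimus", 4, "pelvis", 45, 840, -5,  "femur", 365, -30, NA, 600),
    slot("Iliacus",        "Iliacus",        4, "pelvis", 10, 850, 40,  "femur", 350, 135, NA, 800),
    slot("Piriformis",     "Piriformis",     4, "pelvis", -20, 835, -50, "femur", 375, 20, NA, 300),
    slot("Pectineus",      "Pectineus",      4, "pelvis", -20, 845, 25, "femur", 340, 150, NA, 300),
    slot("ObturatorInternus", "ObturatorInternus", 4, "pelvis", -15, 830, -10, "femur", 372, 30, NA, 250),
    slot("ObturatorExternus", "ObturatorExternus", 4, "pelvis", -18, 828, -20, "femur", 368, 60, NA, 250),
    slot("GemellusInferior",  "GemellusInferior",  4, "pelvis", -5, 825, -30, "femur", 370, 35, NA, 150),
    slot("GemellusSuperior",  "GemellusSuperior",  4, "pelvis", -8, 828, -35, "femur", 374, 25, NA, 150),
    slot("QuadratusFemoris",  "QuadratusFemoris",  4, "pelvis", -10, 820, -40, "femur", 355, 70, NA, 250),
    slot("AdductorBrevis", "AdductorBrevisDistal",   2, "pelvis", -30, 835, 10, "femur", 280, .TH_MED, NA, 400),
    slot("AdductorBrevis", "AdductorBrevisMid",      2, "pelvis", -30, 835, 10, "femur", 300, .TH_MED, NA, 400),
    slot("AdductorBrevis", "AdductorBrevisProximal", 2, "pelvis", -30, 835, 10, "femur", 320, .TH_MED, NA, 400),
    slot("AdductorLongus", "AdductorLongus", 4, "pelvis", -32, 840, 20, "femur", 230, 170, NA, 500),
    slot("AdductorMagnus", "AdductorMagnusDistal",   2, "pelvis", -28, 825, 0, "femur", 120, 175, NA, 1100),
    slot("AdductorMagnus", "AdductorMagnusMid",      2, "pelvis", -28, 825, 0, "femur", 200, 175, NA, 1100),
    slot("AdductorMagnus", "AdductorMagnusProximal", 2, "pelvis", -28, 825, 0, "femur", 280, 175, NA, 1100),
    # pelvis-origin two-joint muscles inserting below the knee
    slot("TensorFasciaeLatae", "TensorFasciaeLatae", 4, "pelvis", 55, 845, 20, "tibia", 350, .TH_LAT, NA, 300),
    slot("Sartorius", "Sartorius", 4, "pelvis", 30, 855, 45, "tibia", 335, -135, NA, 250),
    slot("Gracilis",  "Gracilis",  4, "pelvis", -35, 830, 20, "tibia", 330, -140, NA, 250),
    slot("BicepsFemorisCaputLongum", "BicepsFemorisCaputLongum", 4, "pelvis", -15, 815, -45, "fibula", 330, 45, NA, 700),
    slot("Semimembranosus", "Semimembranosus", 4, "pelvis", -20, 812, -40, "tibia", 355, 135, NA, 1000),
    slot("Semitendinosus",  "Semitendinosus",  4, "pelvis", -25, 815, -35, "tibia", 340, 165, NA, 400),
    slot("RectusFemoris",   "RectusFemoris",   4, "pelvis", 25, 850, 35, "patella", 25, .TH_ANT, NA, 900),
    # femur-origin knee muscles
    slot("VastusIntermedius", "VastusIntermedius", 4, "femur", 200, .TH_ANT, NA, "patella", 24, -60, NA, 1200),
    slot("VastusLateralis",   "VastusLateralis",   4, "femur", 180, -45, NA, "patella", 22, .TH_LAT, NA, 1500),
    slot("VastusMedialis",    "VastusMedialis",    4, "femur", 160, -135, NA, "patella", 22, .TH_MED, NA, 1300),
    slot("BicepsFemorisCaputBreve", "BicepsFemorisCaputBreve", 4, "femur", 150, 45, NA, "fibula", 325, 30, NA, 400),
    slot("Popliteus", "Popliteus", 4, "femur", 10, 30, NA, "tibia", 330, 110, NA, 200),
    slot("Plantaris", "Plantaris", 4, "femur", 15, 60, NA, "calcaneus", NA, NA, NA, 150),
    slot("GastrocnemiusMedialis", "GastrocnemiusMedialis", 4, "femur", 12, 120, NA, "calcaneus", NA, NA, NA, 1100),
    slot("GastrocnemiusLateralis", "GastrocnemiusLateralis", 4, "femur", 12, 60, NA, "calcaneus", NA, NA, NA, 700)
  ))
  do.call(rbind, L)
}

# Resolve a slot attachment (centre point + part) given the part specs and
# the calcaneus location. Returns list(part, point).
.resolve_attachment <- function(part, c1, c2, c3, specs, calcaneus) {
  if (part == "pelvis") {
    list(part = "pelvis", point = c(c1, c2, c3))
  } else if (part == "calcaneus") {
    list(part = "calcaneus", point = calcaneus)
  } else {
    list(part = part, point = cyl_point(specs[[part]], c1, c2))
  }
}

#' Generate the full synthetic lower limb
#'
#' Builds the four bone meshes (femur, tibia, fibula, patella) plus a soft
#' knee layer bonding femur and tibia, places landmarks, generates the
#' 122-element muscle table with per-element attachment scatter, and cuts
#' one attachment patch per slot end on each modelled bone, plus the
#' coupling patches (femoral-head cap, distal-tibia cap, tibial tuberosity,
#' patellar base, patellofemoral facing surfaces, tibiofibular interfaces).
#'
#' The femur/knee-layer/tibia chain is generated with a shared cross-section
#' discretisation so the interface annuli are node-conforming and can be
#' bonded by node merging. Fibula and patella are joined by stiff interface
#' springs instead (their tubes are not conforming).
#'
#' @param config pipeline config, see [default_config()].
#' @param seed integer seed for the attachment scatter.
#' @return object of class `stance_limb`: parts, muscle element table, slot
#'   table, joint centres, calcaneus point, segment map, config.
#' @export
gen_lower_limb <- function(config = default_config(), seed = 1L) {
  geo <- config$geometry
  es <- geo$element_size
  r_knee <- max(geo$knee_layer$r_out)
  n_th_main <- max(10L, ceiling(2 * pi * r_knee / es))

  spec_of <- function(nm, extra = list()) {
    sp <- geo[[nm]]
    sp$name <- nm
    sp$element_size <- es
    utils::modifyList(sp, extra)
  }
  specs <- list(
    femur = spec_of("femur", list(
      n_theta = n_th_main, n_radial = 1L,
      landmarks = list(
        femoral_head_centre = c(geo$femur$length, 0, NA),
        lateral_epicondyle = c(5, .TH_LAT, 15),
        medial_epicondyle = c(5, .TH_MED, 15)))),
    knee_layer = spec_of("knee_layer", list(n_theta = n_th_main, n_radial = 1L)),
    tibia = spec_of("tibia", list(
      n_theta = n_th_main, n_radial = 1L,
      landmarks = list(
        medial_malleolus = c(5, .TH_MED, 12),
        tibial_tuberosity = c(345, .TH_ANT, NA)))),
    fibula = spec_of("fibula"),
    patella = spec_of("patella")
  )
  parts <- lapply(specs, gen_bone_mesh, seed = seed)

  defs <- default_muscle_defs()
  att <- geo$attachment
  set.seed(seed)
  rows <- vector("list", nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    n_muscle_el <- sum(defs$n_elements[defs$muscle == d$muscle])
    per_el_strength <- d$strength_N / n_muscle_el
    el <- vector("list", d$n_elements)
    for (e in seq_len(d$n_elements)) {
      jpt <- function(part, c1, c2, c3) {
        if (part == "pelvis") {
          list(part = part,
               point = c(c1, c2, c3) + stats::runif(3, -att$jitter_pelvis, att$jitter_pelvis))
        } else if (part == "calcaneus") {
          list(part = part, point = geo$calcaneus)     # exact: remote-point transfer
        } else {
          list(part = part,
               point = cyl_point(specs[[part]],
                                 c1 + stats::runif(1, -att$jitter_axial, att$jitter_axial),
                                 c2 + stats::runif(1, -att$jitter_angle, att$jitter_angle)))
        }
      }
      o <- jpt(d$origin_part, d$o1, d$o2, d$o3)
      ins <- jpt(d$insertion_part, d$i1, d$i2, d$i3)
      el[[e]] <- data.frame(
        element = sprintf("%s_%d", d$slot, e), muscle = d$muscle, slot = d$slot,
        origin_part = o$part, ox = o$point[1], oy = o$point[2], oz = o$point[3],
        insertion_part = ins$part, ix = ins$point[1], iy = ins$point[2], iz = ins$point[3],
        strength_N = per_el_strength, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, el)
  }
  elements <- do.call(rbind, rows)

  # slot table with patch references and slot-centre application points
  slots <- defs
  slots$origin_patch <- NA_character_
  slots$insertion_patch <- NA_character_
  patch_specs <- list(femur = list(), knee_layer = list(), tibia = list(),
                      fibula = list(), patella = list())
  add_patch <- function(part, name, c1, c2, surface = "outer",
                        half_axial = att$half_axial, half_angle = att$half_angle) {
    ctr <- cyl_point(specs[[part]], c1, c2)
    patch_specs[[part]][[length(patch_specs[[part]]) + 1L]] <<-
      list(name = name, centre = ctr, half_axial = half_axial,
           half_angle = half_angle, surface = surface)
    ctr
  }
  slots$o_point <- slots$i_point <- vector("list", nrow(slots))
  for (i in seq_len(nrow(slots))) {
    d <- slots[i, ]
    o <- .resolve_attachment(d$origin_part, d$o1, d$o2, d$o3, specs, geo$calcaneus)
    ins <- .resolve_attachment(d$insertion_part, d$i1, d$i2, d$i3, specs, geo$calcaneus)
    slots$o_point[[i]] <- o$point
    slots$i_point[[i]] <- ins$point
    if (!o$part %in% c("pelvis", "calcaneus")) {
      slots$origin_patch[i] <- paste0(d$slot, "_org")
      add_patch(o$part, slots$origin_patch[i], d$o1, d$o2)
    }
    if (!ins$part %in% c("pelvis", "calcaneus")) {
      slots$insertion_patch[i] <- paste0(d$slot, "_ins")
      add_patch(ins$part, slots$insertion_patch[i], d$i1, d$i2)
    }
  }
  # coupling patches
  add_patch("femur", "femoral_head_cap", geo$femur$length, 0, surface = "cap",
            half_axial = 2, half_angle = 180)
  add_patch("tibia", "distal_tibia_cap", 0, 0, surface = "cap",
            half_axial = 2, half_angle = 180)
  add_patch("tibia", "tibial_tuberosity", 345, .TH_ANT, half_axial = 8, half_angle = 35)
  add_patch("patella", "patella_base_cap", 0, 0, surface = "cap",
            half_axial = 2, half_angle = 180)
  add_patch("patella", "patella_facet", geo$patella$length / 2, .TH_POST,
            half_axial = geo$patella$length / 2 + 1, half_angle = 60)
  add_patch("femur", "trochlea", 5, .TH_ANT, half_axial = 6, half_angle = 45)
  add_patch("fibula", "fibula_head", geo$fibula$length, .TH_MED, surface = "any",
            half_axial = 8, half_angle = 120)
  add_patch("fibula", "fibula_distal", 0, .TH_MED, surface = "any",
            half_axial = 8, half_angle = 120)
  f_or <- geo$fibula$origin
  t_sp <- specs$tibia
  # tibia-side tibiofibular patches sit laterally, facing the fibula ends
  add_patch("tibia", "tibia_fibula_prox",
            f_or[2] + geo$fibula$length - t_sp$origin[2], .TH_LAT,
            half_axial = 8, half_angle = 40)
  add_patch("tibia", "tibia_fibula_dist", f_or[2] - t_sp$origin[2], .TH_LAT,
            half_axial = 8, half_angle = 40)

  for (p in names(patch_specs)) {
    if (length(patch_specs[[p]])) {
      parts[[p]] <- gen_attachment_patches(parts[[p]], patch_specs[[p]])
    }
  }

  # RB-stage geometry: the rigid-body model "donor" differs from the FE
  # geometry by what remains after the 3-point femur registration — a small
  # residual rotation about the femoral-head centre plus an offset of the
  # leg-segment attachments (the two tibiae differ in form). The RB stage
  # works in its own attachment frame; the FE stage applies the recruited
  # forces on the unperturbed patches.
  donor <- utils::modifyList(list(rotation_deg = 0, leg_offset = c(0, 0, 0)),
                             geo$donor %||% list())
  phi <- donor$rotation_deg
  leg_parts <- c("tibia", "fibula", "patella", "calcaneus")
  rb <- list(knee_centre = geo$knee_centre, tibia_axis = c(0, 1, 0),
             calcaneus = geo$calcaneus,
             femur_markers = rbind(
               parts$femur$landmarks$femoral_head_centre,
               (parts$femur$landmarks$lateral_epicondyle +
                  parts$femur$landmarks$medial_epicondyle) / 2,
               parts$femur$landmarks$medial_epicondyle))
  if (phi != 0 || any(donor$leg_offset != 0)) {
    rot <- .rot_about(geo$hip_centre, c(1, 0, 0), phi)
    for (side in list(c("origin_part", "ox", "oy", "oz"),
                      c("insertion_part", "ix", "iy", "iz"))) {
      cols <- side[2:4]
      pts <- rot(as.matrix(elements[, cols]))
      on_leg <- elements[[side[1]]] %in% leg_parts
      pts[on_leg, ] <- sweep(pts[on_leg, , drop = FALSE], 2, donor$leg_offset, `+`)
      elements[, cols] <- pts
    }
    rb$knee_centre <- as.numeric(rot(matrix(geo$knee_centre, 1)))
    rb$tibia_axis <- as.numeric(rot(matrix(geo$hip_centre + c(0, 1, 0), 1))) - geo$hip_centre
    rb$femur_markers <- rot(rb$femur_markers)
    rb$calcaneus <- as.numeric(rot(matrix(geo$calcaneus, 1))) + donor$leg_offset
  }

  structure(list(
    parts = parts,
    specs = specs,
    elements = elements,
    slots = slots,
    rb = rb,
    hip_centre = geo$hip_centre,
    knee_centre = geo$knee_centre,
    knee_axis = c(1, 0, 0),
    calcaneus = geo$calcaneus,
    segment_of_part = c(femur = "thigh", knee_layer = "leg_foot",
                        tibia = "leg_foot", fibula = "leg_foot",
                        patella = "leg_foot", calcaneus = "leg_foot"),
    config = config
  ), class = "stance_limb")
}

#' @export
print.stance_limb <- function(x, ...) {
  cat(sprintf("stance_limb: %d parts, %d muscles, %d slots, %d elements\n",
              length(x$parts), length(unique(x$elements$muscle)),
              nrow(x$slots), nrow(x$elements)))
  for (p in x$parts) print(p)
  invisible(x)
}
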