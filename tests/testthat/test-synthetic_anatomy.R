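# Synthetic anatomy: mesh generation, patches, gait tables, penetration.

test_that("generated tube meshes are valid, watertight and deterministic", {
  specs <- list(
    list(name = "femurlike", length = 400, r_out = 15, r_in = 10, element_size = 8),
    list(name = "frustum", length = 200, r_out = c(20, 10), r_in = c(14, 6),
         element_size = 9),
    list(name = "stubby", length = 30, r_out = 12, r_in = 4, element_size = 6))
  for (sp in specs) {
    m <- gen_bone_mesh(sp, seed = 7L)
    expect_gt(nrow(m$tets), 0)
    expect_true(all(tet_volumes(m) > 0))
    expect_true(is_watertight(m))
    expect_true(validate_mesh(m))
    m2 <- gen_bone_mesh(sp, seed = 7L)
    expect_identical(m$nodes, m2$nodes)
    expect_identical(m$tets, m2$tets)
    # requested axis-end landmarks sit on the axis
    expect_equal(m$landmarks[[paste0(sp$name, "_base")]], c(0, 0, 0))
    expect_equal(m$landmarks[[paste0(sp$name, "_tip")]], c(0, sp$length, 0))
  }
})

test_that("halving the element size refines the mesh by at least 4x", {
  sp <- list(name = "f", length = 400, r_out = 15, r_in = 10, element_size = 8)
  n1 <- nrow(gen_bone_mesh(sp)$tets)
  n2 <- nrow(gen_bone_mesh(utils::modifyList(sp, list(element_size = 4)))$tets)
  expect_gte(n2 / n1, 4)
})

test_that("degenerate radii are rejected", {
  expect_error(gen_bone_mesh(list(name = "bad", length = 100, r_out = 5,
                                  r_in = 7, element_size = 5)),
               "inner radius")
})

test_that("an end-cap patch recovers the annulus area within 10%", {
  m <- small_tube(length = 100, r_out = 15, r_in = 10, element_size = 5)
  analytic <- pi * (15^2 - 10^2)
  expect_lt(abs(patch_area(m, "top") - analytic) / analytic, 0.10)
})

test_that("disjoint patch specs give disjoint facet sets; empty selections error", {
  m <- gen_bone_mesh(list(name = "t", length = 100, r_out = 8, r_in = 5,
                          element_size = 6))
  m <- gen_attachment_patches(m, list(
    list(name = "low", centre = cyl_point(attr(m, "spec"), 20, 0),
         half_axial = 10, half_angle = 60),
    list(name = "high", centre = cyl_point(attr(m, "spec"), 80, 180),
         half_axial = 10, half_angle = 60)))
  key <- function(f) paste(apply(f, 1, function(r) paste(sort(r), collapse = "_")))
  expect_length(intersect(key(m$patches$low), key(m$patches$high)), 0)
  expect_gt(patch_area(m, "low"), 0)
  expect_error(
    gen_attachment_patches(m, list(list(name = "off", centre = c(500, 500, 500),
                                        half_axial = 5, half_angle = 20))),
    "bounding box|empty")
})

test_that("patches are connected boundary facet sets", {
  limb <- fixture_limb()
  for (p in limb$parts) {
    if (!length(p$patches)) next
    bkey <- stancelimb:::.facet_key(boundary_facets(p))
    for (pn in names(p$patches)) {
      f <- p$patches[[pn]]
      expect_true(all(stancelimb:::.facet_key(f) %in% bkey), label = pn)
      comp <- stancelimb:::.facet_components(f)
      expect_equal(length(unique(comp)), 1L, label = pn)
    }
  }
})

test_that("gait table carries the study defaults", {
  gait <- gen_gait_table(stance_config())
  expect_length(gait, 5)
  expect_equal(gait[[4]]$knee_flexion, 14)
  expect_equal(gait[[5]]$knee_flexion, 38)
  mags <- vapply(gait, function(p) sqrt(sum(p$grf^2)), 0)
  expect_equal(mags, c(253, 592, 483, 644, 15), tolerance = 1e-12)
  # first GRF peak of the order of body weight for a 62 kg subject
  expect_lt(abs(mags[2] - 62 * 9.81) / (62 * 9.81), 0.05)
})

test_that("zero accelerations give zero inertial forces; mass must be positive", {
  cfg <- stance_config(list(gait = list(
    inertial_thigh = matrix(0, 5, 3), inertial_legfoot = matrix(0, 5, 3))))
  gait <- gen_gait_table(cfg)
  for (p in gait) {
    expect_equal(inertial_force(list(mass = 6.22, accel = p$segment_accel$thigh))$force,
                 c(0, 0, 0))
  }
  expect_error(gen_gait_table(stance_config(list(body_mass_kg = -1))), "positive")
})

test_that("default gait satisfies the quasi-static premise by construction", {
  cfg <- stance_config()
  qs <- quasi_static_ratio(gen_gait_table(cfg), cfg$segment_masses_kg)
  expect_true(all(qs$ratio[qs$considered] <= 0.10))
  expect_true(attr(qs, "negligible"))
})

test_that("penetration checks: separated, overlapping and tangent meshes", {
  a <- gen_bone_mesh(list(name = "a", length = 50, r_out = 5, r_in = 2,
                          element_size = 5))
  b_far <- gen_bone_mesh(list(name = "b", length = 50, r_out = 5, r_in = 2,
                              element_size = 5, origin = c(20, 0, 0)))
  expect_true(check_no_penetration(a, b_far)$ok)
  # deeply overlapping near-solid meshes (offset by half an element so
  # nodes fall strictly inside the other mesh's elements)
  solid <- gen_bone_mesh(list(name = "s", length = 30, r_out = 5, r_in = 1,
                              element_size = 2, n_radial = 2))
  solid2 <- gen_bone_mesh(list(name = "s2", length = 30, r_out = 5, r_in = 1,
                               element_size = 2, n_radial = 2,
                               origin = c(0.6, 0.9, 0.4)))
  overlap <- check_no_penetration(solid, solid2, tol = 0.01)
  expect_false(overlap$ok)
  expect_gt(max(overlap$a_depth, overlap$b_depth), 0.01)
  # tangent: solid cylinders touching along a line (gap 0) must pass at tol
  s1 <- gen_bone_mesh(list(name = "s1", length = 40, r_out = 5, r_in = 1,
                           element_size = 4))
  s2 <- gen_bone_mesh(list(name = "s2", length = 40, r_out = 5, r_in = 1,
                           element_size = 4, origin = c(10, 0, 0)))
  expect_true(check_no_penetration(s1, s2, tol = 0.01)$ok)
  # oracle: no node of s1 lies strictly inside s2 (point-in-tet test)
  expect_false(any(points_in_mesh(s2, s1$nodes)))
})

test_that("the synthetic limb reproduces the muscle bookkeeping of the study", {
  limb <- fixture_limb()
  expect_equal(nrow(limb$elements), 122)
  expect_equal(nrow(limb$slots), 33)
  expect_length(unique(limb$elements$muscle), 29)
  # adductor magnus and brevis carry three slots each, everyone else one
  tab <- table(limb$slots$muscle)
  expect_equal(unname(tab[["AdductorMagnus"]]), 3L)
  expect_equal(unname(tab[["AdductorBrevis"]]), 3L)
  expect_true(all(tab[setdiff(names(tab), c("AdductorMagnus", "AdductorBrevis"))] == 1L))
  # every muscle subdivided into at least two elements
  expect_true(all(table(limb$elements$muscle) >= 2))
  # assembled parts do not interpenetrate
  expect_true(check_no_penetration(limb$parts$femur, limb$parts$patella)$ok)
  expect_true(check_no_penetration(limb$parts$tibia, limb$parts$fibula)$ok)
})
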