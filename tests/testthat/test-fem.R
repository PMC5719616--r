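# FE solver: element matrices, assembly, ties, springs, remote points,
# static solves and equilibrium identities.

test_that("tendon spring stiffness follows k = E A / L with a parallel split", {
  k <- tendon_spring_stiffness(E = 900, A = 160, L = 50, n_springs = 3)
  expect_equal(k$k_total, 2880)
  expect_equal(k$k_per_spring, 960)
  expect_equal(tendon_spring_stiffness(17000, 100, 100, 1)$k_total, 17000)
  # doubling the area doubles the stiffness
  expect_equal(tendon_spring_stiffness(900, 320, 50)$k_total,
               2 * tendon_spring_stiffness(900, 160, 50)$k_total)
  expect_error(tendon_spring_stiffness(900, 160, 0), "positive")
})

test_that("tet4 stiffness is symmetric PSD with six rigid-body modes", {
  set.seed(5)
  for (case in 1:5) {
    X <- matrix(runif(12, 0, 10), 4, 3)
    if (det(cbind(1, X)) < 1) next     # keep well-shaped tets
    K <- tet4_stiffness(X, list(E = 17000, nu = 0.3))
    expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)
    expect_true(all(ev > -1e-9 * max(ev)))
    # rigid translation in the null space
    for (tdir in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      expect_lt(max(abs(K %*% rep(tdir, 4))), 1e-9 * max(abs(K)))
    }
  }
  expect_error(tet4_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                              list(E = 1, nu = 0)), "degenerate")
})

test_that("tet4 stiffness matches the quadrature oracle", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- tet4_stiffness(X, list(E = 1, nu = 0))
  K_o <- oracle_tet4_stiffness(X, E = 1, nu = 0)
  expect_lt(max(abs(K - K_o)), 1e-8)
  # a skewed tet with a realistic modulus
  X2 <- rbind(c(0, 0, 0), c(2, 0.3, 0), c(0.4, 1.7, 0.2), c(0.1, 0.2, 1.5))
  K2 <- tet4_stiffness(X2, list(E = 17000, nu = 0.3))
  K2_o <- oracle_tet4_stiffness(X2, E = 17000, nu = 0.3)
  expect_lt(max(abs(K2 - K2_o)) / max(abs(K2)), 1e-7)
})

test_that("uniaxial patch test is exact", {
  bar <- small_tube(length = 100, r_out = 6, r_in = 3, element_size = 5)
  base <- sort(unique(as.vector(bar$patches$base)))
  sys <- assemble_system(list(bar = bar), list(bar = list(E = 17000, nu = 0)),
                         fixed = list(list(part = "bar", nodes = base)))
  sigma <- 2
  A <- patch_area(bar, "top")
  loads <- add_patch_load(sys, node_loads(sys), bar, "bar", "top", c(0, sigma * A, 0))
  res <- solve_static(sys, loads)
  eps <- res$strains$bar$tensor
  expect_lt(max(abs(eps[, "yy"] - sigma / 17000)), 1e-10)
  expect_lt(max(abs(eps[, c("xx", "zz", "xy", "yz", "zx")])), 1e-10)
})

test_that("bonded tie by node merging reproduces the continuous bar", {
  mk <- function(name, origin, len, nax) {
    gen_bone_mesh(list(name = name, length = len, r_out = 6, r_in = 3,
                       element_size = 5, n_axial = nax, n_theta = 8,
                       origin = origin))
  }
  one <- gen_attachment_patches(mk("one", c(0, 0, 0), 100, 20), list(
    list(name = "base", centre = c(0, 0, 0), half_axial = 1, half_angle = 180, surface = "cap"),
    list(name = "top", centre = c(0, 100, 0), half_axial = 1, half_angle = 180, surface = "cap")))
  a <- gen_attachment_patches(mk("a", c(0, 0, 0), 50, 10), list(
    list(name = "base", centre = c(0, 0, 0), half_axial = 1, half_angle = 180, surface = "cap")))
  b <- gen_attachment_patches(mk("b", c(0, 50, 0), 50, 10), list(
    list(name = "top", centre = c(0, 100, 0), half_axial = 1, half_angle = 180, surface = "cap")))
  mat <- list(E = 17000, nu = 0.3)
  s1 <- assemble_system(list(one = one), list(one = mat),
                        fixed = list(list(part = "one",
                                          nodes = sort(unique(as.vector(one$patches$base))))))
  s2 <- assemble_system(list(a = a, b = b), list(a = mat, b = mat),
                        ties = list(list(a = "a", b = "b")),
                        fixed = list(list(part = "a",
                                          nodes = sort(unique(as.vector(a$patches$base))))))
  expect_equal(s2$ndof, s1$ndof)      # interface ring merged
  l1 <- add_patch_load(s1, node_loads(s1), one, "one", "top", c(120, 500, -60))
  l2 <- add_patch_load(s2, node_loads(s2), b, "b", "top", c(120, 500, -60))
  r1 <- solve_static(s1, l1)
  r2 <- solve_static(s2, l2)
  expect_equal(max(r2$node_disp_norm), max(r1$node_disp_norm), tolerance = 1e-10)
  # analytic check of the axial response: sigma = F / A
  sigA <- 500 / patch_area(one, "top")
  eps_mid <- r1$strains$one$tensor[, "yy"]
  expect_lt(abs(stats::median(eps_mid) - sigA / 17000) / (sigA / 17000), 0.05)
})

test_that("non-conforming declared ties list orphan nodes", {
  a <- small_tube(name = "a")
  b <- gen_bone_mesh(list(name = "b", length = 100, r_out = 6, r_in = 3,
                          element_size = 5, origin = c(0.37, 100, 0)))
  expect_error(
    assemble_system(list(a = a, b = b),
                    list(a = list(E = 1, nu = 0), b = list(E = 1, nu = 0)),
                    ties = list(list(a = "a", b = "b", a_patch = "top"))),
    "orphan")
})

test_that("a free part without springs is reported singular", {
  bar <- small_tube()
  sys <- assemble_system(list(bar = bar), list(bar = list(E = 100, nu = 0.3)))
  loads <- add_patch_load(sys, node_loads(sys), bar, "bar", "top", c(1, 0, 0))
  expect_error(solve_static(sys, loads), "singular")
})

test_that("grounded spring carries F with displacement F/k and reaction -F", {
  # a bar suspended only by grounded springs at its two end remotes: the
  # applied force at the top remote is carried by the top spring group
  # (F/k displacement), with very weak springs below pinning the leftover
  # rigid modes
  bar <- small_tube(length = 40, r_out = 6, r_in = 3, element_size = 6)
  k <- 250
  springs <- list()
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    springs[[length(springs) + 1L]] <- list(a = list(remote = "rp"), b = "ground",
                                            k = k, axis = ax, group = "g")
    # two separated weak anchors below: no rotation axis through the top
    # remote can pass through both, so all rigid modes are held
    springs[[length(springs) + 1L]] <- list(a = list(remote = "rb"), b = "ground",
                                            k = 1e-3, axis = ax, group = "weak")
    springs[[length(springs) + 1L]] <- list(a = list(remote = "rb2"), b = "ground",
                                            k = 1e-3, axis = ax, group = "weak")
  }
  sys <- assemble_system(
    list(bar = bar), list(bar = list(E = 2e5, nu = 0.3)),
    springs = springs,
    remote_points = list(
      rp = list(location = c(0, 40, 0), part = "bar", patch = "top"),
      rb = list(location = c(4, 0, 3), part = "bar", patch = "base"),
      rb2 = list(location = c(-4, 0, -3), part = "bar", patch = "base")))
  F <- c(0, -50, 0)
  loads <- add_remote_load(sys, loads = node_loads(sys), remote = "rp", force = F)
  res <- solve_static(sys, loads)
  urp <- remote_displacement(sys, res$u, "rp")
  expect_equal(urp[2], F[2] / k, tolerance = 1e-3)
  expect_equal(res$grounded_reactions$g, -F, tolerance = 1e-3)
  chk <- global_equilibrium_check(sys, res, loads)
  expect_true(chk$ok)
})

test_that("remote-point load transfer is statically equivalent", {
  bar <- small_tube(length = 80, r_out = 8, r_in = 4, element_size = 6)
  base <- sort(unique(as.vector(bar$patches$base)))
  sys <- assemble_system(list(bar = bar), list(bar = list(E = 17000, nu = 0.3)),
                         remote_points = list(
                           rp = list(location = c(5, 95, -12), part = "bar", patch = "top")),
                         fixed = list(list(part = "bar", nodes = base)))
  F <- c(30, -120, 45)
  loads <- add_remote_load(sys, node_loads(sys), "rp", F)
  lm <- matrix(loads[seq_len(3 * nrow(sys$nodes))], ncol = 3, byrow = TRUE)
  expect_equal(colSums(lm), F, tolerance = 1e-10)
  # zero moment about the remote location
  r <- sweep(sys$nodes, 2, c(5, 95, -12))
  M <- c(sum(r[, 2] * lm[, 3] - r[, 3] * lm[, 2]),
         sum(r[, 3] * lm[, 1] - r[, 1] * lm[, 3]),
         sum(r[, 1] * lm[, 2] - r[, 2] * lm[, 1]))
  expect_lt(max(abs(M)), 1e-8 * max(abs(F)) * 100)
})

test_that("solution is linear in the load and equilibrium holds for random loads", {
  bar <- small_tube(length = 100, r_out = 6, r_in = 3, element_size = 6)
  base <- sort(unique(as.vector(bar$patches$base)))
  sys <- assemble_system(list(bar = bar), list(bar = list(E = 17000, nu = 0.3)),
                         fixed = list(list(part = "bar", nodes = base)))
  set.seed(21)
  l0 <- add_patch_load(sys, node_loads(sys), bar, "bar", "top", c(10, -40, 25))
  r0 <- solve_static(sys, l0)
  r3 <- solve_static(sys, 3 * l0)
  expect_equal(r3$u, 3 * r0$u, tolerance = 1e-9)
  for (case in 1:10) {
    loads <- node_loads(sys)
    idx <- sample(length(loads), 30)
    loads[idx] <- rnorm(30, sd = 50)
    res <- solve_static(sys, loads)
    chk <- global_equilibrium_check(sys, res, loads)
    expect_true(chk$ok)
    expect_lt(chk$relative, 1e-6)
  }
})

test_that("rigid motions: zero strain for translations, O(theta^2) for rotations", {
  bar <- small_tube(length = 60, r_out = 6, r_in = 3, element_size = 6)
  sys <- assemble_system(list(bar = bar), list(bar = list(E = 1, nu = 0.25)))
  tets <- sys$parts_el$bar$tets
  strain_of <- function(u_nodes) {
    mx <- 0
    for (e in seq_len(nrow(tets))) {
      bv <- stancelimb:::.tet_B(sys$nodes[tets[e, ], , drop = FALSE])
      ue <- as.vector(t(u_nodes[tets[e, ], , drop = FALSE]))
      mx <- max(mx, max(abs(bv$B %*% ue)))
    }
    mx
  }
  u_tr <- matrix(rep(c(3, -2, 5), each = nrow(sys$nodes)), ncol = 3)
  expect_lt(strain_of(u_tr), 1e-12)
  for (theta in c(1e-3, 1e-2)) {
    rot <- stancelimb:::.rot_about(c(0, 30, 0), c(0.3, 0.8, 0.52), theta * 180 / pi)
    u_rot <- rot(sys$nodes) - sys$nodes
    expect_lt(strain_of(u_rot), theta^2 * 1.01)
  }
})

test_that("stabilisation-spring force equals k times its relative displacement", {
  an <- fixture_analysis()
  rep4 <- an$reports[[4]]
  res <- rep4$fe_result
  sysp <- place_remote(an$system, "cop", an$gait[[4]]$cop)
  k_stab <- an$config$springs$stabilisation_N_mm
  for (sf in res$spring_forces) {
    if (sf$group != "stabilisation") next
    expect_equal(sf$magnitude, k_stab * abs(sf$elongation[1]), tolerance = 1e-9,
                 label = sf$label)
  }
  # grounding springs pin the femoral head: displacement <= 1e-5 mm under
  # kN-level reactions through 1e9 N/mm springs
  uh <- remote_displacement(sysp, res$u, "femoral_head")
  expect_lt(sqrt(sum(uh^2)), 1e-5)
})

test_that("rigid remote-point coupling transmits loads and stiffens the patch", {
  bar <- small_tube(length = 80, r_out = 8, r_in = 4, element_size = 6)
  base <- sort(unique(as.vector(bar$patches$base)))
  sys <- assemble_system(list(bar = bar), list(bar = list(E = 17000, nu = 0.3)),
                         remote_points = list(
                           rp = list(location = c(0, 80, 0), part = "bar",
                                     patch = "top", coupling = "rigid")),
                         fixed = list(list(part = "bar", nodes = base)))
  loads <- add_remote_load(sys, node_loads(sys), "rp", c(50, 0, 0))
  res <- solve_static(sys, loads)
  chk <- global_equilibrium_check(sys, res, loads)
  expect_true(chk$ok)
  # the rigidly coupled cap moves as one plane: displacement spread ~ 0
  top_nodes <- sort(unique(as.vector(bar$patches$top)))
  gl <- sys$node_map$global[sys$node_map$part == "bar"][top_nodes]
  ux <- res$displacements[gl, 1]
  expect_lt(stats::sd(ux), 1e-8 * max(abs(ux)))
})
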