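# Muscle mapping: recombination, action-reaction pairing, traction
# distribution, rigid registration, frontal-plane axis check.

test_that("122 grouped elements recombine into 33 applied forces", {
  limb <- fixture_limb()
  applied <- recombine_elements(limb$elements, rep(1, nrow(limb$elements)))
  expect_equal(nrow(applied), 33)
  expect_setequal(applied$slot, limb$slots$slot)
})

test_that("recombination sums vectors per slot and keeps zero slots", {
  el <- data.frame(
    element = c("a_1", "a_2", "b_1"), muscle = c("a", "a", "b"),
    slot = c("a", "a", "b"),
    origin_part = "femur", ox = c(0, 0, 0), oy = c(10, 10, 5), oz = c(0, 0, 0),
    insertion_part = "tibia", ix = c(0, 0, 0), iy = c(0, 0, 0), iz = c(0, 0, 0),
    stringsAsFactors = FALSE)
  # single-element group: output equals the input force vector
  ap1 <- recombine_elements(el[3, ], 7)
  expect_equal(c(ap1$fx, ap1$fy, ap1$fz), 7 * c(0, 1, 0))
  # two equal elements with opposite directions cancel but keep the slot
  el2 <- el[1:2, ]
  el2$oy[2] <- -10                      # second pulls the other way
  ap2 <- recombine_elements(el2, c(3, 3))
  expect_equal(nrow(ap2), 1)
  expect_equal(c(ap2$fx, ap2$fy, ap2$fz), c(0, 0, 0))
  # unknown group label in the grouping rule errors
  expect_error(recombine_elements(el, c(1, 1, 1), grouping = c(a = "a")),
               "unknown group label")
})

test_that("action-reaction pairs cancel in force and (collinear) in moment", {
  set.seed(11)
  n <- 12
  org <- matrix(runif(3 * n, -50, 50), n, 3)
  dir <- matrix(rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  ins <- org + dir * runif(n, 20, 80)
  mag <- runif(n, 10, 500)
  applied <- data.frame(slot = sprintf("s%d", 1:n),
                        fx = -dir[, 1] * mag, fy = -dir[, 2] * mag, fz = -dir[, 3] * mag,
                        origin_part = "femur", insertion_part = "tibia",
                        ox = org[, 1], oy = org[, 2], oz = org[, 3],
                        ix = ins[, 1], iy = ins[, 2], iz = ins[, 3])
  loads <- build_action_reaction(applied, modelled_parts = c("femur", "tibia"))
  expect_equal(nrow(loads), 2 * n)
  F <- as.matrix(loads[, c("fx", "fy", "fz")])
  P <- as.matrix(loads[, c("px", "py", "pz")])
  expect_lt(max(abs(colSums(F))), 1e-10 * max(abs(F)))
  M <- colSums(cbind(P[, 2] * F[, 3] - P[, 3] * F[, 2],
                     P[, 3] * F[, 1] - P[, 1] * F[, 3],
                     P[, 1] * F[, 2] - P[, 2] * F[, 1]))
  expect_lt(max(abs(M)), 1e-10 * max(abs(P)) * max(abs(F)))
  # off-model origin: insertion load only
  applied$origin_part <- "pelvis"
  single <- build_action_reaction(applied, modelled_parts = c("femur", "tibia"))
  expect_equal(nrow(single), n)
  expect_true(all(single$end == "insertion"))
  expect_true(all(!single$paired))
})

test_that("uniform traction conserves the applied force exactly", {
  m <- small_tube(length = 60, r_out = 8, r_in = 5, element_size = 5)
  A <- patch_area(m, "top")
  F <- c(25, -90, 40)
  dt <- distribute_traction(m, "top", F)
  expect_equal(colSums(dt$loads), F, tolerance = 1e-14)
  expect_equal(dt$traction, F / A)
  z <- distribute_traction(m, "top", c(0, 0, 0))
  expect_true(all(z$loads == 0))
  # single triangle: each node receives a third of the force
  tri <- tet_part_mesh("tri", rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       matrix(c(1, 2, 3, 4), 1), validate = FALSE)
  tri$patches$one <- matrix(c(1, 2, 3), 1)
  d1 <- distribute_traction(tri, "one", c(9, 0, 3))
  expect_equal(d1$loads, rbind(c(3, 0, 1), c(3, 0, 1), c(3, 0, 1)))
  # force / area: 100 N over the 0.5 mm^2 triangle is a 200 MPa traction
  expect_equal(distribute_traction(tri, "one", c(0, 100, 0))$traction, c(0, 200, 0))
  # zero-area patch errors
  degen <- tri
  degen$patches$one <- matrix(c(1, 1, 1), 1)
  expect_error(distribute_traction(degen, "one", c(1, 0, 0)), "zero area")
})

test_that("3-point registration recovers constructed rigid transforms", {
  src <- rbind(c(0, 790, 0), c(0, 405, 0), c(-15, 405, 0))
  # identity
  id <- register_3pt(src, src)
  expect_equal(id$R, diag(3), tolerance = 1e-12)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(id$residual, 1e-10)
  # constructed rotation + translation recovered to 1e-9
  th <- 0.3
  R0 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t0 <- c(4, -7, 11)
  tgt <- sweep(src %*% t(R0), 2, t0, `+`)
  tr <- register_3pt(src, tgt)
  expect_lt(max(abs(tr$R - R0)), 1e-9)
  expect_lt(max(abs(tr$t - t0)), 1e-9)
  expect_lt(max(abs(apply_transform(tr, src) - tgt)), 1e-9)
  # orthonormal with det +1
  expect_lt(max(abs(crossprod(tr$R) - diag(3))), 1e-10)
  expect_equal(det(tr$R), 1, tolerance = 1e-10)
  # pure translation
  tr2 <- register_3pt(src, sweep(src, 2, c(1, 2, 3), `+`))
  expect_equal(tr2$R, diag(3), tolerance = 1e-9)
  expect_equal(tr2$t, c(1, 2, 3), tolerance = 1e-9)
  # collinear landmark triples are rejected
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(register_3pt(col, src), "collinear")
})

test_that("registration recovers random transforms (property)", {
  set.seed(3)
  for (case in 1:10) {
    src <- matrix(runif(9, -100, 100), 3, 3)
    while (stancelimb:::.norm3(stancelimb:::.cross3(src[2, ] - src[1, ],
                                                    src[3, ] - src[1, ])) < 50) {
      src <- matrix(runif(9, -100, 100), 3, 3)
    }
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    rot <- stancelimb:::.rot_about(c(0, 0, 0), ax, runif(1, -170, 170))
    t0 <- runif(3, -50, 50)
    tgt <- sweep(rot(src), 2, t0, `+`)
    tr <- register_3pt(src, tgt)
    expect_lt(max(abs(apply_transform(tr, src) - tgt)), 1e-9)
    expect_lt(tr$residual, 1e-9)
  }
})

test_that("frontal-plane axis angle and its acceptance flag", {
  a <- c(0, 1, 0)
  expect_equal(frontal_axis_angle(a, a)$angle_deg, 0)
  # axes differing by a 2 degree rotation about the frontal normal (z)
  rot2 <- stancelimb:::.rot_about(c(0, 0, 0), c(0, 0, 1), 2)
  b <- as.numeric(rot2(matrix(a, 1)))
  r <- frontal_axis_angle(b, a)
  expect_equal(r$angle_deg, 2, tolerance = 1e-6)
  expect_true(r$ok)
  rot10 <- stancelimb:::.rot_about(c(0, 0, 0), c(0, 0, 1), 10)
  expect_false(frontal_axis_angle(as.numeric(rot10(matrix(a, 1))), a)$ok)
  expect_error(frontal_axis_angle(c(0, 0, 1), a), "zero projection")
})
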