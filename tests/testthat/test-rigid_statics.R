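# Rigid-body statics: inertial bookkeeping, equilibrium assembly and
# min/max recruitment.

# planar toy linkage used across tests (y-z plane, knee axis = x)
toy_linkage <- list(hip_centre = c(0, 100, 0), knee_centre = c(0, 0, 0),
                    knee_axis = c(1, 0, 0),
                    segment_of_part = c(femur = "thigh", tibia = "leg_foot"))

toy_muscles <- function(rows) {
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(element = sprintf("m%d", i), muscle = sprintf("m%d", i),
               slot = sprintf("m%d", i),
               origin_part = "femur", ox = r$o[1], oy = r$o[2], oz = r$o[3],
               insertion_part = "tibia", ix = r$i[1], iy = r$i[2], iz = r$i[3],
               strength_N = r$N, stringsAsFactors = FALSE)
  }))
}

toy_position <- function(grf = c(0, -100, 0), cop = c(0, -50, 20),
                         active = c("m1", "m2")) {
  list(index = 1L, grf = grf, cop = cop, active_muscles = active)
}

test_that("inertial force magnitudes reproduce the printed table cells", {
  # thigh, position 2 and 3 of the reference gait data; the position-2
  # components give 14.46 N against a printed 15 N (the reference table's
  # own component rounding), so that cell is held to 1 N
  f2 <- inertial_force(list(mass = 1, accel = c(-12, -4, -7)))
  expect_equal(f2$magnitude, sqrt(209))
  expect_lte(abs(f2$magnitude_rounded - 15), 1)
  f3 <- inertial_force(list(mass = 1, accel = c(-3, -11, -2)))
  expect_equal(f3$magnitude_rounded, 12)
  z <- inertial_force(list(mass = 3.8, accel = c(0, 0, 0)))
  expect_equal(z$force, c(0, 0, 0))
  expect_equal(z$magnitude, 0)
  # m*a in newtons: kg times m/s^2
  expect_equal(inertial_force(list(mass = 2, accel = c(3, 0, 4)))$magnitude, 10)
})

test_that("quasi-static ratio divides printed inertial by GRF magnitudes", {
  gait <- list(
    list(index = 1L, grf = c(0, 592, 0),
         segment_accel = list(thigh = c(0, 0, 0), leg_foot = c(-41, -10, 9) / 3.8)),
    list(index = 2L, grf = c(0, 0, 0),
         segment_accel = list(thigh = c(1, 0, 0), leg_foot = c(0, 0, 0))))
  qs <- quasi_static_ratio(gait, list(thigh = 6.22, leg_foot = 3.8))
  # 43 N inertial force over 592 N GRF
  expect_equal(qs$ratio[1], sqrt(sum(c(-41, -10, 9)^2)) / 592, tolerance = 1e-12)
  expect_equal(round(qs$ratio[1], 3), 0.073)
  expect_true(is.infinite(qs$ratio[2]))
  expect_false(qs$considered[2])
  expect_true(attr(qs, "negligible"))
})

test_that("assembled equilibrium matches the hand-derived planar fixture", {
  # two parallel sagittal muscles: hand-derived coefficients (frozen):
  # leg force y row (1, 1); leg force z row (0, 0); knee-axis moment row
  # (-10, 15) from insertion offsets z = +10 and z = -15
  mus <- toy_muscles(list(
    list(o = c(0, 20, 10), i = c(0, -40, 10), N = 100),
    list(o = c(0, 20, -15), i = c(0, -40, -15), N = 100)))
  sys <- assemble_equilibrium(toy_linkage, toy_position(), mus)
  expect_equal(dim(sys$C), c(12, 2))
  expect_equal(sys$C[2, ], c(1, 1))          # leg force y
  expect_equal(sys$C[3, ], c(0, 0))          # leg force z
  expect_equal(sys$C[4, ], c(-10, 15))       # knee-axis moment
  expect_equal(sys$d[1:3], c(0, 100, 0))
  expect_equal(sys$d[4:6], c(-2000, 0, 0))
  # no muscles, zero GRF: homogeneous system
  sys0 <- assemble_equilibrium(toy_linkage,
                               toy_position(grf = c(0, 0, 0), active = character(0)),
                               mus)
  expect_equal(ncol(sys0$C), 0)
  expect_equal(sys0$d, rep(0, 12))
  # zero-length line of action is rejected
  bad <- toy_muscles(list(list(o = c(0, 1, 1), i = c(0, 1, 1), N = 10)))
  expect_error(assemble_equilibrium(toy_linkage, toy_position(active = "m1"), bad),
               "zero-length")
})

test_that("single-muscle recruitment gives f = M/r and beta = M/(r N)", {
  # one moment equation: arm -10 mm, external knee moment -2000 N mm
  sol <- recruit_minmax(C = matrix(-10, 1, 1), d = -2000, strengths = 500)
  expect_equal(sol$forces, 200, tolerance = 1e-9)
  expect_equal(sol$beta, 200 / 500, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-8 * 2000)
  # a muscle cannot balance a GRF moment about a joint it does not span:
  # the single knee-spanning muscle of the planar linkage leaves the hip
  # moment unbalanced and the system is rejected as infeasible
  mus <- toy_muscles(list(list(o = c(0, 20, 10), i = c(0, -40, 10), N = 500)))
  sys <- assemble_equilibrium(toy_linkage, toy_position(active = "m1"), mus)
  expect_error(recruit_minmax(sys$C, sys$d, sys$strengths, B = sys$B),
               "infeasible")
})

test_that("two identical parallel muscles split the load equally", {
  sol <- recruit_minmax(C = matrix(c(-10, -10), 1, 2), d = -2000,
                        strengths = c(300, 300))
  # oracle: 1-D grid search over the split f1 + f2 = 200 minimising the
  # peak activation
  split <- seq(0, 200, by = 0.01)
  peak <- pmax(split / 300, (200 - split) / 300)
  expect_equal(sol$beta, min(peak), tolerance = 1e-6)
  expect_equal(sol$forces, c(100, 100), tolerance = 1e-6)
})

test_that("min/max equals the bisection + vertex-enumeration oracle", {
  # three-muscle planar case with strengths (100, 200, 400)
  C <- matrix(c(-10, 15, -25), 1, 3)
  d <- -2000
  N <- c(100, 200, 400)
  sol <- recruit_minmax(C, d, N)
  expect_equal(sol$beta, oracle_minmax_beta(C, d, N), tolerance = 1e-6)
  # randomly generated systems with <= 4 muscles and <= 3 equations
  set.seed(42)
  for (case in 1:25) {
    n <- sample(1:4, 1); m <- sample(1:min(3, n), 1)
    C <- matrix(rnorm(m * n), m, n)
    f0 <- runif(n, 0, 5)
    d <- as.numeric(C %*% f0)            # feasible by construction
    N <- runif(n, 0.5, 4)
    sol <- recruit_minmax(C, d, N)
    beta_oracle <- oracle_minmax_beta(C, d, N)
    expect_equal(sol$beta, beta_oracle, tolerance = 1e-6,
                 label = sprintf("case %d", case))
    expect_true(all(sol$forces >= -1e-12))
    expect_equal(max(sol$forces / N), sol$beta, tolerance = 1e-9)
  }
})

test_that("recruitment is homogeneous and monotone under redundancy", {
  set.seed(7)
  C <- matrix(rnorm(6), 2, 3)
  f0 <- runif(3, 0.5, 2)
  d <- as.numeric(C %*% f0)
  N <- c(1, 2, 1.5)
  sol <- recruit_minmax(C, d, N)
  # scaling d by alpha scales forces and beta by alpha (LP homogeneity)
  for (alpha in c(0.5, 3)) {
    sa <- recruit_minmax(C, alpha * d, N)
    expect_equal(sa$beta, alpha * sol$beta, tolerance = 1e-8)
    expect_equal(sa$forces, alpha * sol$forces, tolerance = 1e-6)
  }
  # duplicating a muscle never increases the optimal peak activation
  for (dup in 1:3) {
    sd_ <- recruit_minmax(cbind(C, C[, dup]), d, c(N, N[dup]))
    expect_lte(sd_$beta, sol$beta + 1e-9)
  }
})

test_that("infeasible recruitment names the unbalanced row", {
  # single muscle cannot push (f >= 0): demand the opposite-sign moment
  C <- matrix(c(-10), 1, 1)
  expect_error(recruit_minmax(C, d = 2000, strengths = 100), "infeasible")
})

test_that("hip reaction balances the external load when no muscle acts", {
  mus <- toy_muscles(list(list(o = c(0, 20, 10), i = c(0, -40, 10), N = 100)))
  # vertical GRF under the knee: reactions alone carry it
  pos <- toy_position(grf = c(0, -600, 0), cop = c(0, -50, 0), active = character(0))
  sys <- assemble_equilibrium(toy_linkage, pos, mus)
  sol <- recruit_minmax(sys$C, sys$d, sys$strengths[0], B = sys$B)
  sol$hip <- sol$reactions[1:3]
  hr <- hip_reaction(sol)
  expect_equal(hr$force, c(0, 600, 0), tolerance = 1e-9)
  expect_equal(hr$magnitude, 600, tolerance = 1e-9)
})

test_that("limb recruitment satisfies equilibrium and the activation identity", {
  an <- fixture_analysis()
  for (rec in an$recruitments) {
    sys <- rec$system
    resid <- sqrt(sum((sys$C %*% rec$forces + sys$B %*% rec$reactions - sys$d)^2))
    expect_lt(resid, 1e-8 * max(1, sqrt(sum(sys$d^2))))
    expect_true(all(rec$forces >= -1e-12))
    expect_equal(rec$beta, max(rec$forces / sys$strengths), tolerance = 1e-9)
    # definition check: hip reaction equals the residual of the muscle
    # wrench on the thigh force rows
    lhs <- sys$d[7:9] - as.numeric(sys$C[7:9, ] %*% rec$forces) -
      as.numeric(sys$B[7:9, 4:8] %*% rec$reactions[4:8])
    expect_equal(rec$hip, lhs, tolerance = 1e-6)
  }
})
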