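# Shared fixtures (built lazily, cached for the whole run) and independent
# oracles used by the property and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small capped tube with end-cap and side patches, used across FE tests
small_tube <- function(length = 100, r_out = 6, r_in = 3, element_size = 5,
                       name = "bar", origin = c(0, 0, 0), ...) {
  m <- gen_bone_mesh(c(list(name = name, length = length, r_out = r_out,
                            r_in = r_in, element_size = element_size,
                            origin = origin), list(...)))
  gen_attachment_patches(m, list(
    list(name = "base", centre = origin, half_axial = 1, half_angle = 180,
         surface = "cap"),
    list(name = "top", centre = origin + c(0, length, 0), half_axial = 1,
         half_angle = 180, surface = "cap")))
}

fixture_limb <- function() fixture("limb", function() {
  gen_lower_limb(stance_config(), seed = 1L)
})

fixture_analysis <- function() fixture("analysis", function() {
  run_stance_analysis(stance_config(), seed = 1L, limb = fixture_limb())
})

# identical RB/FE geometry: no donor mismatch
consistent_config <- function() {
  stance_config(list(geometry = list(
    donor = list(rotation_deg = 0, leg_offset = c(0, 0, 0)))))
}

fixture_analysis_consistent <- function() fixture("analysis0", function() {
  run_stance_analysis(consistent_config(), seed = 1L)
})

# ---------------------------------------------------------------------------
# independent oracles

# Min/max recruitment by bisection on beta; feasibility of
# {C f = d, 0 <= f <= beta N} decided by exhaustive vertex enumeration of the
# affine slice intersected with the box (n <= 4 variables).
oracle_minmax_beta <- function(C, d, N, beta_hi = 1e3, tol = 1e-9) {
  C <- as.matrix(C); n <- ncol(C)
  qr_ <- qr(C)
  m <- qr_$rank
  feasible <- function(beta) {
    ub <- beta * N
    free_ct <- n - m
    if (free_ct < 0) return(FALSE)
    if (free_ct == 0) {
      f <- tryCatch(qr.solve(C, d), error = function(e) NULL)
      return(!is.null(f) && all(f >= -tol) && all(f <= ub + tol) &&
               max(abs(C %*% f - d)) <= 1e-6 * max(1, max(abs(d))))
    }
    combos <- utils::combn(n, free_ct)
    for (ci in seq_len(ncol(combos))) {
      fixed_idx <- combos[, ci]
      grid <- as.matrix(expand.grid(rep(list(c(0, 1)), free_ct)))
      for (gi in seq_len(nrow(grid))) {
        f <- rep(NA_real_, n)
        f[fixed_idx] <- grid[gi, ] * ub[fixed_idx]
        rest <- setdiff(seq_len(n), fixed_idx)
        rhs <- d - C[, fixed_idx, drop = FALSE] %*% f[fixed_idx]
        sol <- tryCatch(qr.solve(C[, rest, drop = FALSE], rhs),
                        error = function(e) NULL)
        if (is.null(sol)) next
        f[rest] <- sol
        if (all(f >= -tol) && all(f <= ub + tol) &&
            max(abs(C %*% f - d)) <= 1e-6 * max(1, max(abs(d)))) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  lo <- 0; hi <- beta_hi
  if (!feasible(hi)) return(NA_real_)
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}

# element stiffness by 4-point Gauss quadrature with numerically
# differentiated shape functions (independent of the analytic path)
oracle_tet4_stiffness <- function(X, E, nu) {
  # shape functions: N(x) solves [1; x] = t([1, X]) %*% N
  A <- t(cbind(1, X))
  shape_at <- function(p) solve(A, c(1, p))
  gradN <- function(p, h = 1e-6) {
    g <- matrix(0, 3, 4)
    for (c_ in 1:3) {
      dp <- numeric(3); dp[c_] <- h
      g[c_, ] <- (shape_at(p + dp) - shape_at(p - dp)) / (2 * h)
    }
    g
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); G <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6); D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * G
  diag(D)[4:6] <- G
  a <- (5 + 3 * sqrt(5)) / 20; b <- (5 - sqrt(5)) / 20
  bary <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  V <- abs(det(cbind(1, X))) / 6
  K <- matrix(0, 12, 12)
  for (q in 1:4) {
    p <- colSums(bary[q, ] * X)
    g <- gradN(p)
    B <- matrix(0, 6, 12)
    for (i in 1:4) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- g[1, i]; B[2, c0 + 2] <- g[2, i]; B[3, c0 + 3] <- g[3, i]
      B[4, c0 + 1] <- g[2, i]; B[4, c0 + 2] <- g[1, i]
      B[5, c0 + 2] <- g[3, i]; B[5, c0 + 3] <- g[2, i]
      B[6, c0 + 1] <- g[3, i]; B[6, c0 + 3] <- g[1, i]
    }
    K <- K + (V / 4) * t(B) %*% D %*% B
  }
  K
}
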