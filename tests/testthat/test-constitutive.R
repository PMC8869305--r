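p_tab <- material_params()

test_that("invariants match direct matrix algebra", {
  k <- compute_invariants(diag(3), c(1, 0, 0))
  expect_equal(k$I1, 3)
  expect_equal(k$I4, 1)
  expect_equal(k$J, 1)

  lam <- 1.2
  k <- compute_invariants(diag(c(lam, lam^-0.5, lam^-0.5)), c(1, 0, 0))
  expect_equal(k$J, 1, tolerance = 1e-12)
  expect_equal(k$I4, lam^2, tolerance = 1e-12)
  expect_equal(k$I1, lam^2 + 2 / lam, tolerance = 1e-12)
  expect_equal(k$Ib4, k$I4)  # isochoric at J = 1

  set.seed(11)
  for (i in 1:5) {
    Q <- random_rotation()
    a0 <- stats::rnorm(3); a0 <- a0 / sqrt(sum(a0^2))
    k <- compute_invariants(Q, a0)
    expect_equal(c(k$I1, k$I4, k$J), c(3, 1, 1), tolerance = 1e-12)
  }

  expect_error(compute_invariants(diag(c(-1, 1, 1)), c(1, 0, 0)), "invalid")
  expect_error(compute_invariants(diag(3), c(1, 1, 0)), "unit")
})

test_that("damage factor reproduces the printed law with the 25% floor", {
  expect_identical(damage_factor(1.10, p_tab), 1)   # below lambda0 = 1.183
  expect_identical(damage_factor(p_tab$lambda0, p_tab), 1)
  expect_equal(damage_factor(1.35, p_tab), 0.25)    # lambdaC: clamped at floor
  expect_equal(damage_factor(2, p_tab), 0.25)

  # scalar evaluation of the exponential law, and its small-beta limit
  expect_equal(damage_factor(1.27, p_tab), oracle_G(1.27, p_tab),
               tolerance = 1e-12)
  small_beta <- (p_tab$lambdaC^4 - 1.27^4) / (p_tab$lambdaC^4 - p_tab$lambda0^4)
  expect_equal(damage_factor(1.27, p_tab), small_beta, tolerance = 1e-3)
  expect_equal(round(damage_factor(1.27, p_tab), 3), 0.528)

  # strictly decreasing between initiation and the clamp, constant after
  lm <- seq(1.19, 1.34, length.out = 40)
  g <- damage_factor(lm, p_tab)
  expect_true(all(diff(g) <= 0))
  above <- g > p_tab$gFloor
  expect_true(all(diff(g[above]) < 0))
  expect_true(all(g >= 0.25 & g <= 1))
})

test_that("damage history is a running maximum of fiber stretch", {
  expect_equal(update_damage(1.0, 1.44), 1.2)
  expect_equal(update_damage(1.3, 1.0), 1.3)
  lm <- 1
  trace <- c()
  for (Ib4 in c(1.21, 1.69, 1.0)) trace <- c(trace, lm <- update_damage(lm, Ib4))
  expect_equal(trace, c(1.1, 1.3, 1.3))
})

test_that("stress is zero at the reference and matches the spatial-form oracle", {
  s <- cauchy_stress(diag(3), c(1, 0, 0), p_tab, lambdaMax = 1.3)
  expect_equal(max(abs(s$cauchy)), 0)

  set.seed(21)
  for (i in 1:20) {
    F <- random_F()
    a0 <- stats::rnorm(3); a0 <- a0 / sqrt(sum(a0^2))
    lm <- stats::runif(1, 1, 1.4)
    got <- cauchy_stress(F, a0, p_tab, lm)$cauchy
    want <- oracle_cauchy(F, a0, p_tab, lm)
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(got, t(got), tolerance = 1e-10)
  }
})

test_that("incompressible-limit uniaxial stress matches the closed form", {
  sig <- oracle_uniaxial(1.1, p_tab)
  expect_equal(sig / 1e6, 13.6, tolerance = 0.01)  # the anchor value
  expect_equal(uniaxial_stress(1.1, p_tab, damage = FALSE), sig)
  # the nearly-incompressible material-point solve converges to it as D -> 0
  for (D in c(1e-11, 1e-13)) {
    pc <- material_params(D = D)
    expect_equal(uniaxial_stress_compressible(1.1, pc), sig,
                 tolerance = 20 * D / 1e-9 * 0.02 + 1e-5)
  }
})

test_that("damage scales the isochoric stress by G", {
  lam <- 1.1
  F <- diag(c(lam, lam^-0.5, lam^-0.5))
  und <- cauchy_stress(F, c(1, 0, 0), p_tab, lambdaMax = 1)
  dam <- cauchy_stress(F, c(1, 0, 0), p_tab, lambdaMax = 1.27)
  g <- damage_factor(1.27, p_tab)
  # J = 1: the volumetric term vanishes, so the whole stress scales by G
  expect_equal(dam$cauchy, g * und$cauchy, tolerance = 1e-12)
  expect_equal(dam$G, g)
})

test_that("material tangent matches central finite differences of the stress", {
  set.seed(31)
  for (i in 1:8) {
    F <- random_F(0.1)
    a0 <- c(1, 0, 0)
    lm <- stats::runif(1, 1, 1.3)
    A <- material_tangent(F, a0, p_tab, lm)
    expect_equal(A, t(A), tolerance = 1e-9 * max(abs(A)))  # major symmetry
    h <- 1e-6
    Afd <- matrix(0, 9, 9)
    for (j in 1:9) {
      Fp <- F; Fp[j] <- Fp[j] + h
      Fm <- F; Fm[j] <- Fm[j] - h
      Afd[, j] <- (as.vector(cauchy_stress(Fp, a0, p_tab, lm)$P) -
                     as.vector(cauchy_stress(Fm, a0, p_tab, lm)$P)) / (2 * h)
    }
    expect_lt(max(abs(A - Afd)) / max(abs(Afd)), 1e-5)
  }
})

test_that("reference-state tangent is positive definite on deviatoric modes", {
  A <- material_tangent(diag(3), c(1, 0, 0), p_tab)
  # deviatoric perturbations dF with tr(dF) = 0
  set.seed(41)
  for (i in 1:10) {
    dF <- matrix(stats::rnorm(9), 3, 3)
    diag(dF) <- diag(dF) - mean(diag(dF))
    v <- as.vector(dF)
    expect_gt(drop(v %*% A %*% v), 0)
  }
})

test_that("damaged tangent blocks scale by G at identical deformation", {
  F <- diag(c(1.08, 1.08^-0.5, 1.08^-0.5))  # J = 1: no volumetric part
  A1 <- material_tangent(F, c(1, 0, 0), p_tab, lambdaMax = 1)
  A2 <- material_tangent(F, c(1, 0, 0), p_tab, lambdaMax = 1.27)
  g <- damage_factor(1.27, p_tab)
  # volumetric contribution is zero at J = 1 except the U'' J^2 term
  pvol <- material_params(C1 = 1e-300, k1 = 0)
  expect_error(material_params(C1 = 0), "C1")
  Avol <- material_tangent(F, c(1, 0, 0), pvol)
  expect_equal(A2 - Avol, g * (A1 - Avol), tolerance = 1e-9)
})

test_that("frame indifference holds to near machine precision", {
  set.seed(51)
  for (i in 1:30) {
    F <- random_F()
    a0 <- stats::rnorm(3); a0 <- a0 / sqrt(sum(a0^2))
    Q <- random_rotation()
    s0 <- cauchy_stress(F, a0, p_tab, 1.2)$cauchy
    s1 <- cauchy_stress(Q %*% F, a0, p_tab, 1.2)$cauchy
    expect_lt(max(abs(s1 - Q %*% s0 %*% t(Q))) / max(abs(s0)), 1e-10)
  }
})

test_that("zero dispersion reduces the fiber exponent to k2 (Ib4 - 1)^2", {
  # with k = 0 the energy's exponent must equal k2 (Ib4-1)^2; compare the
  # fiber energy against that scalar form at random states
  set.seed(61)
  for (i in 1:10) {
    F <- random_F(0.1)
    kin <- compute_invariants(F, c(0, 1, 0))
    s <- cauchy_stress(F, c(0, 1, 0), p_tab, 1)
    p_iso <- p_tab; p_iso$k1 <- 0
    s_iso <- cauchy_stress(F, c(0, 1, 0), p_iso, 1)
    fib_energy <- s$energy - s_iso$energy
    want <- if (kin$Ib4 > 1)
      p_tab$k1 / (2 * p_tab$k2) * (exp(p_tab$k2 * (kin$Ib4 - 1)^2) - 1) else 0
    expect_equal(fib_energy, want, tolerance = 1e-9 * max(1, abs(want)))
  }
})

test_that("full-invariant mode carries a nonzero reference stress", {
  p_full <- material_params(isochoric = FALSE)
  s <- cauchy_stress(diag(3), c(1, 0, 0), p_full)
  # 2 C1 I from the I1 term plus 2 k1 ... a0 x a0 is absent at I4 = 1
  expect_equal(diag(s$cauchy), rep(2 * p_full$C1, 3), tolerance = 1e-9)
})

test_that("literal damage mode scales the volumetric term too", {
  p_lit <- material_params(damageVolumetric = TRUE)
  F <- diag(c(1.05, 1.05, 1.05))  # purely volumetric
  lm <- 1.27
  g <- damage_factor(lm, p_lit)
  s_lit <- cauchy_stress(F, c(1, 0, 0), p_lit, lm)$cauchy
  s_def <- cauchy_stress(F, c(1, 0, 0), material_params(), lm)$cauchy
  expect_equal(s_lit, g * s_def, tolerance = 1e-12)
})
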