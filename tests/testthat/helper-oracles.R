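# Independent oracles used across the test files. These deliberately use a
# different derivation route than the package kernels: the spatial
# (push-forward deviator) form of the stress, scalar closed forms, and
# brute-force evaluation.

# Cauchy stress via the spatial formula sigma = G * (2/J) dev[psi1 b_bar +
# psi4 m_bar (x) m_bar] + U'(J) I, for fully aligned fibers (k = 0).
oracle_cauchy <- function(F, a0, p, lambdaMax = 1) {
  J <- det(F)
  Fb <- J^(-1 / 3) * F
  bb <- Fb %*% t(Fb)
  mb <- as.numeric(Fb %*% a0)
  Ib4 <- sum(mb^2)
  G <- oracle_G(lambdaMax, p)
  psi1 <- p$C1
  psi4 <- if (Ib4 > 1) p$k1 * (Ib4 - 1) * exp(p$k2 * (Ib4 - 1)^2) else 0
  dev3 <- function(A) A - diag(mean(diag(A)), 3)
  sig_iso <- (2 / J) * dev3(psi1 * bb + psi4 * (mb %o% mb))
  pvol <- (1 / p$D) * (J - 1 / J)
  G * sig_iso + pvol * diag(3)
}

# Scalar damage law evaluated directly from its printed form, with the
# clamp applied afterwards.
oracle_G <- function(lm, p) {
  if (lm <= p$lambda0) return(1)
  raw <- (1 - exp(p$beta / 2 * (lm^4 - p$lambdaC^4))) /
    (1 - exp(p$beta / 2 * (p$lambda0^4 - p$lambdaC^4)))
  min(1, max(p$gFloor, raw))
}

# Closed-form incompressible uniaxial axial Cauchy stress (undamaged).
oracle_uniaxial <- function(lam, p) {
  2 * p$C1 * (lam^2 - 1 / lam) +
    ifelse(lam > 1,
           2 * p$k1 * (lam^2 - 1) * exp(p$k2 * (lam^2 - 1)^2) * lam^2, 0)
}

# Random deformation gradient with det > 0, bounded distortion.
random_F <- function(scale = 0.15) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, scale), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

random_rotation <- function() {
  th <- stats::rnorm(3)
  rot_mat(th / sqrt(sum(th^2)) * stats::runif(1, 0, pi))
}

# Small uniaxial bar with symmetric lateral boundary conditions; returns the
# converged solution at axial stretch `lam`.
solve_uniaxial_bar <- function(lam, params = material_params(),
                               n = c(2, 4, 2), dims = c(0.008, 0.03, 0.008)) {
  m <- bar_model(n = n, dims = dims, fiber = c(0, 1, 0), params = params,
                 damage = FALSE)
  bc <- bc_set(fixed = rbind(
    data.frame(node = bar_face(m, "x0"), dof = 1, value = 0),
    data.frame(node = bar_face(m, "z0"), dof = 3, value = 0),
    data.frame(node = bar_face(m, "y0"), dof = 2, value = 0),
    data.frame(node = bar_face(m, "y1"), dof = 2, value = lam * dims[2])),
    label = "uniaxial")
  # seed Newton with the incompressible homogeneous state so the stiff
  # volumetric term starts near J = 1 at any compressibility
  st <- fe_state(m)
  st$x <- m$nodes_ref %*% diag(c(lam^-0.5, lam, lam^-0.5))
  list(model = m, sol = solve_increment(m, bc, 1, state = st))
}
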