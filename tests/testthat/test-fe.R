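p_tab <- material_params()

test_that("homogeneous deformation patch test passes in all element modes", {
  F <- diag(c(0.96, 1.08, 0.97))
  F[1, 2] <- 0.03
  for (mode in c("mixed-up", "nodal-pressure-averaged", "displacement")) {
    m <- bar_model(n = c(1, 2, 1), dims = c(0.01, 0.02, 0.01),
                   fiber = c(0, 1, 0))
    m <- apply_element_technology(m, mode)
    bc <- bc_set(fixed = prescribe_deformation(m, seq_len(nrow(m$nodes_ref)), F))
    sol <- solve_increment(m, bc, 1)
    ref <- cauchy_stress(F, c(0, 1, 0), p_tab)$cauchy
    rv <- c(ref[1, 1], ref[2, 2], ref[3, 3], ref[1, 2], ref[2, 3], ref[1, 3])
    expect_lt(max(abs(sweep(sol$cauchy, 2, rv))) / max(abs(ref)), 1e-10)
  }
  expect_error(apply_element_technology(bar_model(), "qp-hybrid"), "arg")
})

test_that("zero load and rigid translation produce zero stress", {
  m <- bar_model(n = c(2, 4, 2))
  clamp <- bar_face(m, "y0")
  fixed <- do.call(rbind, lapply(1:3, function(d)
    data.frame(node = clamp, dof = d, value = m$nodes_ref[clamp, d])))
  sol <- solve_increment(m, bc_set(fixed = fixed), 1)
  expect_lt(max(abs(sol$x - m$nodes_ref)), 1e-12)
  expect_lt(max(abs(sol$cauchy)), 1e-6)

  shift <- c(0.002, -0.001, 0.003)
  trans <- prescribe_deformation(m, seq_len(nrow(m$nodes_ref)), diag(3))
  trans$value <- trans$value + shift[trans$dof]
  sol2 <- solve_increment(m, bc_set(fixed = trans), 1)
  expect_lt(max(abs(sol2$cauchy)), 1e-6)
})

test_that("FE uniaxial stretch matches the material-point solution", {
  ub <- solve_uniaxial_bar(1.1)
  oracle <- uniaxial_stress_compressible(1.1, p_tab)
  got <- mean(ub$sol$cauchy[, 2])
  expect_lt(abs(got - oracle) / oracle, 1e-6)
  # state is homogeneous across elements
  expect_lt(diff(range(ub$sol$cauchy[, 2])) / oracle, 1e-9)
  # near-incompressible: within about a percent of the incompressible form
  expect_lt(abs(got - oracle_uniaxial(1.1, p_tab)) / oracle, 0.02)
})

test_that("averaged-nodal-pressure tets avoid the locking of plain tets", {
  p_iso <- material_params()
  p_iso$k1 <- 0  # isotropic neo-Hookean plus volumetric term
  bend <- function(mode, n) {
    m <- bar_model(n = n, dims = c(0.01, 0.05, 0.01), fiber = c(0, 1, 0),
                   params = p_iso, damage = FALSE)
    m <- apply_element_technology(m, mode)
    clamp <- bar_face(m, "y0")
    fixed <- do.call(rbind, lapply(1:3, function(d)
      data.frame(node = clamp, dof = d, value = m$nodes_ref[clamp, d])))
    tipn <- bar_face(m, "y1")
    bc <- bc_set(fixed = fixed,
                 nodal_loads = data.frame(node = tipn, dof = 3,
                                          value = 3 / length(tipn)))
    s <- run_schedule(m, bc, nSteps = 3)[[3]]
    # the analytic near-incompressibility bound |J - 1| ~ p / kappa applies
    # to the beam field; exclude the clamped/loaded end faces where the
    # local pressure concentration legitimately exceeds it
    interior <- m$nodes_ref[, 2] > 0.1 * m$dims[2] &
      m$nodes_ref[, 2] < 0.9 * m$dims[2]
    list(tip = mean(s$x[tipn, 3] - m$nodes_ref[tipn, 3]),
         maxJdev = max(abs(s$Jbar[interior] - 1)))
  }
  mixed <- bend("mixed-up", c(2, 10, 2))
  displ <- bend("displacement", c(2, 10, 2))
  # bending is isochoric: the nodal-averaged Jacobian (the pressure-bearing
  # volumetric measure of this mixed element) must stay near one
  expect_lt(mixed$maxJdev, 1e-3)
  # negative control: the plain linear tet locks grossly (far too stiff)
  expect_lt(displ$tip, 0.5 * mixed$tip)
})

test_that("monotone load ramps are step-size independent", {
  # rate-independent law under a monotone ramp: the converged state at the
  # final load must not depend on the step count
  m <- build_knee(geometry_config(refinement = 0))
  base <- mount_state(m)
  bc <- apply_anterior_shear(m, 300)
  run <- function(n) run_schedule(m, bc, nSteps = n, state = base$state)[[n]]
  s10 <- run(10)
  s30 <- run(30)
  avg10 <- mid_substance_vm(m, s10)
  avg30 <- mid_substance_vm(m, s30)
  expect_lt(max(abs(avg10 - avg30) / avg30), 0.005)
  expect_lt(max(abs(s10$lambdaMax - s30$lambdaMax)), 0.005)
})

test_that("elastic load-unload below the damage threshold is reversible", {
  m <- build_knee(geometry_config(refinement = 0))
  base <- mount_state(m)
  bc <- apply_anterior_shear(m, 50)  # small load: no damage expected
  sols <- run_schedule(m, bc, factors = c(0.5, 1, 0.5, 1e-9),
                       state = base$state)
  fin <- sols[[4]]
  # below the damage threshold: no degradation anywhere, response elastic
  expect_true(all(fin$G == 1))
  expect_lt(max(fin$lambdaMax), material_params()$lambda0)
  expect_lt(max(abs(fin$x - base$x)), 1e-5)  # back to the mounted state
})

test_that("global force balance holds at every converged increment", {
  m <- build_knee(geometry_config(refinement = 0))
  base <- mount_state(m)
  bc <- apply_anterior_shear(m, 100)
  sols <- run_schedule(m, bc, nSteps = 4, state = base$state)
  for (s in sols) {
    # bone reactions: femoral attachments plus the net force transmitted to
    # the tibial frame (whose constrained dofs react the residual load path)
    bal <- sqrt(sum((s$reaction_total + s$frame_force_total)^2)) /
      max(sqrt(sum(s$applied_total^2)), 1)
    expect_lt(bal, 1e-8)
    expect_lt(s$residual / s$residual_ref, 1e-8)
  }
})

test_that("tie constraints transmit the applied load to the bone frames", {
  m <- build_knee(geometry_config(refinement = 0))
  base <- mount_state(m)
  bc <- apply_anterior_shear(m, 100)
  s <- run_schedule(m, bc, nSteps = 2, state = base$state)[[2]]
  # anterior reaction at the femur balances the 100 N applied shear
  expect_equal(s$reaction_total[3], -100, tolerance = 1e-6)
})

test_that("divergent increments report a diagnostic with residual history", {
  m <- bar_model(n = c(1, 2, 1))
  clamp <- bar_face(m, "y0")
  fixed <- do.call(rbind, lapply(1:3, function(d)
    data.frame(node = clamp, dof = d, value = m$nodes_ref[clamp, d])))
  huge <- data.frame(node = bar_face(m, "y1"), dof = 2, value = 1e9)
  bc <- bc_set(fixed = fixed, nodal_loads = huge, label = "overload")
  ctrl <- fe_control(maxit = 5, max_bisect = 1)
  expect_error(solve_increment(m, bc, 1, control = ctrl),
               "did not converge.*overload|overload.*did not converge")
})
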