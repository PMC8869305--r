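# Scenario-level behavior on a coarse surrogate (fast): structural
# contracts of the staged protocol. The quantitative scenario comparisons
# at the default refinement live in the acceptance tests.

coarse <- build_knee(geometry_config(refinement = 0))
proto <- function(s, shear = 100)
  load_protocol(scenario = s, shearMax = shear,
                steps = list(quad_up = 8, quad_down = 3, shear = 2, torque = 5))

test_that("load builders produce the documented force systems", {
  bc0 <- apply_quadriceps(coarse, 0)
  expect_length(bc0$frame_loads, 0)
  bcq <- apply_quadriceps(coarse, 2000, angle_deg = 25)
  Fq <- bcq$frame_loads[[1]]$force
  expect_equal(sqrt(sum(Fq^2)), 2000)
  expect_gt(Fq[3], 0)  # anterior component
  expect_gt(Fq[2], 0)  # superior component
  expect_equal(Fq[3] / sqrt(sum(Fq^2)), sin(25 * pi / 180))

  bct <- apply_tibial_torque(coarse, 10, arm = 0.05)
  f1 <- bct$frame_loads[[1]]; f2 <- bct$frame_loads[[2]]
  expect_equal(sqrt(sum(f1$force^2)), 100)  # 10 N m over 2 x 0.05 m
  expect_equal(f1$force + f2$force, c(0, 0, 0))  # zero net force
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  mom <- xp(f1$point - coarse$bones$tibia$center, f1$force) +
    xp(f2$point - coarse$bones$tibia$center, f2$force)
  expect_equal(mom, c(0, 10, 0), tolerance = 1e-12)
  expect_error(apply_tibial_torque(coarse, 10, arm = 0), "degenerate")

  bcs <- apply_anterior_shear(coarse, 300)
  expect_equal(bcs$frame_loads[[1]]$force, c(0, 0, 300))
})

und <- run_scenario(coarse, proto("undamaged"), "shear")
mod <- run_scenario(coarse, proto("moderate"), "shear")
rem <- run_scenario(coarse, proto("acl_removed"), "shear")

test_that("the undamaged scenario never develops damage", {
  # fibers carry stretch under load and pre-tension, but degradation never
  # initiates: G stays one and the ACL never reaches lambda0
  expect_true(all(und$report$G == 1))
  expect_lt(max(und$report$lambdaMax), material_params()$lambda0)
  acl <- und$model$elem_lig == "ACL"
  expect_true(all(und$report$lambdaMax[!acl] == 1))
  expect_null(und$induction)
})

test_that("quadriceps loading induces localized damage in the ACL only", {
  acl <- mod$model$elem_lig == "ACL"
  expect_gt(max(mod$induction$lambdaMax[acl]), mod$protocol$quadricepsForce * 0 + 1.183)
  expect_lt(min(mod$induction$G[acl]), 1)
  # localized: part of the ACL stays undamaged
  expect_gt(mean(mod$induction$lambdaMax[acl] <= 1.183), 0.1)
  # neighbors stay pristine (damage is modeled in the ACL alone)
  expect_true(all(mod$induction$G[!acl] == 1))
  expect_true(all(mod$report$G[!acl] == 1))
  # applied load is identically zero after unload, damage retained
  expect_equal(mod$induction$applied_total, c(0, 0, 0))
  expect_gt(max(mod$induction$lambdaMax[acl]), 1.183)
})

test_that("quadriceps loading drives the tibia anteriorly at peak", {
  bcq <- apply_quadriceps(coarse, 2000)
  base <- mount_state(coarse)
  peak <- run_schedule(coarse, bcq, nSteps = 4, state = base$state)[[4]]
  expect_gt(peak$q[3] - base$q[3], 0)
})

test_that("ACL-removed runs contain no ACL entries anywhere", {
  expect_false("ACL" %in% rem$summary$ligament)
  expect_false("ACL" %in% names(rem$model$ligs))
  expect_false(any(rem$model$elem_lig == "ACL"))
})

test_that("scenario damage extent is ordered: none, some, absent", {
  acl_und <- und$model$elem_lig == "ACL"
  expect_equal(sum(und$report$G[acl_und] < 1), 0)
  acl_mod <- mod$model$elem_lig == "ACL"
  expect_gt(sum(mod$report$G[acl_mod] < 1), 0)
  expect_equal(sum(rem$model$elem_lig == "ACL"), 0)
})

test_that("summaries are bit-identical across repeated runs", {
  again <- run_scenario(coarse, proto("undamaged"), "shear")
  expect_identical(und$summary, again$summary)
})

test_that("anterior shear reaction satisfies the global equilibrium oracle", {
  expect_equal(und$report$reaction_total[3], -100, tolerance = 1e-6)
})

test_that("per-ligament averages lie within their element value ranges", {
  for (nm in names(und$model$ligs)) {
    lg <- und$model$ligs[[nm]]
    avg <- average_over_set(und$report$vm, lg$mid_elems, und$report$V0)
    expect_gte(avg, min(und$report$vm[lg$mid_elems]))
    expect_lte(avg, max(und$report$vm[lg$mid_elems]))
  }
})

test_that("the torque mode runs and reports at 10 N m with zero net force", {
  tor <- run_scenario(coarse, load_protocol(
    scenario = "undamaged", torqueMax = 10,
    steps = list(quad_up = 8, quad_down = 3, shear = 2, torque = 5)), "torque")
  expect_equal(unique(subset(tor$summary, load == 10)$load_unit), "Nm")
  expect_equal(tor$report$applied_total, c(0, 0, 0))  # force couple
  # internal torque rotates the tibia about its long axis
  expect_gt(abs(tor$report$q[5]), 0.01)
  expect_true(all(subset(tor$summary, load == 10)$avg_vm_Pa > 0))
})
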