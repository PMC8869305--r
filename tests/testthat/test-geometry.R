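test_that("the default surrogate has the expected structure", {
  m <- build_knee(geometry_config(refinement = 0))
  expect_setequal(names(m$ligs), c("ACL", "PCL", "MCL", "LCL"))
  expect_setequal(names(m$bones), c("femur", "tibia", "fibula"))
  expect_length(m$ties, 8)
  expect_true(all(vapply(m$ties, function(t) length(t$nodes) > 0, logical(1))))
  # every ligament end node appears in exactly one tie map
  all_tied <- unlist(lapply(m$ties, `[[`, "nodes"))
  expect_equal(anyDuplicated(all_tied), 0)
  # damage capability is restricted to the ACL
  expect_true(all(m$damage_on[m$elem_lig == "ACL"]))
  expect_false(any(m$damage_on[m$elem_lig != "ACL"]))
})

test_that("refinement levels strictly increase element counts", {
  counts <- vapply(0:2, function(r)
    nrow(build_knee(geometry_config(refinement = r))$elems), numeric(1))
  expect_true(all(diff(counts) > 0))
  # halving the target edge multiplies counts roughly 8-fold (within 2x)
  c1 <- nrow(build_knee(geometry_config(edge = 0.004, refinement = 0))$elems)
  c2 <- nrow(build_knee(geometry_config(edge = 0.002, refinement = 0))$elems)
  expect_gt(c2 / c1, 8 / 2)
  expect_lt(c2 / c1, 8 * 2)
})

test_that("the generator is deterministic for a given configuration", {
  a <- build_knee(geometry_config(refinement = 0, seed = 5))
  b <- build_knee(geometry_config(refinement = 0, seed = 5))
  expect_identical(a$nodes_ref, b$nodes_ref)
  expect_identical(a$elems, b$elems)
  expect_identical(a$fibers, b$fibers)
})

test_that("meshes are positively oriented with bounded quality", {
  m <- build_knee(geometry_config(refinement = 1))
  q <- mesh_quality(m)
  expect_true(all(q$volumes > 0))
  expect_gt(q$min, 0.2)  # scaled-Jacobian floor of the structured struts
})

test_that("fiber directions connect one end of a ligament to the other", {
  m <- bar_model(n = c(2, 6, 2))
  f <- assign_fibers(m$nodes_ref, m$elems, bar_face(m, "y0"), bar_face(m, "y1"))
  expect_equal(unname(f), matrix(rep(c(0, 1, 0), nrow(m$elems)),
                                 ncol = 3, byrow = TRUE))
  # 3-4-5 normalization
  nodes <- rbind(c(0, 0, 0), c(0.03, 0.04, 0))
  el <- matrix(c(1, 2, 1, 2), 1)
  expect_equal(as.numeric(assign_fibers(nodes, el, 1, 2)), c(0.6, 0.8, 0))
  expect_error(assign_fibers(nodes, el, 1, 1), "degenerate")
  # normalization invariant on the knee
  k <- build_knee(geometry_config(refinement = 0))
  expect_lt(max(abs(sqrt(rowSums(k$fibers^2)) - 1)), 1e-12)
})

test_that("rigid rotation of a configuration rotates the fiber field with it", {
  m <- bar_model(n = c(2, 5, 2))
  Q <- rot_mat(c(0.3, -0.2, 0.9))
  f0 <- assign_fibers(m$nodes_ref, m$elems, bar_face(m, "y0"), bar_face(m, "y1"))
  fr <- assign_fibers(m$nodes_ref %*% t(Q), m$elems,
                      bar_face(m, "y0"), bar_face(m, "y1"))
  expect_equal(fr, f0 %*% t(Q), tolerance = 1e-12)
})

test_that("mid-substance band captures the central fraction by volume", {
  m <- bar_model(n = c(2, 20, 2), dims = c(0.01, 0.08, 0.01))
  q <- mesh_quality(list(nodes_ref = m$nodes_ref, elems = m$elems))
  set <- mid_substance_set(m$nodes_ref, m$elems, c(0, 1, 0), 0.2)
  frac <- sum(q$volumes[set]) / sum(q$volumes)
  expect_lt(abs(frac - 0.2), 0.05)
  # brute-force centroid classification oracle
  cent <- (m$nodes_ref[m$elems[, 1], 2] + m$nodes_ref[m$elems[, 2], 2] +
             m$nodes_ref[m$elems[, 3], 2] + m$nodes_ref[m$elems[, 4], 2]) / 4
  brute <- which(cent >= 0.04 - 0.008 & cent <= 0.04 + 0.008)
  expect_setequal(set, brute)
  # band excludes both attachment neighborhoods
  ends <- c(bar_face(m, "y0"), bar_face(m, "y1"))
  expect_false(any(m$elems[set, ] %in% ends))
  # limit case: the band approaches the whole mesh
  expect_equal(length(mid_substance_set(m$nodes_ref, m$elems, c(0, 1, 0), 0.999)),
               nrow(m$elems))
  expect_error(mid_substance_set(m$nodes_ref, m$elems, c(0, 1, 0), 1.2), "band")
})

test_that("self-intersecting configurations are rejected with the pair named", {
  lig <- default_ligaments()
  lig$PCL$tibial <- lig$ACL$tibial + c(0.001, 0, 0)
  lig$PCL$femoral <- lig$ACL$femoral + c(0.001, 0, 0)
  expect_error(build_knee(geometry_config(ligaments = lig)), "ACL.*PCL|PCL.*ACL")
})

test_that("removing the ACL leaves a consistent three-ligament model", {
  m <- build_knee(geometry_config(refinement = 0))
  r <- remove_ligament(m, "ACL")
  expect_setequal(names(r$ligs), c("PCL", "MCL", "LCL"))
  expect_length(r$ties, 6)
  expect_false(any(r$elem_lig == "ACL"))
  expect_equal(max(r$elems), nrow(r$nodes_ref))
  q <- mesh_quality(r)
  expect_true(all(q$volumes > 0))
  # fibers still unit and mid-substance sets intact
  expect_lt(max(abs(sqrt(rowSums(r$fibers^2)) - 1)), 1e-12)
  for (lg in r$ligs) expect_true(all(lg$mid_elems <= nrow(r$elems)))
})
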