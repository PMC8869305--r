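# Minimal rectangular-bar models for verification problems (patch tests,
# the uniaxial oracle, the locking benchmark). They satisfy the same model
# contract the knee surrogate does, with no rigid frame.

#' Rectangular tetrahedral bar model for verification runs
#'
#' A `[0, w] x [0, L] x [0, h]` block meshed with the same Kuhn
#' tetrahedralization as the ligament struts, one fiber direction
#' everywhere. Nodes start at their reference positions (no pre-stretch).
#'
#' @param n integer vector `c(nx, ny, nz)` of cell divisions.
#' @param dims numeric `c(w, L, h)` in meters.
#' @param fiber unit fiber direction.
#' @param params a [material_params()].
#' @param damage logical: allow damage evolution in this bar.
#' @return a model list usable with [solve_increment()] / [run_schedule()].
#' @export
bar_model <- function(n = c(2, 6, 2), dims = c(0.01, 0.04, 0.01),
                      fiber = c(0, 1, 0), params = material_params(),
                      damage = TRUE) {
  g <- strut_grid(n[1], n[2], n[3])
  nodes <- cbind(g$params[, 1] * dims[1], g$params[, 2] * dims[2],
                 g$params[, 3] * dims[3])
  el <- g$elems
  for (r in seq_len(nrow(el))) {
    v <- nodes[el[r, ], ]
    if (det(cbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) < 0)
      el[r, c(3, 4)] <- el[r, c(4, 3)]
  }
  fiber <- fiber / sqrt(sum(fiber^2))
  structure(list(
    nodes_ref = nodes, nodes_mounted = nodes, nodes_guess = nodes,
    elems = el, fibers = matrix(rep(fiber, each = nrow(el)), ncol = 3),
    elem_lig = rep("BAR", nrow(el)),
    damage_on = rep(damage, nrow(el)),
    ligs = list(), ties = list(),
    bones = list(tibia = list(center = c(0, 0, 0))),
    slave_nodes = integer(0),
    tibia_free = rep(FALSE, 6),
    params = params, element_mode = 1L, element_mode_name = "mixed-up",
    dims = dims, n = n,
    axes = "x, y, z cartesian; fiber as given"), class = "bar_model")
}

#' Node sets of a bar model by face
#'
#' @param model a [bar_model()].
#' @param face one of `"x0"`, `"x1"`, `"y0"`, `"y1"`, `"z0"`, `"z1"`.
#' @param tol coordinate tolerance (m).
#' @return integer node indices.
#' @export
bar_face <- function(model, face, tol = 1e-12) {
  ax <- match(substr(face, 1, 1), c("x", "y", "z"))
  val <- if (substr(face, 2, 2) == "0") 0 else model$dims[ax]
  which(abs(model$nodes_ref[, ax] - val) < tol + 1e-9)
}

#' Prescribe a homogeneous deformation on selected nodes
#'
#' Builds a `fixed` table mapping the listed nodes to positions `F %*% X`.
#'
#' @param model a model list.
#' @param nodes node indices.
#' @param F 3x3 deformation gradient.
#' @param dofs which coordinate components to prescribe (default all 3).
#' @return data.frame usable as `bc_set(fixed = ...)`.
#' @export
prescribe_deformation <- function(model, nodes, F, dofs = 1:3) {
  x <- model$nodes_ref[nodes, , drop = FALSE] %*% t(F)
  do.call(rbind, lapply(dofs, function(d)
    data.frame(node = nodes, dof = d, value = x[, d])))
}
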