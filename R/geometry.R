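# Parametric desk-scale knee surrogate: four ligament struts meshed with
# tetrahedra between rigid bone frames.
#
# Coordinate convention (recorded in model$axes): y = longitudinal
# (proximal +), x = medial-lateral (medial +), z = anterior (+) / posterior.
# The tibial plateau center is the origin and the tibial frame center.

#' Geometry configuration for the synthetic knee surrogate
#'
#' Attachment sites, cross-sections and in-situ pre-stretch are
#' literature-informed defaults for an adult knee near full extension
#' (lengths: ACL/PCL about 36 mm, LCL about 56 mm, MCL about 75 mm;
#' cross-sections: ACL 35 mm^2, PCL 56 mm^2, MCL 42 mm^2 broad and thin,
#' LCL 16 mm^2 cord-like; in-situ stretch: MCL 1.04, ACL and LCL 1.02,
#' PCL slack). Units: meters.
#'
#' @param ligaments named list (ACL, PCL, MCL, LCL) of
#'   `list(tibial=, femoral=, d1=, d2=, prestretch=)`: attachment-footprint
#'   centers (tibial entry is the fibular one for the LCL), cross-section
#'   extents along the local medial-lateral (`d1`) and anterior-posterior
#'   (`d2`) axes, and mounted-over-rest length ratio.
#' @param edge target element edge length (m) at refinement level 0.
#' @param refinement mesh refinement level (integer >= 0); each level
#'   shrinks the effective edge length by `1.5`.
#' @param band_fraction axial fraction of each ligament counted as
#'   mid-substance (centered band).
#' @param seed integer stored with the configuration; the generator is
#'   deterministic, the seed namespaces derived randomized studies.
#' @param tibia_free logical(6): free tibial-frame dofs
#'   (ux, uy, uz, thx, thy, thz). Default: uy fixed (longitudinal, per the
#'   loading protocol) and flexion thx fixed (the surrogate's stand-in for
#'   condylar contact); all others free.
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(ligaments = default_ligaments(),
                            edge = 0.004, refinement = 1L,
                            band_fraction = 0.2, seed = 1L,
                            tibia_free = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)) {
  stopifnot(edge > 0, refinement >= 0, band_fraction > 0, band_fraction < 1)
  for (nm in c("ACL", "PCL", "MCL", "LCL")) {
    lg <- ligaments[[nm]]
    stopifnot(!is.null(lg), lg$d1 > 0, lg$d2 > 0, lg$prestretch >= 1)
  }
  structure(list(ligaments = ligaments, edge = edge,
                 refinement = as.integer(refinement),
                 band_fraction = band_fraction, seed = as.integer(seed),
                 tibia_free = tibia_free),
            class = "geometry_config")
}

#' @rdname geometry_config
#' @export
default_ligaments <- function() {
  list(
    ACL = list(tibial = c(-0.002, 0, 0.012), femoral = c(-0.006, 0.030, -0.008),
               d1 = 0.0075, d2 = 0.006, prestretch = 1.02),
    PCL = list(tibial = c(0.002, 0, -0.014), femoral = c(0.006, 0.030, 0.006),
               d1 = 0.008, d2 = 0.007, prestretch = 1.00),
    MCL = list(tibial = c(0.035, -0.040, 0.004), femoral = c(0.035, 0.035, 0),
               d1 = 0.003, d2 = 0.014, prestretch = 1.04),
    LCL = list(tibial = c(-0.035, -0.025, -0.006), femoral = c(-0.035, 0.030, 0.004),
               d1 = 0.004, d2 = 0.004, prestretch = 1.02))
}

# Kuhn 6-tetrahedron subdivision of the unit cube: conforming across a
# structured grid when every cell uses the same main diagonal.
kuhn_tets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  corner <- function(b) 1L + b[1] + 2L * b[2] + 4L * b[3]  # binary corner id
  t(vapply(perms, function(p) {
    b <- c(0L, 0L, 0L)
    v <- integer(4)
    v[1] <- corner(b)
    for (s in 1:3) { b[p[s]] <- 1L; v[s + 1] <- corner(b) }
    v
  }, integer(4)))
}

# Structured hex grid of a strut, split into tetrahedra. Returns local
# parametric nodes (i, j, k) in [0,1]^3 and 1-based connectivity.
strut_grid <- function(n1, nax, n2) {
  nx <- n1 + 1L; ny <- nax + 1L; nz <- n2 + 1L
  idx <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  params <- cbind((g$i - 1) / n1, (g$j - 1) / nax, (g$k - 1) / n2)
  kt <- kuhn_tets()
  elems <- matrix(0L, 6L * n1 * nax * n2, 4L)
  row <- 0L
  for (k in seq_len(n2)) for (j in seq_len(nax)) for (i in seq_len(n1)) {
    corners <- c(idx(i, j, k), idx(i + 1L, j, k), idx(i, j + 1L, k), idx(i + 1L, j + 1L, k),
                 idx(i, j, k + 1L), idx(i + 1L, j, k + 1L), idx(i, j + 1L, k + 1L),
                 idx(i + 1L, j + 1L, k + 1L))
    for (t in 1:6) {
      row <- row + 1L
      elems[row, ] <- corners[kt[t, ]]
    }
  }
  list(params = params, elems = elems, nx = nx, ny = ny, nz = nz)
}

strut_mesh <- function(bottom, top, d1, d2, n1, nax, n2, prestretch) {
  axis_vec <- top - bottom
  L <- sqrt(sum(axis_vec^2))
  ey <- axis_vec / L
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * ey) * ey
  if (sqrt(sum(ex^2)) < 1e-6) ex <- c(0, 0, 1) - sum(c(0, 0, 1) * ey) * ey
  ex <- ex / sqrt(sum(ex^2))
  ez <- crossprod_vec(ex, ey)
  g <- strut_grid(n1, nax, n2)
  s1 <- (g$params[, 1] - 0.5) * d1
  sax <- g$params[, 2]
  s2 <- (g$params[, 3] - 0.5) * d2
  off <- outer(s1, ex) + outer(s2, ez)
  mounted <- sweep(outer(sax * L, ey) + off, 2, bottom, "+")
  ref <- sweep(outer(sax * L / prestretch, ey) + off, 2, bottom, "+")
  bottom_nodes <- which(g$params[, 2] == 0)
  top_nodes <- which(g$params[, 2] == 1)
  # orientation fix: swap two nodes of negatively oriented tets
  el <- g$elems
  for (r in seq_len(nrow(el))) {
    v <- ref[el[r, ], ]
    if (det(cbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) < 0)
      el[r, c(3, 4)] <- el[r, c(4, 3)]
  }
  list(ref = ref, mounted = mounted, elems = el,
       bottom_nodes = bottom_nodes, top_nodes = top_nodes,
       axis = ey, length = L)
}

#' Single end-to-end fiber direction for a ligament mesh
#'
#' Every element of a ligament is assigned the same unit fiber vector: the
#' direction from the origin-set centroid to the insertion-set centroid.
#'
#' @param nodes node coordinate matrix (reference configuration).
#' @param elems element connectivity (rows of node indices).
#' @param origin_set,insertion_set node-index vectors of the two attachment
#'   footprints.
#' @return matrix `nrow(elems) x 3` of unit fiber vectors.
#' @export
assign_fibers <- function(nodes, elems, origin_set, insertion_set) {
  stopifnot(length(origin_set) > 0, length(insertion_set) > 0)
  c0 <- colMeans(nodes[origin_set, , drop = FALSE])
  c1 <- colMeans(nodes[insertion_set, , drop = FALSE])
  d <- c1 - c0
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("degenerate geometry: coincident attachment centroids")
  matrix(rep(d / nd, each = nrow(elems)), ncol = 3)
}

#' Mid-substance element set of a ligament
#'
#' Elements whose centroids fall in the central `bandFraction` of the
#' ligament's axial extent (projection onto the fiber axis), away from both
#' attachments.
#'
#' @param nodes node coordinates.
#' @param elems connectivity rows (node indices into `nodes`).
#' @param axis unit vector of the ligament axis.
#' @param bandFraction central fraction in (0, 1); default 0.2.
#' @return integer vector of element-row indices.
#' @export
mid_substance_set <- function(nodes, elems, axis, bandFraction = 0.2) {
  stopifnot(bandFraction > 0, bandFraction < 1)
  cent <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
           nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  s <- as.numeric(cent %*% axis)
  sn <- as.numeric(nodes %*% axis)
  lo <- min(sn); hi <- max(sn)
  midv <- (lo + hi) / 2; half <- (hi - lo) * bandFraction / 2
  set <- which(s >= midv - half & s <= midv + half)
  if (!length(set)) stop("mid-substance set empty: mesh too coarse for bandFraction")
  set
}

#' Build the synthetic knee surrogate
#'
#' Generates the four ligaments as tetrahedral struts swept between their
#' attachment footprints, assigns one end-to-end fiber direction per
#' ligament, tags mid-substance element bands, and records the rigid bone
#' frames (femur fixed; fibula rigidly following the tibia) together with
#' the eight attachment tie maps. Deterministic for a given configuration.
#'
#' @param config a [geometry_config()].
#' @param params a [material_params()] object used by the solver.
#' @return list of class `knee_model`.
#' @export
#' @examples
#' m <- build_knee(geometry_config(refinement = 0))
#' names(m$ligs)
build_knee <- function(config = geometry_config(), params = material_params()) {
  lig_names <- c("ACL", "PCL", "MCL", "LCL")
  edge_eff <- config$edge / 1.5^config$refinement
  nodes_ref <- NULL; nodes_mounted <- NULL; elems <- NULL
  fibers <- NULL; elem_lig <- character(0)
  ligs <- list(); ties <- list()
  offset <- 0L
  for (nm in lig_names) {
    lg <- config$ligaments[[nm]]
    L <- sqrt(sum((lg$femoral - lg$tibial)^2))
    n1 <- max(1L, ceiling(lg$d1 / edge_eff))
    n2 <- max(1L, ceiling(lg$d2 / edge_eff))
    nax <- max(2L, ceiling(L / edge_eff))
    sm <- strut_mesh(lg$tibial, lg$femoral, lg$d1, lg$d2, n1, nax, n2,
                     lg$prestretch)
    ne_before <- if (is.null(elems)) 0L else nrow(elems)
    el <- sm$elems + offset
    fib <- assign_fibers(rbind(nodes_ref, sm$ref), el,
                         sm$bottom_nodes + offset, sm$top_nodes + offset)
    mid <- mid_substance_set(sm$ref, sm$elems, sm$axis, config$band_fraction) +
      ne_before
    ligs[[nm]] <- list(
      name = nm,
      elems = ne_before + seq_len(nrow(el)),
      nodes = offset + seq_len(nrow(sm$ref)),
      femoral_nodes = sm$top_nodes + offset,
      tibial_nodes = sm$bottom_nodes + offset,
      mid_elems = mid, axis = sm$axis, length = L,
      prestretch = lg$prestretch,
      distal_bone = if (nm == "LCL") "fibula" else "tibia")
    ties[[paste0(nm, "_femoral")]] <- list(ligament = nm, end = "femoral",
                                           nodes = sm$top_nodes + offset,
                                           bone = "femur")
    ties[[paste0(nm, "_distal")]] <- list(ligament = nm, end = "distal",
                                          nodes = sm$bottom_nodes + offset,
                                          bone = ligs[[nm]]$distal_bone)
    nodes_ref <- rbind(nodes_ref, sm$ref)
    nodes_mounted <- rbind(nodes_mounted, sm$mounted)
    elems <- rbind(elems, el)
    fibers <- rbind(fibers, fib)
    elem_lig <- c(elem_lig, rep(nm, nrow(el)))
    offset <- nrow(nodes_ref)
  }
  check_no_intersection(config)
  damage_on <- elem_lig == "ACL"  # damage modeled in the ACL only
  bones <- list(
    femur = list(kind = "rigid", fixed = TRUE, E = 20e9, nu = 0.42),
    tibia = list(kind = "rigid", fixed = FALSE, E = 20e9, nu = 0.42,
                 center = c(0, 0, 0),
                 horn_point = c(0, 0, -0.010),
                 quad_point = c(0, -0.020, 0.025),
                 distal_point = c(0, -0.080, 0)),
    fibula = list(kind = "rigid", follows = "tibia", E = 20e9, nu = 0.42))
  slave_nodes <- sort(unique(unlist(
    lapply(ties[grep("_distal$", names(ties))], `[[`, "nodes"))))
  # initial solver guess: mounted positions with the isochoric lateral
  # contraction of each pre-stretched strut applied to interior nodes
  nodes_guess <- nodes_mounted
  for (nm in lig_names) {
    lg <- ligs[[nm]]
    pre <- lg$prestretch
    if (pre > 1) {
      interior <- setdiff(lg$nodes, c(lg$femoral_nodes, lg$tibial_nodes))
      b <- config$ligaments[[nm]]$tibial
      e <- lg$axis
      v <- sweep(nodes_mounted[interior, , drop = FALSE], 2, b)
      ax <- outer(as.numeric(v %*% e), e)
      nodes_guess[interior, ] <- sweep(ax + (v - ax) / sqrt(pre), 2, b, "+")
    }
  }
  model <- structure(list(
    nodes_ref = nodes_ref, nodes_mounted = nodes_mounted,
    nodes_guess = nodes_guess,
    elems = elems, fibers = fibers, elem_lig = elem_lig,
    damage_on = damage_on, ligs = ligs, ties = ties, bones = bones,
    slave_nodes = slave_nodes,
    tibia_free = config$tibia_free,
    params = params, element_mode = 1L,
    element_mode_name = "mixed-up",
    axes = paste("x = medial-lateral (medial +), y = longitudinal",
                 "(proximal +), z = anterior (+) / posterior (-);",
                 "origin at the tibial plateau center"),
    config = config), class = "knee_model")
  model
}

# Approximate clearance check: minimum distance between strut center-line
# segments must exceed the sum of the larger cross-section half-extents.
check_no_intersection <- function(config) {
  nms <- names(config$ligaments)
  for (i in seq_along(nms)) for (j in seq_len(max(0L, i - 1L))) {
    a <- config$ligaments[[nms[i]]]; b <- config$ligaments[[nms[j]]]
    d <- segment_distance(a$tibial, a$femoral, b$tibial, b$femoral)
    clear <- max(a$d1, a$d2) / 2 + max(b$d1, b$d2) / 2
    if (d < clear)
      stop("ligament geometries intersect: ", nms[i], " and ", nms[j],
           sprintf(" (center-line clearance %.1f mm < %.1f mm)",
                   1000 * d, 1000 * clear))
  }
  invisible(TRUE)
}

segment_distance <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * cc - b * b
  s <- if (den > 1e-20) (b * e - cc * d) / den else 0
  s <- min(max(s, 0), 1)
  t <- if (cc > 1e-20) (b * s + e) / cc else 0
  t <- min(max(t, 0), 1)
  # re-clamp s for the clamped t
  s <- if (a > 1e-20) min(max((b * t - d) / a, 0), 1) else 0
  sqrt(sum((p1 + s * u - q1 - t * v)^2))
}

#' Remove a ligament from the model
#'
#' Used by the complete-tear scenario: the named ligament's elements and
#' nodes are deleted and all index maps remapped.
#'
#' @param model a `knee_model`.
#' @param name ligament name (e.g. "ACL").
#' @return the reduced `knee_model`.
#' @export
remove_ligament <- function(model, name) {
  stopifnot(name %in% names(model$ligs))
  keep_e <- model$elem_lig != name
  drop_nodes <- model$ligs[[name]]$nodes
  keep_n <- setdiff(seq_len(nrow(model$nodes_ref)), drop_nodes)
  remap <- integer(nrow(model$nodes_ref)); remap[keep_n] <- seq_along(keep_n)
  old_elem_ids <- which(keep_e)
  emap <- integer(length(keep_e)); emap[old_elem_ids] <- seq_along(old_elem_ids)
  model$nodes_ref <- model$nodes_ref[keep_n, , drop = FALSE]
  model$nodes_mounted <- model$nodes_mounted[keep_n, , drop = FALSE]
  model$nodes_guess <- model$nodes_guess[keep_n, , drop = FALSE]
  model$elems <- matrix(remap[model$elems[keep_e, ]], ncol = 4)
  model$fibers <- model$fibers[keep_e, , drop = FALSE]
  model$elem_lig <- model$elem_lig[keep_e]
  model$damage_on <- model$damage_on[keep_e]
  model$ligs[[name]] <- NULL
  model$ties <- model$ties[!grepl(paste0("^", name, "_"), names(model$ties))]
  for (nm in names(model$ligs)) {
    lg <- model$ligs[[nm]]
    lg$elems <- emap[lg$elems]
    lg$mid_elems <- emap[lg$mid_elems]
    lg$nodes <- remap[lg$nodes]
    lg$femoral_nodes <- remap[lg$femoral_nodes]
    lg$tibial_nodes <- remap[lg$tibial_nodes]
    model$ligs[[nm]] <- lg
  }
  for (nm in names(model$ties)) model$ties[[nm]]$nodes <- remap[model$ties[[nm]]$nodes]
  model$slave_nodes <- remap[setdiff(model$slave_nodes, drop_nodes)]
  model
}

#' Mesh quality summary
#'
#' Scaled Jacobian (ratio of tet volume to the volume of an ideal
#' equilateral tet with the same RMS edge length) per element, on the
#' reference mesh.
#'
#' @param model a `knee_model`.
#' @return list with `min`, `mean` scaled Jacobian and `volumes` (m^3).
#' @export
mesh_quality <- function(model) {
  X <- model$nodes_ref; el <- model$elems
  v1 <- X[el[, 2], ] - X[el[, 1], ]
  v2 <- X[el[, 3], ] - X[el[, 1], ]
  v3 <- X[el[, 4], ] - X[el[, 1], ]
  vol <- (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  e <- function(a, b) rowSums((X[el[, a], ] - X[el[, b], ])^2)
  lrms <- sqrt((e(1, 2) + e(1, 3) + e(1, 4) + e(2, 3) + e(2, 4) + e(3, 4)) / 6)
  ideal <- lrms^3 / (6 * sqrt(2))
  q <- vol / ideal
  list(min = min(q), mean = mean(q), volumes = vol)
}
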