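# Quasi-static total-Lagrangian Newton solver for the knee surrogate:
# tetrahedral ligament meshes, rigid bone frames with tie constraints,
# incremental dead loading, and staggered damage-history updates.

#' Solver controls for the nonlinear finite-element solve
#'
#' @param rtol relative residual tolerance for Newton convergence (relative
#'   to the larger of the applied-load norm and the initial residual of the
#'   increment). The tight default keeps the global force-balance invariant
#'   at the 1e-8 level.
#' @param atol absolute residual floor, N; far below any physical load in
#'   this domain, it lets load-free equilibria (an unstressed mesh) pass.
#' @param maxit maximum Newton iterations per attempt.
#' @param max_bisect maximum automatic load-step bisection depth on
#'   divergence.
#' @param damage_tol staggered damage pass stops when the largest change in
#'   the damage multiplier G falls below this.
#' @param max_damage_pass cap on staggered damage passes per increment.
#' @param max_linesearch backtracking halvings when a Newton step lands in
#'   an invalid (inverted-element) state.
#' @param step_cap largest nodal displacement increment per Newton step, m
#'   (a trust-region-style damping for far-from-equilibrium starts; steps
#'   near the solution are far below it).
#' @param rot_cap largest frame-rotation increment per Newton step, rad.
#' @return list of class `fe_control`.
#' @export
fe_control <- function(rtol = 1e-9, atol = 1e-9, maxit = 40, max_bisect = 4,
                       damage_tol = 1e-6, max_damage_pass = 25,
                       max_linesearch = 8, step_cap = 0.005, rot_cap = 0.02) {
  structure(list(rtol = rtol, atol = atol, maxit = maxit,
                 max_bisect = max_bisect, damage_tol = damage_tol,
                 max_damage_pass = max_damage_pass,
                 max_linesearch = max_linesearch, step_cap = step_cap,
                 rot_cap = rot_cap),
            class = "fe_control")
}

element_mode_code <- function(mode) {
  mode <- match.arg(mode, c("mixed-up", "nodal-pressure-averaged", "displacement"))
  # the mixed u-p tetrahedron is realized as the averaged-nodal-pressure
  # element (pressure condensed onto nodal volume averages)
  if (mode == "displacement") 0L else 1L
}

#' Select the element technology used against volumetric locking
#'
#' `"mixed-up"` (the default) and `"nodal-pressure-averaged"` both select the
#' averaged-nodal-pressure tetrahedron: the volumetric energy is evaluated at
#' volume-weighted nodal Jacobian averages, the condensed form of a mixed
#' displacement-pressure formulation with nodal pressure projection, which
#' relieves the volumetric locking of the plain linear tetrahedron.
#' `"displacement"` selects the plain (locking-prone) linear tetrahedron,
#' useful as a negative control.
#'
#' @param model a `knee_model` (or any model list used by the solver).
#' @param mode one of `"mixed-up"`, `"nodal-pressure-averaged"`,
#'   `"displacement"`.
#' @return the model with the element formulation recorded.
#' @export
apply_element_technology <- function(model, mode = "mixed-up") {
  model$element_mode <- element_mode_code(mode)
  model$element_mode_name <- mode
  model
}

#' Initial solver state for a model
#'
#' Nodes start at their mounted positions, the tibial frame at rest, and the
#' damage history at `lambdaMax = 1` everywhere.
#'
#' @param model a `knee_model`.
#' @return list of class `fe_state` with `x` (current nodal positions),
#'   `q` (frame translation + rotation vector), `lambdaMax`.
#' @export
fe_state <- function(model) {
  structure(list(x = model$nodes_guess %||% model$nodes_mounted,
                 q = numeric(6),
                 lambdaMax = rep(1, nrow(model$elems))),
            class = "fe_state")
}

#' Boundary-condition set
#'
#' @param fixed matrix/data.frame with columns `node`, `dof` (1..3), `value`
#'   (prescribed absolute coordinate), or NULL.
#' @param frame_active logical(6): which tibial-frame degrees of freedom
#'   (ux, uy, uz, thx, thy, thz) are free.
#' @param frame_loads list of dead loads attached to the tibial frame, each
#'   `list(point = <mounted coords>, force = <N, at full load>)`.
#' @param nodal_loads matrix/data.frame with columns `node`, `dof`, `value`
#'   (N at full load), or NULL.
#' @param label optional stage name used in error messages.
#' @return list of class `bc_set`.
#' @export
bc_set <- function(fixed = NULL, frame_active = rep(FALSE, 6),
                   frame_loads = list(), nodal_loads = NULL, label = "") {
  if (!is.null(fixed)) {
    fixed <- as.data.frame(fixed)
    names(fixed) <- c("node", "dof", "value")
  }
  if (!is.null(nodal_loads)) {
    nodal_loads <- as.data.frame(nodal_loads)
    names(nodal_loads) <- c("node", "dof", "value")
    if (!is.null(fixed)) {
      clash <- interaction(nodal_loads$node, nodal_loads$dof) %in%
        interaction(fixed$node, fixed$dof)
      if (any(clash))
        stop("a node dof is both prescribed and loaded: node ",
             paste(nodal_loads$node[clash], collapse = ", "))
    }
  }
  structure(list(fixed = fixed, frame_active = frame_active,
                 frame_loads = frame_loads, nodal_loads = nodal_loads,
                 label = label),
            class = "bc_set")
}

# Baseline BCs of the knee protocol: femoral attachment ends fixed in all
# directions at their mounted positions; distal ends tied to the tibial
# frame; tibia free except longitudinal translation and flexion rotation.
knee_base_bc <- function(model, label = "") {
  fem <- sort(unique(unlist(lapply(model$ligs, function(l) l$femoral_nodes))))
  fixed <- data.frame(node = rep(fem, each = 3), dof = rep(1:3, length(fem)),
                      value = as.vector(t(model$nodes_mounted[fem, , drop = FALSE])))
  bc_set(fixed = fixed, frame_active = model$tibia_free, label = label)
}

# --- internal: dof bookkeeping -------------------------------------------

# Builds the reduction map S (3N x nunk) from global nodal dofs onto the
# unknowns (free nodal dofs followed by active frame dofs), the slave
# transform T depending on the current rotation, and slave positions.
reduction_map <- function(model, bc, q) {
  N <- nrow(model$nodes_ref)
  ndof <- 3L * N
  fixed_dofs <- integer(0)
  if (!is.null(bc$fixed)) fixed_dofs <- 3L * (bc$fixed$node - 1L) + bc$fixed$dof
  slave_nodes <- model$slave_nodes
  slave_dofs <- as.vector(vapply(slave_nodes, function(n) 3L * (n - 1L) + 1:3,
                                 integer(3)))
  free_dofs <- setdiff(seq_len(ndof), c(fixed_dofs, slave_dofs))
  nfree <- length(free_dofs)
  act <- which(bc$frame_active)
  nq <- length(act)

  th <- q[4:6]
  R <- rot_mat(th)
  dR <- rot_mat_d(th)
  cen <- model$bones$tibia$center
  rs <- sweep(model$nodes_mounted[slave_nodes, , drop = FALSE], 2, cen)
  # slave positions
  xs <- sweep(rs %*% t(R), 2, cen + q[1:3], "+")

  # triplets of S
  ii <- free_dofs
  jj <- seq_len(nfree)
  vv <- rep(1, nfree)
  if (length(slave_nodes) && nq) {
    ns <- length(slave_nodes)
    # translation columns
    for (k in seq_along(act)) {
      a <- act[k]
      if (a <= 3) {
        ii <- c(ii, 3L * (slave_nodes - 1L) + a)
        jj <- c(jj, rep(nfree + k, ns))
        vv <- c(vv, rep(1, ns))
      } else {
        drs <- rs %*% t(dR[[a - 3L]])  # ns x 3: d x_s / d theta_(a-3)
        ii <- c(ii, as.vector(t(matrix(3L * (slave_nodes - 1L), ns, 3) +
                                  matrix(1:3, ns, 3, byrow = TRUE))))
        jj <- c(jj, rep(nfree + k, 3L * ns))
        vv <- c(vv, as.vector(t(drs)))
      }
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, nfree + nq))
  list(S = S, free_dofs = free_dofs, fixed_dofs = fixed_dofs,
       slave_nodes = slave_nodes, slave_pos = xs, act = act, nfree = nfree,
       R = R, dR = dR, rs = rs, cen = cen)
}

# External loads reduced onto the unknowns. Returns the full-load nodal
# force vector, the frame generalized force, and the frame load-stiffness.
external_loads <- function(model, bc, red, factor, want_K = TRUE) {
  N <- nrow(model$nodes_ref)
  fext <- numeric(3L * N)
  if (!is.null(bc$nodal_loads)) {
    d <- 3L * (bc$nodal_loads$node - 1L) + bc$nodal_loads$dof
    fext[d] <- fext[d] + factor * bc$nodal_loads$value
  }
  nq <- length(red$act)
  Q <- numeric(nq)
  KL <- matrix(0, nq, nq)
  if (length(bc$frame_loads)) {
    th_idx <- which(red$act > 3)
    d2R <- if (want_K && length(th_idx)) rot_mat_d2(attr(red, "theta")) else NULL
    for (ld in bc$frame_loads) {
      Fv <- factor * ld$force
      rp <- ld$point - red$cen
      for (k in seq_len(nq)) {
        a <- red$act[k]
        dxp <- if (a <= 3) { e <- numeric(3); e[a] <- 1; e } else drop(red$dR[[a - 3L]] %*% rp)
        Q[k] <- Q[k] + sum(dxp * Fv)
      }
      if (want_K && length(th_idx)) {
        for (k in th_idx) for (l in th_idx) {
          i <- red$act[k] - 3L; j <- red$act[l] - 3L
          KL[k, l] <- KL[k, l] + sum((d2R[, , i, j] %*% rp) * Fv)
        }
      }
    }
  }
  list(fext = fext, Q = Q, KL = KL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble reduced residual and (optionally) tangent at the current state.
assemble_reduced <- function(model, bc, state, factor, want_K = TRUE) {
  red <- reduction_map(model, bc, state$q)
  attr(red, "theta") <- state$q[4:6]
  x <- state$x
  # impose prescribed and slave positions
  if (!is.null(bc$fixed)) {
    xt <- t(x)
    xt[cbind(bc$fixed$dof, bc$fixed$node)] <- bc$fixed$value
    x <- t(xt)
  }
  if (length(red$slave_nodes)) x[red$slave_nodes, ] <- red$slave_pos

  asm <- cpp_assemble(model$nodes_ref, x, model$elems, model$fibers,
                      state$lambdaMax, model$damage_on, model$params,
                      mode = model$element_mode %||% 1L, want_K = want_K)
  if (!isTRUE(asm$ok))
    return(list(ok = FALSE, bad_elem = asm$bad_elem, x = x, red = red))

  ext <- external_loads(model, bc, red, factor, want_K = want_K)
  r_full <- asm$f - ext$fext
  r <- as.numeric(Matrix::crossprod(red$S, r_full))
  nq <- length(red$act)
  if (nq) r[red$nfree + seq_len(nq)] <- r[red$nfree + seq_len(nq)] - ext$Q

  out <- list(ok = TRUE, r = r, red = red, asm = asm, x = x,
              ext = ext, f_int = asm$f)
  if (want_K) {
    N3 <- 3L * nrow(model$nodes_ref)
    K <- Matrix::sparseMatrix(i = asm$Ki, j = asm$Kj, x = asm$Kv,
                              dims = c(N3, N3))
    if ((model$element_mode %||% 1L) == 1L && length(asm$Hi)) {
      H <- Matrix::sparseMatrix(i = asm$Hi, j = asm$Hj, x = asm$Hv,
                                dims = c(nrow(model$nodes_ref), N3))
      cU <- pmax(asm$cU, 0)
      K <- K + Matrix::crossprod(Matrix::Diagonal(x = sqrt(cU)) %*% H)
    }
    Kr <- Matrix::crossprod(red$S, K %*% red$S)
    # geometric stiffness of the rotation parametrization and of the
    # frame-attached dead loads
    if (nq) {
      th_idx <- which(red$act > 3)
      if (length(th_idx)) {
        d2R <- rot_mat_d2(state$q[4:6])
        fs <- matrix(asm$f[as.vector(t(matrix(3L * (red$slave_nodes - 1L),
                                              length(red$slave_nodes), 3) +
                                         matrix(1:3, length(red$slave_nodes), 3, byrow = TRUE)))],
                     ncol = 3, byrow = TRUE)
        Gg <- matrix(0, nq, nq)
        for (k in th_idx) for (l in th_idx) {
          i <- red$act[k] - 3L; j <- red$act[l] - 3L
          d2x <- red$rs %*% t(d2R[, , i, j])
          Gg[k, l] <- sum(d2x * fs)
        }
        idx <- red$nfree + seq_len(nq)
        Kr[idx, idx] <- Kr[idx, idx] + Gg - ext$KL
      }
    }
    out$K <- Kr
  }
  out
}

apply_increment <- function(state, red, du, bc, model) {
  nq <- length(red$act)
  nfree <- red$nfree
  x <- state$x
  xv <- as.vector(t(x))
  xv[red$free_dofs] <- xv[red$free_dofs] + du[seq_len(nfree)]
  x <- matrix(xv, ncol = 3, byrow = TRUE)
  q <- state$q
  if (nq) q[red$act] <- q[red$act] + du[nfree + seq_len(nq)]
  state$x <- x
  state$q <- q
  state
}

# Sparse solve of the Newton system: supernodal Cholesky on the symmetric
# part (the tangent is an energy Hessian up to the small frame load-
# stiffness block), falling back to sparse LU when the factorization
# reports indefiniteness (softening or far-from-equilibrium states).
solve_tangent <- function(K, b) {
  Ks <- Matrix::symmpart(K)
  try_chol <- function(A) tryCatch(
    withCallingHandlers({
      ch <- Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
      as.numeric(Matrix::solve(ch, b))
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  du <- try_chol(Ks)
  if (is.null(du)) {
    # indefinite tangent (softening / far-from-equilibrium): Levenberg-style
    # diagonal shift keeps the fast factorization and a descent-like step
    dscale <- mean(abs(Matrix::diag(Ks)))
    for (tau in c(1e-6, 1e-4, 1e-2)) {
      du <- try_chol(Ks + Matrix::Diagonal(nrow(Ks), tau * dscale))
      if (!is.null(du)) break
    }
  }
  if (is.null(du) || any(!is.finite(du)))
    du <- tryCatch(as.numeric(Matrix::solve(K, b)), error = function(e) NULL)
  du
}

newton_solve <- function(model, bc, state, factor, control) {
  sys <- assemble_reduced(model, bc, state, factor, want_K = TRUE)
  if (!sys$ok) return(list(converged = FALSE, state = state, why = "invalid deformation"))
  ref <- max(sqrt(sum(sys$ext$fext^2) + sum(sys$ext$Q^2)),
             sqrt(sum(sys$r^2)), 1e-6)
  # floor at the round-off level of the assembled internal forces (sum of
  # absolute element contributions), so prescribed-displacement problems
  # and deeply bisected steps can converge
  tol <- max(control$rtol * ref, 1e-12 * sqrt(sum(sys$asm$fabs^2)),
             control$atol)
  rnorm <- sqrt(sum(sys$r^2))
  hist <- rnorm
  for (it in seq_len(control$maxit)) {
    if (rnorm <= tol) {
      state$x <- sys$x  # prescribed/slave positions imposed
      return(list(converged = TRUE, state = state, iterations = it - 1L,
                  residual = rnorm, ref = ref, sys = sys, hist = hist))
    }
    du <- solve_tangent(sys$K, -sys$r)
    if (is.null(du) || any(!is.finite(du)))
      return(list(converged = FALSE, state = state, why = "singular tangent",
                  hist = hist))
    # cap displacement-like dofs in meters and frame rotations in radians,
    # scaling uniformly to preserve the Newton direction
    nfree <- sys$red$nfree
    rot_idx <- nfree + which(sys$red$act > 3)
    trans_idx <- setdiff(seq_along(du), rot_idx)
    sc <- 1
    if (length(trans_idx)) sc <- min(sc, control$step_cap / max(abs(du[trans_idx]), 1e-300))
    if (length(rot_idx)) sc <- min(sc, control$rot_cap / max(abs(du[rot_idx]), 1e-300))
    if (sc < 1) du <- du * sc
    # full Newton steps: the stiff volumetric term makes the residual grow
    # transiently before the quadratic phase, so no monotone line search;
    # backtrack only out of invalid (J <= 0) states, and leave genuine
    # divergence to the load-step bisection
    alpha <- 1
    best <- NULL
    for (ls in 0:control$max_linesearch) {
      cand <- apply_increment(state, sys$red, alpha * du, bc, model)
      trial <- assemble_reduced(model, bc, cand, factor, want_K = TRUE)
      if (trial$ok) {
        tn <- sqrt(sum(trial$r^2))
        if (is.finite(tn) && tn <= 1e5 * max(rnorm, tol)) {
          best <- list(cand = cand, trial = trial); break
        }
      }
      alpha <- alpha / 2
    }
    if (is.null(best))
      return(list(converged = FALSE, state = state,
                  why = "invalid deformation", hist = hist))
    state <- best$cand
    sys <- best$trial
    rnorm <- sqrt(sum(sys$r^2))
    hist <- c(hist, rnorm)
  }
  if (rnorm <= tol) {
    state$x <- sys$x
    return(list(converged = TRUE, state = state, iterations = control$maxit,
                residual = rnorm, ref = ref, sys = sys, hist = hist))
  }
  list(converged = FALSE, state = state, why = "max iterations", hist = hist,
       residual = rnorm, ref = ref)
}

#' Solve one quasi-static load increment
#'
#' Newton iteration at the given load factor, with automatic step bisection
#' on divergence and a staggered update of the damage history: the solve is
#' repeated with refreshed `lambdaMax` until the damage multiplier field is
#' stationary, so the converged state at a load level is independent of the
#' stepping that reached it (for monotone loading of this rate-independent
#' law).
#'
#' @param model a `knee_model` (see [build_knee()]) or compatible mesh model.
#' @param bc a [bc_set()].
#' @param factor load factor in `[0, 1]` scaling all loads in `bc`.
#' @param state an `fe_state` (previous converged state).
#' @param control an [fe_control()].
#' @param factor_from load factor of `state` (for bisection), default
#'   `attr(state, "factor")` or 0.
#' @return list of class `equilibrium_solution`; see [solution_fields()].
#' @export
solve_increment <- function(model, bc, factor, state = fe_state(model),
                            control = fe_control(), factor_from = NULL) {
  if (is.null(factor_from)) factor_from <- attr(state, "factor") %||% 0
  res <- solve_increment_rec(model, bc, factor_from, factor, state, control,
                             depth = 0L)
  if (!res$converged) {
    stop("increment did not converge (stage '", bc$label, "', load factor ",
         signif(factor, 4), "): ", res$why,
         "; residual history: ",
         paste(signif(utils::tail(res$hist, 6), 3), collapse = " "))
  }
  res
}

solve_increment_rec <- function(model, bc, f0, f1, state, control, depth) {
  # staggered damage fixed point at load factor f1
  st <- state
  last <- NULL
  for (pass in seq_len(control$max_damage_pass)) {
    ns <- newton_solve(model, bc, st, f1, control)
    if (!ns$converged) {
      if (depth >= control$max_bisect) return(ns)
      mid <- (f0 + f1) / 2
      half <- solve_increment_rec(model, bc, f0, mid, state, control, depth + 1L)
      if (!half$converged) return(half)
      return(solve_increment_rec(model, bc, mid, f1, half$state, control,
                                 depth + 1L))
    }
    lm_new <- update_damage(st$lambdaMax, ns$sys$asm$Ib4)
    lm_new[!model$damage_on] <- st$lambdaMax[!model$damage_on]
    gold <- cpp_damage_factor(st$lambdaMax, model$params)
    gnew <- cpp_damage_factor(lm_new, model$params)
    dG <- max(abs(gnew - gold) * as.numeric(model$damage_on))
    st <- ns$state
    st$lambdaMax <- lm_new
    last <- ns
    if (dG <= control$damage_tol) break
  }
  sol <- build_solution(model, bc, f1, st, last)
  attr(sol$state, "factor") <- f1
  sol
}

build_solution <- function(model, bc, factor, state, ns) {
  asm <- ns$sys$asm
  vm <- von_mises_voigt(asm$cauchy)
  fixed_dofs <- ns$sys$red$fixed_dofs
  reactions <- asm$f[fixed_dofs] - ns$sys$ext$fext[fixed_dofs]
  sl <- ns$sys$red$slave_nodes
  frame_force_total <- if (length(sl)) {
    sdof <- as.vector(vapply(sl, function(n) 3L * (n - 1L) + 1:3, integer(3)))
    fs <- asm$f[sdof]
    c(sum(fs[seq(1, length(fs), 3)]), sum(fs[seq(2, length(fs), 3)]),
      sum(fs[seq(3, length(fs), 3)]))
  } else c(0, 0, 0)
  applied <- ns$sys$ext$fext
  # total applied force (nodal + frame loads)
  Ftot <- c(sum(applied[seq(1, length(applied), 3)]),
            sum(applied[seq(2, length(applied), 3)]),
            sum(applied[seq(3, length(applied), 3)]))
  for (ld in bc$frame_loads) Ftot <- Ftot + factor * ld$force
  Rtot <- c(sum(reactions[(fixed_dofs - 1) %% 3 == 0]),
            sum(reactions[(fixed_dofs - 1) %% 3 == 1]),
            sum(reactions[(fixed_dofs - 1) %% 3 == 2]))
  # reactions at constrained frame dofs (slaves) and fixed nodes balance the
  # applied loads; the residual carries the free-dof imbalance
  structure(list(
    converged = ns$converged, factor = factor, state = state,
    x = state$x, q = state$q, lambdaMax = state$lambdaMax,
    cauchy = asm$cauchy, vm = vm, G = asm$G, J = asm$J, Ib4 = asm$Ib4,
    V0 = asm$V0, energy = asm$total_energy,
    residual = ns$residual, residual_ref = ns$ref,
    iterations = ns$iterations,
    Jbar = asm$Jbar %||% asm$J,
    reactions = reactions, fixed_dofs = fixed_dofs,
    frame_force_total = frame_force_total,
    applied_total = Ftot, reaction_total = Rtot,
    label = bc$label), class = "equilibrium_solution")
}

#' Fields carried by an equilibrium solution
#'
#' Documents the list layout returned by [solve_increment()] /
#' [run_schedule()]: nodal positions `x`, tibial frame coordinates `q`,
#' per-element Cauchy stress (`cauchy`, Voigt xx yy zz xy yz xz), von Mises
#' stress `vm`, damage multiplier `G`, damage history `lambdaMax`, element
#' Jacobians `J`, reference volumes `V0`, converged `residual` and its
#' normalization `residual_ref`, reactions at fixed dofs, and the load
#' `factor`.
#'
#' @return invisibly, the character vector of field names.
#' @export
solution_fields <- function() {
  invisible(c("converged", "factor", "state", "x", "q", "lambdaMax", "cauchy",
              "vm", "G", "J", "Ib4", "V0", "energy", "residual",
              "residual_ref", "iterations", "reactions", "fixed_dofs",
              "applied_total", "reaction_total", "label"))
}

#' Run a monotone load schedule (and optional unload)
#'
#' Solves the model at each requested load factor in sequence, carrying
#' displacement and damage state forward. Damage persists through any
#' unloading segment of the schedule.
#'
#' @param model a `knee_model`.
#' @param bc a [bc_set()].
#' @param nSteps number of equal steps to factor 1 (ignored when `factors`
#'   given).
#' @param factors explicit load-factor sequence (may ramp down for
#'   unloading).
#' @param state starting `fe_state`.
#' @param control an [fe_control()].
#' @return list of `equilibrium_solution`, one per requested factor.
#' @export
run_schedule <- function(model, bc, nSteps = 10, factors = NULL,
                         state = fe_state(model), control = fe_control()) {
  stopifnot(nSteps >= 1)
  if (is.null(factors)) factors <- seq_len(nSteps) / nSteps
  out <- vector("list", length(factors))
  st <- state
  f_prev <- attr(state, "factor") %||% 0
  for (i in seq_along(factors)) {
    sol <- solve_increment(model, bc, factors[i], st, control,
                           factor_from = f_prev)
    st <- sol$state
    f_prev <- factors[i]
    out[[i]] <- sol
  }
  out
}

#' Equilibrate the mounted (pre-strained) configuration
#'
#' Ligaments are generated with literature-informed in-situ pre-stretch:
#' their stress-free reference length is shorter than the mounted
#' attachment-to-attachment distance. This solve finds the self-equilibrated
#' pre-tension state under zero external load, which is the baseline of
#' every loading scenario.
#'
#' @param model a `knee_model`.
#' @param control an [fe_control()].
#' @return converged `equilibrium_solution` at zero external load.
#' @export
mount_state <- function(model, control = fe_control(),
                        stages = seq(0.25, 1, by = 0.25)) {
  bc <- knee_base_bc(model, label = "mounting")
  # mounting has no external load to scale Newton against: keep rotation
  # steps small for a stable descent to the pre-tension equilibrium
  control$rot_cap <- min(control$rot_cap, 0.005)
  # homotopy on the stress-free reference: ramp the pre-strain in stages
  # (at s = 0 the reference coincides with the mounted geometry, so every
  # stage starts near its equilibrium)
  st <- fe_state(model)
  st$x <- model$nodes_mounted +
    stages[1] * ((model$nodes_guess %||% model$nodes_mounted) -
                   model$nodes_mounted)
  sol <- NULL
  for (s in stages) {
    ms <- model
    ms$nodes_ref <- model$nodes_mounted +
      s * (model$nodes_ref - model$nodes_mounted)
    sol <- solve_increment(ms, bc, factor = 1, state = st, control = control)
    st <- sol$state
    st$lambdaMax <- rep(1, nrow(model$elems))  # no damage from mounting
    attr(st, "factor") <- 0
  }
  sol
}
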