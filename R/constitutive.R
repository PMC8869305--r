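#' Deformation invariants at a material point
#'
#' Computes the invariants of the right Cauchy-Green tensor `C = t(F) %*% F`
#' for a deformation gradient `F` and a unit reference fiber direction `a0`:
#' `I1 = tr(C)`, `I4 = a0 . C a0`, `J = det(F)`, together with their
#' isochoric counterparts `Ib1 = J^(-2/3) I1`, `Ib4 = J^(-2/3) I4`.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param a0 reference fiber direction, unit length to within 1e-12.
#' @return list with `I1`, `I4`, `J`, `Ib1`, `Ib4`, `F`, `a0` (class
#'   `kinematics`).
#' @export
#' @examples
#' compute_invariants(diag(3), c(1, 0, 0))$I1  # 3
compute_invariants <- function(F, a0) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)))
  a0 <- as.numeric(a0)
  if (abs(sqrt(sum(a0^2)) - 1) > 1e-12)
    stop("a0 must be a unit vector (|a0| = 1 within 1e-12)")
  J <- det(F)
  if (!(J > 0)) stop("invalid deformation: det(F) <= 0")
  C <- crossprod(F)
  I1 <- sum(diag(C))
  I4 <- drop(a0 %*% C %*% a0)
  s <- J^(-2 / 3)
  out <- list(F = F, a0 = a0, I1 = I1, I4 = I4, J = J,
              Ib1 = s * I1, Ib4 = s * I4)
  class(out) <- "kinematics"
  out
}

#' Cauchy stress of the damage-modified fiber-reinforced law
#'
#' Evaluates the Cauchy stress
#' \eqn{\sigma = (2/J) F (\partial W_{mod}/\partial C) F^T} at one material
#' point, with the damage multiplier `G(lambdaMax)` frozen at the supplied
#' history and applied to the isochoric terms (the volumetric term is left
#' undamaged unless `params$damageVolumetric`). Fibers carry load in tension
#' only (`Ib4 > 1`).
#'
#' @param F 3x3 deformation gradient (or a `kinematics` object).
#' @param a0 unit fiber direction (ignored if `F` is a `kinematics` object).
#' @param params a [material_params()] object.
#' @param lambdaMax maximum historical fiber stretch (damage state).
#' @return list of class `stress_result` with `cauchy` (3x3, Pa), `P`
#'   (first Piola stress), `G`, `energy` (strain-energy density, Pa), and
#'   the invariants.
#' @export
cauchy_stress <- function(F, a0 = c(1, 0, 0), params = material_params(),
                          lambdaMax = 1) {
  if (inherits(F, "kinematics")) { a0 <- F$a0; F <- F$F }
  kin <- compute_invariants(F, a0)  # validates inputs
  res <- cpp_point(kin$F, kin$a0, params, lambdaMax,
                   want_tangent = FALSE, include_vol = TRUE)
  out <- list(cauchy = res$cauchy, P = res$P, G = res$G, energy = res$energy,
              J = res$J, I1 = res$I1, I4 = res$I4, Ib1 = res$Ib1, Ib4 = res$Ib4)
  class(out) <- "stress_result"
  out
}

#' Material tangent d(P)/d(F) at a material point
#'
#' Full first-Piola tangent `A = d2 W_mod / dF dF`, consistent with
#' [cauchy_stress()] with the damage history frozen within the increment.
#' Returned as a 9x9 matrix pairing column-major `vec(P)` with `vec(F)`, so
#' it can be checked directly against finite differences of `vec(P)`.
#' Possesses major symmetry (it is an energy Hessian).
#'
#' @inheritParams cauchy_stress
#' @return 9x9 numeric matrix, Pa.
#' @export
material_tangent <- function(F, a0 = c(1, 0, 0), params = material_params(),
                             lambdaMax = 1) {
  if (inherits(F, "kinematics")) { a0 <- F$a0; F <- F$F }
  kin <- compute_invariants(F, a0)
  res <- cpp_point(kin$F, kin$a0, params, lambdaMax,
                   want_tangent = TRUE, include_vol = TRUE)
  res$A
}

#' Compressible uniaxial response of the material point
#'
#' Solves the lateral stress-free condition for uniaxial loading along the
#' fiber at the compressibility in `params` (root-find on the lateral
#' stretch), returning the axial Cauchy stress. As `D` becomes small this
#' converges to [uniaxial_stress()], the incompressible closed form.
#'
#' @param lambda axial stretch (scalar or vector).
#' @param params a [material_params()] object.
#' @param lambdaMax damage history (default: undamaged).
#' @return axial Cauchy stress, Pa.
#' @export
uniaxial_stress_compressible <- function(lambda, params = material_params(),
                                         lambdaMax = 1) {
  a0 <- c(1, 0, 0)
  one <- function(l) {
    lat_stress <- function(mu) {
      F <- diag(c(l, mu, mu))
      cauchy_stress(F, a0, params, lambdaMax)$cauchy[2, 2]
    }
    mu <- stats::uniroot(lat_stress, c(0.2, 2), tol = 1e-14)$root
    cauchy_stress(diag(c(l, mu, mu)), a0, params, lambdaMax)$cauchy[1, 1]
  }
  vapply(lambda, one, numeric(1))
}
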