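#' Constitutive and damage parameters for ligament tissue
#'
#' Bundles the constants of the fiber-reinforced Holzapfel-type strain energy
#' and of the fiber-stretch damage law into a validated parameter object.
#'
#' The strain energy is
#' \deqn{W = C_1(\bar I_1 - 3) + \frac{k_1}{2 k_2}\left(e^{k_2 E^2} - 1\right)
#'       + \frac{1}{D}\left(\frac{J^2 - 1}{2} - \ln J\right),}
#' with \eqn{E = k(\bar I_1 - 3) + (1 - 3k)(\bar I_4 - 1)} and the fiber term
#' active in tension only (\eqn{\bar I_4 > 1}). Damage scales the isochoric
#' terms by \eqn{G(\lambda_{\max}) \in [g_{floor}, 1]}, a non-increasing
#' function of the maximum historical fiber stretch (see
#' [damage_factor()]).
#'
#' @param C1 isotropic (ground-matrix) modulus, Pa.
#' @param D volumetric compliance, 1/Pa (bulk modulus is `2/D` at `J = 1`).
#' @param k1 fiber modulus, Pa.
#' @param k2 fiber stiffening exponent, dimensionless.
#' @param k fiber dispersion in `[0, 1/3]`; 0 means fully aligned fibers.
#' @param lambda0 fiber stretch at damage initiation (> 1).
#' @param lambdaC fiber stretch at complete tearing (> `lambda0`).
#' @param beta damage-rate parameter.
#' @param gFloor residual degradation fraction: `G` is clamped below at this
#'   value so damaged stiffness never drops under `gFloor` times the
#'   undamaged stiffness.
#' @param isochoric logical; use isochoric invariants in the `C1`/`k1` terms
#'   (default). `FALSE` selects the full-invariant variant, which carries a
#'   nonzero reference stress.
#' @param damageVolumetric logical; if `TRUE`, `G` also scales the volumetric
#'   term (the literal reading of the damage-modified energy). Default
#'   `FALSE`: the volumetric constraint is left undamaged.
#' @return an object of class `material_params` (a named list).
#' @export
#' @examples
#' p <- material_params()   # packaged ligament parameter set
#' p$C1
material_params <- function(C1 = 5e6, D = 1e-9, k1 = 2.06e7, k2 = 0.201,
                            k = 0, lambda0 = 1.183, lambdaC = 1.35,
                            beta = 0.00019, gFloor = 0.25,
                            isochoric = TRUE, damageVolumetric = FALSE) {
  p <- list(C1 = C1, D = D, k1 = k1, k2 = k2, k = k,
            lambda0 = lambda0, lambdaC = lambdaC, beta = beta,
            gFloor = gFloor, isochoric = isochoric,
            damageVolumetric = damageVolumetric)
  validate_material_params(p)
  class(p) <- "material_params"
  p
}

validate_material_params <- function(p) {
  stopifnot(p$C1 > 0, p$k1 >= 0, p$k2 > 0, p$D > 0,
            p$k >= 0, p$k <= 1 / 3,
            p$lambda0 > 1, p$lambdaC > p$lambda0,
            p$gFloor > 0, p$gFloor <= 1)
  invisible(p)
}

#' @export
print.material_params <- function(x, ...) {
  cat("Ligament material parameters (SI units):\n")
  cat(sprintf("  C1 = %.4g Pa, k1 = %.4g Pa, k2 = %.4g, k = %.3g, D = %.3g 1/Pa\n",
              x$C1, x$k1, x$k2, x$k, x$D))
  cat(sprintf("  damage: lambda0 = %.4g, lambdaC = %.4g, beta = %.3g, floor = %.2f\n",
              x$lambda0, x$lambdaC, x$beta, x$gFloor))
  cat(sprintf("  invariants: %s; volumetric term %s\n",
              if (x$isochoric) "isochoric" else "full",
              if (x$damageVolumetric) "damaged" else "undamaged"))
  invisible(x)
}

#' Damage multiplier as a function of maximum fiber stretch
#'
#' \deqn{G(\lambda_{\max}) =
#'   \frac{1 - e^{\beta/2\,(\lambda_{\max}^4 - \lambda_c^4)}}
#'        {1 - e^{\beta/2\,(\lambda_0^4 - \lambda_c^4)}},}
#' equal to 1 for \eqn{\lambda_{\max} \le \lambda_0} and clamped below at
#' `params$gFloor` (reached at or before \eqn{\lambda_c}). Vectorized.
#'
#' @param lambdaMax maximum historical fiber stretch(es), >= 1.
#' @param params a [material_params()] object.
#' @return numeric vector of damage multipliers in `[gFloor, 1]`.
#' @export
damage_factor <- function(lambdaMax, params = material_params()) {
  stopifnot(all(lambdaMax >= 1))
  cpp_damage_factor(as.numeric(lambdaMax), params)
}

#' Irreversible damage-history update
#'
#' The damage variable is the running maximum of the fiber stretch
#' \eqn{\lambda = \sqrt{\bar I_4}}; it never decreases.
#'
#' @param lambdaMax current maximum fiber stretch(es).
#' @param Ib4 isochoric fiber invariant(s) of the new state.
#' @return updated `lambdaMax`, elementwise `max(lambdaMax, sqrt(Ib4))`.
#' @export
update_damage <- function(lambdaMax, Ib4) {
  pmax(lambdaMax, sqrt(pmax(Ib4, 0)))
}

#' Closed-form incompressible uniaxial stress along the fiber direction
#'
#' Axial Cauchy stress for uniaxial stretch `lambda` along the fiber in the
#' incompressible limit (lateral stress-free), including damage softening
#' for a monotone loading history (`lambdaMax = lambda`):
#' \deqn{\sigma = G(\lambda)\left[2C_1(\lambda^2 - \lambda^{-1}) +
#'   2k_1(\lambda^2 - 1) e^{k_2 (\lambda^2-1)^2} \lambda^2\right]}
#' (fully aligned fibers, `k = 0`; fiber term active for `lambda > 1`).
#' Used as the calibration model and as an independent oracle for the
#' finite-element path.
#'
#' @param lambda fiber stretch(es), >= the reciprocal of feasibility but
#'   typically >= 1.
#' @param params a [material_params()] object.
#' @param damage logical; apply the damage factor for a monotone history.
#' @return axial Cauchy stress, Pa (vectorized over `lambda`).
#' @export
uniaxial_stress <- function(lambda, params = material_params(), damage = TRUE) {
  l2 <- lambda^2
  iso <- 2 * params$C1 * (l2 - 1 / lambda)
  fib <- ifelse(l2 > 1,
                2 * params$k1 * (l2 - 1) * exp(params$k2 * (l2 - 1)^2) * l2,
                0)
  g <- if (damage) damage_factor(pmax(lambda, 1), params) else 1
  g * (iso + fib)
}

#' Read / write material parameters as YAML
#'
#' The packaged default parameter set ships as
#' `system.file("extdata", "ligament_params.yaml", package = "kneedamage")`.
#'
#' @param params a [material_params()] object.
#' @param path file path.
#' @return `write_material_params`: the path, invisibly;
#'   `read_material_params`: a `material_params` object.
#' @export
write_material_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_material_params
#' @export
read_material_params <- function(path) {
  do.call(material_params, yaml::read_yaml(path))
}
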