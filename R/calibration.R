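# Calibration of the constitutive parameters to uniaxial stress-stretch
# data, with a synthetic-curve generator standing in for averaged knee
# ligament tension data.

#' Generate a synthetic uniaxial stress-stretch curve
#'
#' The noiseless curve is the closed-form incompressible uniaxial response
#' of the constitutive law along the fiber ([uniaxial_stress()]), including
#' damage softening once the stretch exceeds `lambda0` (monotone loading).
#' Optional additive Gaussian noise is reproducible for a given seed.
#'
#' @param params a [material_params()] object.
#' @param grid stretch grid, strictly increasing, within `[1, lambdaC]`.
#' @param noiseSd noise standard deviation, Pa (0 = noiseless).
#' @param seed integer RNG seed used when `noiseSd > 0`.
#' @param nominal if `TRUE`, report nominal (first Piola) stress
#'   `sigma / lambda` instead of Cauchy stress.
#' @return object of class `stress_stretch_curve`: list with `stretch`,
#'   `stress` (Pa), `noiseSd`, `seed`, `nominal`.
#' @export
generate_uniaxial_curve <- function(params = material_params(),
                                    grid = seq(1, 1.32, length.out = 25),
                                    noiseSd = 0, seed = 1L, nominal = FALSE) {
  if (any(grid < 1 - 1e-12) || any(grid > params$lambdaC + 1e-12))
    stop("stretch grid must lie within [1, lambdaC]")
  if (is.unsorted(grid, strictly = TRUE)) stop("stretch grid must be strictly increasing")
  stopifnot(noiseSd >= 0)
  stress <- uniaxial_stress(grid, params, damage = TRUE)
  if (nominal) stress <- stress / grid
  if (noiseSd > 0) {
    set.seed(seed)
    stress <- stress + stats::rnorm(length(grid), 0, noiseSd)
  }
  structure(list(stretch = grid, stress = stress, noiseSd = noiseSd,
                 seed = seed, nominal = nominal),
            class = "stress_stretch_curve")
}

#' Read / write stress-stretch curves as 2-column CSV
#'
#' Columns `stretch`, `stress_Pa` with a header row.
#'
#' @param curve a `stress_stretch_curve` (or list with `stretch`, `stress`).
#' @param path file path.
#' @param nominal flag recorded on read (the file format does not carry it).
#' @return `write_curve`: path invisibly; `read_curve`: a
#'   `stress_stretch_curve`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(stretch = curve$stretch,
                              stress_Pa = curve$stress),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path, nominal = FALSE) {
  d <- utils::read.csv(path)
  structure(list(stretch = d$stretch, stress = d$stress_Pa,
                 noiseSd = NA_real_, seed = NA_integer_, nominal = nominal),
            class = "stress_stretch_curve")
}

#' Least-squares fit of constitutive parameters to a uniaxial curve
#'
#' Bounded Levenberg-Marquardt minimization of the summed squared stress
#' residuals between the curve and the closed-form uniaxial response. By
#' default the dispersion `k` is fixed at zero (fully aligned fibers), the
#' volumetric compliance `D` is not identifiable from incompressible
#' uniaxial data and stays fixed, and the damage-rate `beta` is fixed at its
#' initial value (at small `beta` it is nearly confounded with
#' `lambda0`/`lambdaC`). The damage thresholds `lambda0`, `lambdaC` are fit
#' only when the curve samples the softening regime; otherwise they are
#' reported as unidentifiable and kept at their initial values.
#'
#' @param curve a `stress_stretch_curve` with at least 8 points.
#' @param init initial [material_params()].
#' @param lower,upper named numeric vectors of bounds for free parameters
#'   (defaults span a generous physical range).
#' @param fixed character vector of parameter names to hold at `init`.
#' @return list of class `fit_report`: `params` (fitted
#'   `material_params`), `residual_norm`, `converged`, `message`,
#'   `unidentifiable`, `values` (named vector), `fitted` (stress at the data
#'   grid), `plausible` (non-negative and non-decreasing below `lambda0`).
#' @export
fit_params <- function(curve, init = material_params(),
                       lower = NULL, upper = NULL,
                       fixed = c("k", "D", "beta")) {
  if (length(curve$stretch) < 8) stop("need at least 8 data points")
  if (all(abs(curve$stress) < .Machine$double.eps))
    stop("degenerate data: all stresses are zero")
  free <- c("C1", "k1", "k2", "lambda0", "lambdaC")
  unident <- character(0)
  if (max(curve$stretch) <= init$lambda0) {
    unident <- c("lambda0", "lambdaC")
  }
  free <- setdiff(free, union(fixed, unident))
  lo <- c(C1 = 1e3, k1 = 1e3, k2 = 1e-4, lambda0 = 1.01, lambdaC = 1.05)
  hi <- c(C1 = 1e9, k1 = 1e10, k2 = 10, lambda0 = 1.6, lambdaC = 2.0)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  p0 <- unlist(init[free])
  mk <- function(pv) {
    p <- init
    p[names(pv)] <- as.list(pv)
    if (p$lambdaC <= p$lambda0) p$lambdaC <- p$lambda0 + 1e-4
    p
  }
  resid <- function(pv) {
    p <- mk(pv)
    model <- uniaxial_stress(curve$stretch, p, damage = TRUE)
    if (isTRUE(curve$nominal)) model <- model / curve$stretch
    model - curve$stress
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            lower = lo[free], upper = hi[free],
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  pfit <- mk(fit$par)
  fitted <- uniaxial_stress(curve$stretch, pfit, damage = TRUE)
  if (isTRUE(curve$nominal)) fitted <- fitted / curve$stretch
  pre <- curve$stretch <= pfit$lambda0
  plausible <- all(fitted > -1e-9) && !is.unsorted(fitted[pre])
  structure(list(
    params = pfit,
    residual_norm = sqrt(sum(fit$fvec^2)),
    converged = fit$info %in% 1:4,
    message = fit$message,
    unidentifiable = unident,
    values = unlist(pfit[c("C1", "D", "k1", "k2", "k",
                           "lambda0", "lambdaC", "beta")]),
    fitted = fitted,
    plausible = plausible), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Uniaxial calibration fit\n")
  cat(sprintf("  converged: %s (%s)\n", x$converged, x$message))
  cat(sprintf("  residual norm: %.4g Pa\n", x$residual_norm))
  if (length(x$unidentifiable))
    cat("  unidentifiable (held at init):",
        paste(x$unidentifiable, collapse = ", "), "\n")
  print(signif(x$values, 5))
  invisible(x)
}

#' Serialize a fit report to JSON
#' @param report a `fit_report`.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_fit_report <- function(report, path) {
  jsonlite::write_json(list(
    values = as.list(report$values),
    residual_norm = report$residual_norm,
    converged = report$converged,
    message = report$message,
    unidentifiable = report$unidentifiable,
    plausible = report$plausible), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
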