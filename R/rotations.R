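# Rotation-vector utilities for the rigid bone frames.

skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

#' Rotation matrix from a rotation vector (Rodrigues form)
#' @param theta length-3 rotation vector (axis times angle, radians).
#' @return 3x3 rotation matrix.
#' @export
rot_mat <- function(theta) {
  phi <- sqrt(sum(theta^2))
  K <- skew(theta)
  if (phi < 1e-10) return(diag(3) + K + 0.5 * K %*% K)
  diag(3) + sin(phi) / phi * K + (1 - cos(phi)) / phi^2 * K %*% K
}

# dR/dtheta_i, i = 1..3 (list of 3x3), closed form with small-angle fallback.
rot_mat_d <- function(theta) {
  phi2 <- sum(theta^2)
  R <- rot_mat(theta)
  out <- vector("list", 3)
  if (phi2 < 1e-16) {
    for (i in 1:3) {
      e <- numeric(3); e[i] <- 1
      out[[i]] <- skew(e)
    }
    return(out)
  }
  for (i in 1:3) {
    e <- numeric(3); e[i] <- 1
    v <- crossprod_vec(theta, drop((diag(3) - R) %*% e))
    out[[i]] <- ((theta[i] * skew(theta) + skew(v)) / phi2) %*% R
  }
  out
}

# d2R/dtheta_i dtheta_j via central differences of the analytic first
# derivative (only enters the tangent, not the residual).
rot_mat_d2 <- function(theta, h = 1e-6) {
  out <- array(0, c(3, 3, 3, 3))
  for (j in 1:3) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    dp <- rot_mat_d(tp); dm <- rot_mat_d(tm)
    for (i in 1:3) out[, , i, j] <- (dp[[i]] - dm[[i]]) / (2 * h)
  }
  out
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
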