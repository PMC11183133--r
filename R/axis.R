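#' Estimate the vertical axis and align a recording to gravity
#'
#' Single-sensor gait pipelines need a vertical (gravity-aligned) channel but
#' the device may be mounted in any orientation. The mean acceleration vector
#' over the recording estimates the gravity direction; a proper rotation
#' (determinant +1) maps it onto the first channel. The returned recording
#' has channel 1 = vertical with gravity removed (dynamic acceleration, g)
#' and channels 2-3 spanning the horizontal plane.
#'
#' @param rec an [accel_recording] of at least 3 s.
#' @return the recording with rotated axes, plus fields `rotation` (the 3 x 3
#'   matrix applied), `gravity_g` (estimated gravity magnitude, g) and
#'   `vertical_aligned = TRUE`.
#' @details The gravity estimate requires the mean vector magnitude to be
#'   near 1 g (between 0.5 and 1.5 g); an all-zero or zero-mean signal has no
#'   recoverable vertical and raises an error.
#' @export
estimate_vertical_axis <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  if (duration_s(rec) < 3) stop("recording must be at least 3 s long")
  if (isTRUE(rec$vertical_aligned)) return(rec)
  g_vec <- colMeans(rec$accel)
  g_mag <- sqrt(sum(g_vec^2))
  if (g_mag < 1e-9) stop("all-zero signal: cannot estimate vertical axis")
  if (g_mag < 0.5 || g_mag > 1.5)
    stop(sprintf(paste0("mean acceleration magnitude %.3f g is implausible ",
                        "for a gravity estimate (expect ~1 g)"), g_mag))
  u <- g_vec / g_mag
  e1 <- c(1, 0, 0)
  cosang <- sum(u * e1)
  if (cosang > 1 - 1e-12) {
    rot <- diag(3)
  } else if (cosang < -1 + 1e-12) {
    rot <- diag(c(-1, -1, 1))  # 180 deg about channel 3; proper
  } else {
    axis <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
    rot <- rotation_matrix(axis, acos(cosang))  # maps u onto e1
  }
  acc <- rec$accel %*% t(rot)
  acc[, 1] <- acc[, 1] - g_mag
  colnames(acc) <- c("v_g", "h1_g", "h2_g")
  out <- rec
  out$accel <- acc
  out$rotation <- rot
  out$gravity_g <- g_mag
  out$vertical_aligned <- TRUE
  out
}
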