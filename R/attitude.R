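# Quaternion attitude solution: accelerometer-referenced complementary
# filter (Mahony family). Quaternions are scalar-first, Hamilton
# convention; frame is right-handed with Z up at rest, so the body-frame
# gravity direction at the identity orientation is (0, 0, 1).

#' Normalize an accelerometer reading to a unit vector
#'
#' The Euclidean norm is computed once from the raw components before any
#' component is used, then all three are divided by it.
#'
#' @param a Numeric acceleration triple.
#' @return Unit-norm triple pointing along `a`.
#' @export
#' @examples
#' normalize_accel(c(3, 0, 4))
normalize_accel <- function(a) {
  if (length(a) != 3 || !all(is.finite(a))) {
    stop_validation("acceleration must be a finite triple")
  }
  n <- sqrt(a[1]^2 + a[2]^2 + a[3]^2)
  if (n == 0) stop_degenerate("zero-norm accelerometer sample cannot be normalized")
  a / n
}

#' Body-frame gravity direction implied by a quaternion
#'
#' For a unit quaternion `q = (q0, q1, q2, q3)` the estimated gravity
#' direction in body coordinates is
#' `V = (2(q1 q3 - q0 q2), 2(q0 q1 + q2 q3), q0^2 - q1^2 - q2^2 + q3^2)`;
#' the identity orientation gives (0, 0, 1).
#'
#' @param q Unit quaternion, scalar first.
#' @return Unit-norm gravity triple.
#' @export
#' @examples
#' gravity_from_quaternion(c(1, 0, 0, 0))
gravity_from_quaternion <- function(q) {
  c(2 * (q[2] * q[4] - q[1] * q[3]),
    2 * (q[1] * q[2] + q[3] * q[4]),
    q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2)
}

#' Attitude error vector
#'
#' Cross product of the measured gravity direction (normalized
#' accelerometer) with the gravity direction implied by the integrated
#' attitude. Zero iff the two directions are parallel; its magnitude is
#' proportional to the gyro integration error and drives the PI correction.
#'
#' @param a_hat Unit accelerometer direction.
#' @param v Unit gravity direction from the quaternion.
#' @return Error triple `a_hat x v`.
#' @export
error_vector <- function(a_hat, v) {
  c(a_hat[2] * v[3] - a_hat[3] * v[2],
    a_hat[3] * v[1] - a_hat[1] * v[3],
    a_hat[1] * v[2] - a_hat[2] * v[1])
}

#' Complementary-filter gains
#'
#' @param kp Proportional gain pulling the attitude toward the
#'   accelerometer's gravity direction (dimensionless, `>= 0`).
#' @param ki Integral gain absorbing slow gyroscope bias (dimensionless,
#'   `>= 0`).
#' @param half_t Half the sampling period, in seconds. `NULL` defers to the
#'   stream's `dt/2` when filtering a stream.
#' @return A `fusion_gains` list.
#' @export
fusion_gains <- function(kp = 2.0, ki = 0.005, half_t = NULL) {
  if (kp < 0 || ki < 0) stop_validation("gains kp and ki must be non-negative")
  if (!is.null(half_t) && (!is.finite(half_t) || half_t <= 0)) {
    stop_validation("half_t must be positive")
  }
  structure(list(kp = kp, ki = ki, half_t = half_t), class = "fusion_gains")
}

#' Attitude-filter state
#'
#' Bundles the current orientation quaternion, the accumulated integral
#' error, and the gains.
#'
#' @param q Initial unit quaternion (scalar first); default identity.
#' @param e_int Initial integral-error triple; default zero.
#' @param gains A [fusion_gains()] object with a concrete `half_t`.
#' @return A `fusion_state` list.
#' @export
fusion_state <- function(q = c(1, 0, 0, 0), e_int = c(0, 0, 0),
                         gains = fusion_gains(half_t = 0.1)) {
  if (length(q) != 4 || !all(is.finite(q))) stop_validation("q must be a finite quadruple")
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop_validation("q must be non-zero")
  if (!all(is.finite(e_int)) || length(e_int) != 3) {
    stop_validation("e_int must be a finite triple")
  }
  if (is.null(gains$half_t)) stop_validation("gains must carry a concrete half_t")
  structure(list(q = q / nq, e_int = e_int, gains = gains),
            class = "fusion_state")
}

#' One fusion step of the attitude solver
#'
#' Advances the attitude by one sample: (i) if the accelerometer reading
#' has non-zero norm, it is normalized, the gravity direction implied by
#' the current quaternion is computed, their cross product forms the error,
#' the integral error accumulates `e * ki`, and the gyro rates are corrected
#' to `g = w + kp * e + e_int`; a zero-norm reading (free fall) skips the
#' correction and integrates the gyro alone; (ii) the quaternion is advanced
#' by the first-order update `q <- q + (q x g) * half_t`, component-wise
#' scalar-first; (iii) the quaternion is re-normalized to unit norm.
#'
#' @param state A [fusion_state()].
#' @param accel Acceleration triple, raw sensor units (only the direction
#'   is used).
#' @param gyro Angular-rate triple, rad/s.
#' @return The advanced `fusion_state`.
#' @export
fuse_step <- function(state, accel, gyro) {
  if (length(accel) != 3 || length(gyro) != 3 ||
      !all(is.finite(accel)) || !all(is.finite(gyro))) {
    stop_validation("accel and gyro must be finite triples")
  }
  q <- state$q
  e_int <- state$e_int
  kp <- state$gains$kp
  ki <- state$gains$ki
  half_t <- state$gains$half_t

  g <- gyro
  an <- sqrt(accel[1]^2 + accel[2]^2 + accel[3]^2)
  if (an > 0) {
    a_hat <- accel / an
    v <- gravity_from_quaternion(q)
    e <- error_vector(a_hat, v)
    e_int <- e_int + e * ki
    g <- gyro + kp * e + e_int
  }

  nq <- c(q[1] + (-q[2] * g[1] - q[3] * g[2] - q[4] * g[3]) * half_t,
          q[2] + ( q[1] * g[1] + q[3] * g[3] - q[4] * g[2]) * half_t,
          q[3] + ( q[1] * g[2] - q[2] * g[3] + q[4] * g[1]) * half_t,
          q[4] + ( q[1] * g[3] + q[2] * g[2] - q[3] * g[1]) * half_t)
  state$q <- nq / sqrt(sum(nq^2))
  state$e_int <- e_int
  state
}

#' Euler angles from a quaternion
#'
#' Yaw rotates about Z, pitch about Y, roll about X (intrinsic Z-Y-X
#' order). Yaw and roll use the two-argument arctangent so the full
#' `(-pi, pi]` range is recovered; the pitch arcsine argument is clamped to
#' `[-1, 1]` against floating-point overshoot near the gimbal poles.
#'
#' @param q Unit quaternion, scalar first.
#' @return Named numeric `c(yaw, pitch, roll)` in radians.
#' @export
#' @examples
#' euler_from_quaternion(c(sqrt(2) / 2, 0, 0, sqrt(2) / 2))  # yaw = pi/2
euler_from_quaternion <- function(q) {
  yaw <- atan2(2 * (q[1] * q[4] + q[2] * q[3]),
               q[1]^2 + q[2]^2 - q[3]^2 - q[4]^2)
  s <- 2 * (q[1] * q[3] - q[2] * q[4])
  pitch <- asin(min(1, max(-1, s)))
  roll <- atan2(2 * (q[1] * q[2] + q[3] * q[4]),
                q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2)
  c(yaw = yaw, pitch = pitch, roll = roll)
}

#' Quaternion from Euler angles
#'
#' Inverse of [euler_from_quaternion()] (intrinsic Z-Y-X: yaw about Z,
#' then pitch about Y, then roll about X).
#'
#' @param yaw,pitch,roll Angles in radians.
#' @return Unit quaternion, scalar first.
#' @export
quaternion_from_euler <- function(yaw, pitch, roll) {
  cy <- cos(yaw / 2);   sy <- sin(yaw / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cr <- cos(roll / 2);  sr <- sin(roll / 2)
  c(cy * cp * cr + sy * sp * sr,
    cy * cp * sr - sy * sp * cr,
    cy * sp * cr + sy * cp * sr,
    sy * cp * cr - cy * sp * sr)
}

#' Run the attitude solver over a single-site stream
#'
#' @param stream An [imu_stream()] containing exactly one site (or pass
#'   `site` to select one).
#' @param gains A [fusion_gains()]; a `NULL` `half_t` is resolved to half
#'   the stream's sampling interval.
#' @param q0 Initial quaternion (default identity).
#' @param site Optional site to filter on.
#' @return Data frame with columns `t`, `q0..q3`, `yaw`, `pitch`, `roll`
#'   (one row per sample, the state after absorbing that sample).
#' @export
fuse_stream <- function(stream, gains = fusion_gains(), q0 = c(1, 0, 0, 0),
                        site = NULL) {
  df <- as.data.frame(stream)
  if (!is.null(site)) df <- df[df$site == site, , drop = FALSE]
  if (nrow(df) == 0) stop_validation("no samples to fuse")
  if (length(unique(df$site)) != 1) {
    stop_validation("fuse_stream expects a single site; pass `site = `")
  }
  if (is.null(gains$half_t)) gains$half_t <- stream_dt(stream) / 2
  st <- fusion_state(q = q0, gains = gains)
  n <- nrow(df)
  qs <- matrix(NA_real_, n, 4)
  eul <- matrix(NA_real_, n, 3)
  ax <- df$ax; ay <- df$ay; az <- df$az
  gx <- df$gx; gy <- df$gy; gz <- df$gz
  for (k in seq_len(n)) {
    st <- fuse_step(st, c(ax[k], ay[k], az[k]), c(gx[k], gy[k], gz[k]))
    qs[k, ] <- st$q
    eul[k, ] <- euler_from_quaternion(st$q)
  }
  data.frame(t = df$t, q0 = qs[, 1], q1 = qs[, 2], q2 = qs[, 3], q3 = qs[, 4],
             yaw = eul[, 1], pitch = eul[, 2], roll = eul[, 3])
}
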