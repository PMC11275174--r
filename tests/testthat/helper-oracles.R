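# Independent oracles, kept deliberately separate from the package's own
# computation paths.

# rotation matrices about single axes
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# body-to-world rotation for intrinsic Z-Y-X Euler angles
rot_from_euler <- function(yaw, pitch, roll) rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)

# Shepperd's method: scalar-first unit quaternion from a rotation matrix
quat_from_rotmat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    k <- which.max(diag(R))
    i <- k; j <- i %% 3 + 1; l <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[l, l] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[l, j] - R[j, l]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[l + 1] <- (R[l, i] + R[i, l]) / s
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# Euler -> quaternion oracle, independent of quaternion_from_euler()
quat_from_euler_oracle <- function(yaw, pitch, roll) {
  quat_from_rotmat(rot_from_euler(yaw, pitch, roll))
}

# body-frame gravity oracle: world (0,0,1) pulled into the body frame
gravity_oracle <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  R <- matrix(c(
    1 - 2 * (q2^2 + q3^2), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1^2 + q3^2), 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1^2 + q2^2)),
    3, 3, byrow = TRUE)
  as.numeric(t(R) %*% c(0, 0, 1))
}

# Hamilton product via the 4x4 matrix form (independent arithmetic)
qmul_oracle <- function(a, b) {
  M <- matrix(c(
    a[1], -a[2], -a[3], -a[4],
    a[2],  a[1], -a[4],  a[3],
    a[3],  a[4],  a[1], -a[2],
    a[4], -a[3],  a[2],  a[1]), 4, 4, byrow = TRUE)
  as.numeric(M %*% b)
}

# exact gyro integration step: q <- q (x) exp(w * dt / 2)
exact_gyro_step <- function(q, w, dt) {
  th <- sqrt(sum(w^2)) * dt
  if (th == 0) return(q)
  axis <- w / sqrt(sum(w^2))
  dq <- c(cos(th / 2), sin(th / 2) * axis)
  out <- qmul_oracle(q, dq)
  out / sqrt(sum(out^2))
}

# brute-force window classifier: plain double loop over sites and samples
brute_force_classify <- function(window_df, cfg) {
  i <- 0L
  for (s in wearmotion::body_sites()) {
    rows <- window_df[window_df$site == s, , drop = FALSE]
    hit <- FALSE
    for (k in seq_len(nrow(rows))) {
      if (abs(rows$ax[k]) > cfg$a || abs(rows$ay[k]) > cfg$a ||
          abs(rows$az[k]) > cfg$a) hit <- TRUE
    }
    if (hit) i <- i + 1L
  }
  lab <- if (i >= cfg$i3) "jump" else if (i >= cfg$i1 && i <= cfg$i2) "walk" else "stand"
  list(i = i, label = lab)
}

# scalar steady-state Riccati fixed point for A = H = 1
riccati_fixed_point <- function(q, r) {
  p_post <- (-q + sqrt(q^2 + 4 * q * r)) / 2
  p_pre <- p_post + q
  list(p_post = p_post, gain = p_pre / (p_pre + r))
}

angle_between <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

make_stream_df <- function(n_ticks = 3, dt = 0.2, sites = wearmotion::body_sites(),
                           mag = 100) {
  df <- expand.grid(site = sites, k = seq_len(n_ticks) - 1,
                    stringsAsFactors = FALSE)
  data.frame(site = df$site, t = df$k * dt,
             ax = mag, ay = -mag / 2, az = mag / 3,
             gx = 0.1, gy = -0.2, gz = 0.3)
}
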