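test_that("accelerometer normalization preserves direction and unit norm", {
  expect_equal(normalize_accel(c(3, 0, 4)), c(0.6, 0, 0.8), tolerance = 1e-12)
  expect_equal(normalize_accel(c(0, 0, 1)), c(0, 0, 1))
  expect_error(normalize_accel(c(0, 0, 0)), class = "wearmotion_degenerate_error")
  set.seed(42)
  for (k in 1:20) {
    a <- rnorm(3) * 10^sample(-3:4, 1)
    if (sqrt(sum(a^2)) == 0) next
    u <- normalize_accel(a)
    expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-9)
    expect_equal(u * sqrt(sum(a^2)), a, tolerance = 1e-9)
  }
})

test_that("quaternion-implied gravity matches closed forms and the rotation-matrix oracle", {
  expect_equal(gravity_from_quaternion(c(1, 0, 0, 0)), c(0, 0, 1))
  expect_equal(gravity_from_quaternion(c(0, 1, 0, 0)), c(0, 0, -1))
  expect_equal(gravity_from_quaternion(c(sqrt(2) / 2, 0, sqrt(2) / 2, 0)),
               c(-1, 0, 0), tolerance = 1e-12)
  set.seed(7)
  for (k in 1:50) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    v <- gravity_from_quaternion(q)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
    expect_equal(v, gravity_oracle(q), tolerance = 1e-12)
  }
})

test_that("error vector is the cross product of measured and estimated gravity", {
  expect_equal(error_vector(c(0, 0, 1), c(0, 0, 1)), c(0, 0, 0))
  expect_equal(error_vector(c(0, 0, 1), c(1, 0, 0)), c(0, 1, 0))
  skip_if_not_installed("pracma")
  set.seed(13)
  for (k in 1:50) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    expect_equal(error_vector(a, v), as.numeric(pracma::cross(a, v)),
                 tolerance = 1e-12)
  }
})

test_that("a fusion step at the aligned fixed point leaves the state unchanged", {
  st <- fusion_state(gains = fusion_gains(kp = 2, ki = 0.005, half_t = 0.1))
  st2 <- fuse_step(st, accel = c(0, 0, 9.8), gyro = c(0, 0, 0))
  expect_equal(st2$q, c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(st2$e_int, c(0, 0, 0))
})

test_that("with zero gains a step is the first-order quaternion update", {
  h <- 0.05; w <- 0.3
  st <- fusion_state(gains = fusion_gains(kp = 0, ki = 0, half_t = h))
  st2 <- fuse_step(st, accel = c(0, 0, 0), gyro = c(0, 0, w))
  raw <- c(1, 0, 0, w * h)  # direct substitution before normalization
  expect_equal(st2$q, raw / sqrt(sum(raw^2)), tolerance = 1e-12)

  expect_error(fuse_step(st, accel = c(0, 0, NA), gyro = c(0, 0, 0)),
               class = "wearmotion_validation_error")
})

test_that("gyro-only filtering tracks exact quaternion integration to O(dt^2)", {
  dt <- 1e-3; n <- 200
  w <- c(0.4, -0.7, 1.1)
  st <- fusion_state(gains = fusion_gains(kp = 0, ki = 0, half_t = dt / 2))
  q_exact <- c(1, 0, 0, 0)
  for (k in seq_len(n)) {
    st <- fuse_step(st, accel = c(0, 0, 0), gyro = w)
    q_exact <- exact_gyro_step(q_exact, w, dt)
  }
  # per-step first-order error ~ (|w| dt / 2)^2, accumulated over n steps
  bound <- n * (sqrt(sum(w^2)) * dt)^2
  expect_lt(max(abs(st$q - q_exact)), bound)
})

test_that("static input makes the gravity-direction error non-increasing", {
  q_true <- quaternion_from_euler(0, 0.4, -0.6)
  a_body <- gravity_from_quaternion(q_true) * 2000  # magnitude is irrelevant
  st <- fusion_state(gains = fusion_gains(kp = 2, ki = 0, half_t = 0.1))
  angles <- numeric(60)
  for (k in 1:60) {
    st <- fuse_step(st, accel = a_body, gyro = c(0, 0, 0))
    angles[k] <- angle_between(gravity_from_quaternion(st$q), a_body)
  }
  # non-increasing up to the acos() noise floor once fully converged
  expect_true(all(diff(angles[10:60]) <= 1e-7))
  expect_lt(angles[60], angles[10])
  expect_lt(angles[60], 1e-6)
})

test_that("quaternion norm is preserved across many fusion steps", {
  set.seed(21)
  st <- fusion_state(gains = fusion_gains(kp = 2, ki = 0.005, half_t = 0.1))
  worst <- 0
  for (k in 1:2000) {
    st <- fuse_step(st, accel = rnorm(3, sd = 100), gyro = rnorm(3, sd = 0.5))
    worst <- max(worst, abs(sum(st$q^2) - 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("Euler extraction matches closed forms and round-trips through the matrix oracle", {
  expect_equal(euler_from_quaternion(c(1, 0, 0, 0)),
               c(yaw = 0, pitch = 0, roll = 0))
  expect_equal(euler_from_quaternion(c(sqrt(2) / 2, 0, 0, sqrt(2) / 2)),
               c(yaw = pi / 2, pitch = 0, roll = 0), tolerance = 1e-12)
  set.seed(31)
  for (k in 1:100) {
    y <- runif(1, -pi + 0.01, pi - 0.01)
    p <- runif(1, -80, 80) * pi / 180  # away from gimbal lock
    r <- runif(1, -pi + 0.01, pi - 0.01)
    q <- quat_from_euler_oracle(y, p, r)
    e <- euler_from_quaternion(q)
    expect_equal(as.numeric(e), c(y, p, r), tolerance = 1e-9)
    # the package's own constructor agrees with the oracle up to sign
    qp <- quaternion_from_euler(y, p, r)
    if (qp[1] < 0) qp <- -qp
    expect_equal(qp, q, tolerance = 1e-9)
  }
  # pitch argument clamped at the poles instead of producing NaN
  q_pole <- quaternion_from_euler(0, pi / 2, 0)
  expect_equal(unname(euler_from_quaternion(q_pole)["pitch"]), pi / 2,
               tolerance = 1e-6)
})

test_that("a static 30-degree tilt is recovered within one degree", {
  traj <- generate_imu_trajectory(roll = pi / 6, duration = 200 * 0.2, dt = 0.2,
                                  gyro_noise_sd = 0.002, accel_mag = 2000,
                                  accel_noise_sd = 5, seed = 3)
  est <- fuse_stream(traj$stream, fusion_gains(kp = 2, ki = 0.005))
  expect_lt(abs(est$roll[nrow(est)] * 180 / pi - 30), 1)
})
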