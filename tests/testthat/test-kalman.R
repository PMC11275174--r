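test_that("predict and update match hand-evaluated scalar cases", {
  m <- kalman_model(A = 1, H = 1, Q = 0, R = 1)
  st <- kalman_state(5, 2)
  pr <- kf_predict(st, m)
  expect_equal(pr$x, 5)
  expect_equal(pr$P[1, 1], 2)

  m2 <- kalman_model(A = 1, H = 1, Q = 0.1, R = 1)
  pr2 <- kf_predict(kalman_state(0, 1), m2)
  expect_equal(pr2$P[1, 1], 1.1)

  # unit scalar update: K = 0.5, x = 0.5, P = 0.5
  up <- kf_update(kalman_state(0, 1), m, z = 1)
  expect_equal(up$x, 0.5)
  expect_equal(up$P[1, 1], 0.5)

  # huge R: the measurement is ignored
  mR <- kalman_model(A = 1, H = 1, Q = 0, R = 1e12)
  expect_equal(kf_update(kalman_state(0, 1), mR, z = 1)$x, 0, tolerance = 1e-9)
  # tiny R: the estimate snaps to the measurement
  mr <- kalman_model(A = 1, H = 1, Q = 0, R = 1e-12)
  expect_equal(kf_update(kalman_state(0, 1), mr, z = 1)$x, 1, tolerance = 1e-9)
})

test_that("matrix predict/update agree with direct matrix arithmetic", {
  set.seed(5)
  for (k in 1:20) {
    A <- matrix(rnorm(4), 2, 2)
    H <- matrix(rnorm(4), 2, 2)
    B <- matrix(rnorm(2), 2, 1)
    Qm <- crossprod(matrix(rnorm(4), 2, 2)) + diag(2) * 0.1
    Rm <- crossprod(matrix(rnorm(4), 2, 2)) + diag(2) * 0.1
    P <- crossprod(matrix(rnorm(4), 2, 2)) + diag(2) * 0.1
    x <- rnorm(2); u <- rnorm(1); z <- rnorm(2)
    m <- kalman_model(A = A, H = H, Q = Qm, R = Rm, B = B)
    pr <- kf_predict(kalman_state(x, P), m, u = u)
    expect_equal(pr$x, as.numeric(A %*% x + B %*% u), tolerance = 1e-12)
    expect_equal(pr$P, (A %*% P %*% t(A) + Qm + t(A %*% P %*% t(A) + Qm)) / 2,
                 tolerance = 1e-12)
    up <- kf_update(pr, m, z)
    K <- pr$P %*% t(H) %*% solve(H %*% pr$P %*% t(H) + Rm)
    expect_equal(up$x, as.numeric(pr$x + K %*% (z - H %*% pr$x)),
                 tolerance = 1e-10)
    expect_equal(up$P, (diag(2) - K %*% H) %*% pr$P, tolerance = 1e-10)
    expect_true(all(diag(up$P) <= diag(pr$P) + 1e-12))
  }
})

test_that("model validation rejects inconsistent or indefinite matrices", {
  expect_error(kalman_model(A = matrix(1, 2, 1), H = 1, Q = 1, R = 1),
               class = "wearmotion_validation_error")
  expect_error(kalman_model(A = 1, H = 1, Q = -1, R = 1),
               class = "wearmotion_validation_error")
  expect_error(kalman_model(A = 1, H = 1, Q = 0, R = 0),
               class = "wearmotion_validation_error")
  expect_error(kf_update(kalman_state(0, 1), kalman_model(1, 1, 0, 1), z = c(1, 2)),
               class = "wearmotion_validation_error")
})

test_that("covariance stays symmetric PSD across thousands of random cycles", {
  set.seed(9)
  m <- kalman_model(A = matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE),
                    H = matrix(c(1, 0), 1, 2),
                    Q = diag(c(0.01, 0.01)), R = matrix(0.5))
  st <- kalman_state(c(0, 0), diag(2))
  worst_asym <- 0; min_eig <- Inf
  for (k in 1:2000) {
    st <- kf_predict(st, m)
    st <- kf_update(st, m, z = rnorm(1))
    worst_asym <- max(worst_asym, max(abs(st$P - t(st$P))))
    min_eig <- min(min_eig, min(eigen(st$P, symmetric = TRUE,
                                      only.values = TRUE)$values))
  }
  expect_lt(worst_asym, 1e-12)
  expect_gt(min_eig, -1e-12)
})

test_that("scalar gain converges to the Riccati fixed point", {
  q <- 0.01; r <- 1
  fix <- riccati_fixed_point(q, r)
  m <- kalman_model(A = 1, H = 1, Q = q, R = r)
  st <- kalman_state(0, 1)
  gain <- NA_real_
  for (k in 1:500) {
    st <- kf_predict(st, m)
    gain <- st$P[1, 1] / (st$P[1, 1] + r)
    st <- kf_update(st, m, z = 0)
  }
  expect_equal(gain, fix$gain, tolerance = 1e-6)
  expect_equal(st$P[1, 1], fix$p_post, tolerance = 1e-6)
})

test_that("the channel smoother contracts white noise below the Riccati bound", {
  set.seed(101)
  z <- rnorm(10000)
  sm <- kf_smooth_series(z, q = 0.01, r = 1)
  expect_length(sm, length(z))
  # steady-state output is an EWMA with the fixed-point gain; its variance
  # on unit white noise is gain / (2 - gain), well under half the input's
  gain <- riccati_fixed_point(0.01, 1)$gain
  oracle_bound <- gain / (2 - gain)
  expect_lt(stats::var(sm) / stats::var(z), 0.5)
  expect_lt(stats::var(sm) / stats::var(z), 2 * oracle_bound)
})

test_that("the smoother is exact on constants, lag-bounded on steps, and resets per segment", {
  expect_identical(kf_smooth_series(numeric(0), 0.01, 1), numeric(0))

  const <- rep(42, 200)
  expect_equal(kf_smooth_series(const, 0.01, 1), const, tolerance = 1e-6)

  step <- c(rep(0, 200), rep(100, 200))
  sm <- kf_smooth_series(step, q = 0.01, r = 1)
  expect_true(any(sm[201:400] > 50))       # crosses the midpoint in finite lag
  expect_true(all(sm <= 100 + 1e-9))       # no overshoot

  seg <- kf_smooth_series(c(rep(100, 50), rep(0, 50)), q = 0.0001, r = 1,
                          segments = rep(1:2, each = 50))
  expect_equal(seg[51], 0, tolerance = 1e-9)  # restart, no bleed-through

  smoothed <- smooth_stream(generate_activity_stream("stand:2,jump:1", seed = 2))
  expect_s3_class(smoothed, "imu_stream")
  expect_equal(nrow(smoothed), 15 * 9)
})
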