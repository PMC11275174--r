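# Synthetic data: labeled nine-site activity streams matching the
# per-activity acceleration-magnitude bands, and rigid-body rotation
# trajectories with body-frame gravity for attitude-solver ground truth.

#' Per-activity acceleration-magnitude bands
#'
#' Absolute-acceleration bands in raw sensor units: standing 20-200 at
#' every site; walking 2000-10,000 at the six limb sites, split into a low
#' (2000-5000) and a high (5000-10,000) sub-band that alternate between the
#' left and right limb groups on successive ticks, while the waist and
#' upper arms stay in the standing band; jumping 9000-25,000 at all nine
#' sites.
#'
#' @return Named list of `c(low, high)` bands.
#' @export
activity_bands <- function() {
  list(stand = c(20, 200),
       walk = c(2000, 10000),
       walk_low = c(2000, 5000),
       walk_high = c(5000, 10000),
       jump = c(9000, 25000))
}

parse_schedule <- function(schedule) {
  if (is.character(schedule) && length(schedule) == 1) {
    parts <- strsplit(strsplit(schedule, ",")[[1]], ":")
    schedule <- data.frame(
      label = vapply(parts, `[`, "", 1),
      duration = as.numeric(vapply(parts, `[`, "", 2)))
  }
  if (!is.data.frame(schedule) || nrow(schedule) == 0 ||
      !all(c("label", "duration") %in% names(schedule))) {
    stop_validation("schedule must be a non-empty data frame with label, duration")
  }
  schedule$label <- as.character(schedule$label)
  bad <- which(!(schedule$label %in% activity_labels()))
  if (length(bad) > 0) {
    stop_validation(sprintf("unknown activity label '%s' in schedule",
                            schedule$label[bad[1]]))
  }
  if (any(!is.finite(schedule$duration) | schedule$duration <= 0)) {
    stop_validation("schedule durations must be positive")
  }
  schedule
}

# magnitude draws for one segment: n_ticks x 9 sites x 3 axes, uniform in
# the band with optional clipped Gaussian jitter and random signs
draw_band <- function(n, band, noise_sd) {
  x <- stats::runif(n, band[1], band[2])
  if (noise_sd > 0) {
    x <- pmin(pmax(x + stats::rnorm(n, 0, noise_sd), band[1]), band[2])
  }
  x
}

#' Generate a labeled synthetic activity stream
#'
#' Emits nine-site six-axis samples at interval `dt` following a schedule
#' of activity segments. Per-axis magnitudes are drawn uniformly within the
#' activity's band (see [activity_bands()]), optionally jittered by
#' clipped Gaussian noise, and given random signs; the classifier consumes
#' absolute values, so signs never affect labels. During walking the six
#' limb sites alternate between the low and high walking sub-bands (left
#' group low on odd ticks, swapped on even ticks) to mimic gait asymmetry.
#' Gyro channels are zero plus optional noise. Output is deterministic
#' given `seed`.
#'
#' @param schedule Data frame with columns `label`, `duration` (seconds),
#'   or a compact string `"stand:10,walk:10,jump:5"`.
#' @param dt Sampling interval in seconds (default 0.2).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param noise_sd Gaussian jitter (sensor units) added to the magnitudes
#'   before clipping back into the band; 0 (default) is the noiseless mode.
#' @param gyro_noise_sd Gaussian noise on the gyro channels, rad/s.
#' @param confusable Inject boundary-band confusion: a fraction
#'   `confuse_frac` of ticks deviate from the nominal site pattern (1-4
#'   standing sites burst into the walk band, a walking tick moves 2-8
#'   sites, a jumping tick moves only 5-8), reproducing the label-confusion
#'   phenomenology near the band boundaries.
#' @param confuse_frac Fraction of confusable ticks (default 0.1).
#' @return An [imu_stream()] with `label` and `trial` (segment index)
#'   columns.
#' @export
#' @examples
#' s <- generate_activity_stream("stand:2,jump:1", dt = 0.2, seed = 1)
#' table(s$label) / 9
generate_activity_stream <- function(schedule, dt = 0.2, seed = NULL,
                                     noise_sd = 0, gyro_noise_sd = 0,
                                     confusable = FALSE, confuse_frac = 0.1) {
  schedule <- parse_schedule(schedule)
  if (!is.finite(dt) || dt <= 0) stop_validation("dt must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  bands <- activity_bands()
  sites <- body_sites()
  limbs <- limb_sites()
  left_limbs <- limbs[startsWith(limbs, "left")]
  nseg <- nrow(schedule)
  seg_ticks <- pmax(1L, as.integer(round(schedule$duration / dt)))
  total <- sum(seg_ticks) * 9L
  mags <- matrix(NA_real_, total, 3)
  t_col <- numeric(total); site_col <- character(total)
  lab_col <- character(total); trial_col <- integer(total)
  row0 <- 0L; tick0 <- 0L
  for (s in seq_len(nseg)) {
    lab <- schedule$label[s]
    n <- seg_ticks[s]
    rows <- row0 + seq_len(n * 9L)
    tick_of <- rep(seq_len(n), each = 9L)        # tick index within segment
    site_of <- rep(sites, times = n)
    t_col[rows] <- (tick0 + tick_of - 1L) * dt
    site_col[rows] <- site_of
    lab_col[rows] <- lab
    trial_col[rows] <- s
    band_of <- matrix("stand", n * 9L, 1)
    if (lab == "walk") {
      is_limb <- site_of %in% limbs
      is_left <- site_of %in% left_limbs
      low <- xor(tick_of %% 2L == 0L, is_left)   # left group low on odd ticks, swaps
      band_of[is_limb & low] <- "walk_low"
      band_of[is_limb & !low] <- "walk_high"
    } else if (lab == "jump") {
      band_of[] <- "jump"
    }
    if (confusable && confuse_frac > 0) {
      conf_tick <- stats::runif(n) < confuse_frac
      for (tk in which(conf_tick)) {
        sel <- which(tick_of == tk)              # the 9 rows of this tick
        if (lab == "stand") {
          band_of[sel[sample.int(9L, sample.int(4L, 1L))]] <- "walk_low"
        } else if (lab == "walk") {
          k <- sample(2:8, 1L)
          band_of[sel] <- "stand"
          band_of[sel[sample.int(9L, k)]] <- "walk_high"
        } else {
          k <- sample(5:8, 1L)
          band_of[sel] <- "stand"
          band_of[sel[sample.int(9L, k)]] <- "jump"
        }
      }
    }
    for (b in unique(as.character(band_of))) {
      pick <- which(band_of == b)
      for (ax in 1:3) mags[rows[pick], ax] <- draw_band(length(pick), bands[[b]], noise_sd)
    }
    row0 <- row0 + n * 9L
    tick0 <- tick0 + n
  }
  signs <- matrix(sample(c(-1, 1), total * 3L, replace = TRUE), total, 3)
  acc <- mags * signs
  gyro <- if (gyro_noise_sd > 0) {
    matrix(stats::rnorm(total * 3L, 0, gyro_noise_sd), total, 3)
  } else matrix(0, total, 3)
  imu_stream(data.frame(
    site = site_col, t = t_col,
    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    label = lab_col, trial = trial_col,
    stringsAsFactors = FALSE), dt = dt)
}

#' Check per-activity band containment of a labeled stream
#'
#' Verifies each sample's three axis magnitudes against the band its label
#' and site prescribe (standing band at quiet sites during walk).
#'
#' @param stream A labeled [imu_stream()].
#' @return Percentage (0-100) of samples with all three magnitudes in band.
#' @export
check_band_containment <- function(stream) {
  df <- as.data.frame(stream)
  if (!("label" %in% names(df))) stop_validation("stream has no label column")
  bands <- activity_bands()
  lo <- numeric(nrow(df)); hi <- numeric(nrow(df))
  quiet <- df$label == "stand" |
    (df$label == "walk" & !(df$site %in% limb_sites()))
  lo[quiet] <- bands$stand[1]; hi[quiet] <- bands$stand[2]
  wk <- df$label == "walk" & df$site %in% limb_sites()
  lo[wk] <- bands$walk[1]; hi[wk] <- bands$walk[2]
  jp <- df$label == "jump"
  lo[jp] <- bands$jump[1]; hi[jp] <- bands$jump[2]
  ok <- abs(df$ax) >= lo & abs(df$ax) <= hi &
    abs(df$ay) >= lo & abs(df$ay) <= hi &
    abs(df$az) >= lo & abs(df$az) <= hi
  100 * mean(ok)
}

#' Generate a rigid-body rotation trajectory with IMU signals
#'
#' Builds a single-site stream whose gyro channels are the body-frame
#' angular rates of a prescribed yaw/pitch/roll trajectory (intrinsic
#' Z-Y-X) and whose acceleration channels are the body-frame gravity
#' direction of the true orientation scaled to `accel_mag`, both plus
#' optional Gaussian noise. Euler-angle time derivatives are evaluated by
#' central differences with a 1e-6 s step and mapped to body rates through
#' the exact Z-Y-X kinematic matrix, so smooth trajectories are represented
#' to near machine precision.
#'
#' @param yaw,pitch,roll Functions of time (seconds) returning radians;
#'   constants are accepted.
#' @param duration Trajectory length in seconds.
#' @param dt Sampling interval in seconds.
#' @param gyro_noise_sd,accel_noise_sd Gaussian noise levels (rad/s and
#'   sensor units).
#' @param accel_mag Magnitude of the gravity vector in sensor units.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param site Body site label for the emitted stream.
#' @return List with `stream` (an [imu_stream()]) and `truth` (data frame
#'   `t`, `yaw`, `pitch`, `roll`, `q0..q3` of the true orientation at each
#'   tick).
#' @export
generate_imu_trajectory <- function(yaw = 0, pitch = 0, roll = 0,
                                    duration = 10, dt = 0.02,
                                    gyro_noise_sd = 0, accel_noise_sd = 0,
                                    accel_mag = 1, seed = NULL,
                                    site = "waist") {
  as_fn <- function(f) if (is.function(f)) f else function(t) rep(f, length(t))
  fy <- as_fn(yaw); fp <- as_fn(pitch); fr <- as_fn(roll)
  if (!is.finite(dt) || dt <= 0 || duration < dt) {
    stop_validation("need dt > 0 and duration >= dt")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  h <- 1e-6
  y <- fy(tt); p <- fp(tt); r <- fr(tt)
  dy <- (fy(tt + h) - fy(tt - h)) / (2 * h)
  dp <- (fp(tt + h) - fp(tt - h)) / (2 * h)
  dr <- (fr(tt + h) - fr(tt - h)) / (2 * h)
  # body rates for intrinsic Z-Y-X Euler angles
  wx <- dr - dy * sin(p)
  wy <- dp * cos(r) + dy * cos(p) * sin(r)
  wz <- -dp * sin(r) + dy * cos(p) * cos(r)
  qs <- t(mapply(quaternion_from_euler, y, p, r))
  grav <- t(apply(qs, 1, gravity_from_quaternion))
  acc <- grav * accel_mag
  if (accel_noise_sd > 0) acc <- acc + matrix(stats::rnorm(3 * n, 0, accel_noise_sd), n, 3)
  gyro <- cbind(wx, wy, wz)
  if (gyro_noise_sd > 0) gyro <- gyro + matrix(stats::rnorm(3 * n, 0, gyro_noise_sd), n, 3)
  stream <- imu_stream(data.frame(
    site = site, t = tt,
    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    stringsAsFactors = FALSE), dt = dt)
  truth <- data.frame(t = tt, yaw = y, pitch = p, roll = r,
                      q0 = qs[, 1], q1 = qs[, 2], q2 = qs[, 3], q3 = qs[, 4])
  list(stream = stream, truth = truth)
}
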