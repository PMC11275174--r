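#' wearmotion: wearable multi-sensor human motion recognition
#'
#' Processing pipeline for six-axis IMU streams from a nine-site body-worn
#' sensor network: quaternion attitude solution with accelerometer-based
#' proportional-integral correction ([fuse_step()]), per-channel Kalman
#' smoothing ([smooth_stream()]), and a threshold classifier that labels
#' each time window as standing, walking or jumping from the number of
#' sensors in motion ([classify_stream()]). Synthetic labeled streams and
#' rotation trajectories with ground truth come from
#' [generate_activity_stream()] and [generate_imu_trajectory()];
#' [confusion_from_decisions()] and [recognition_rates()] evaluate results.
#'
#' Acceleration is carried in raw (dimensionless) sensor units throughout:
#' the per-activity magnitude bands and the classifier threshold live on the
#' sensor's native count scale, and no conversion to physical units is
#' attempted. Angular rate is carried in radians per second internally.
#'
#' @keywords internal
"_PACKAGE"

# ---- condition helpers -------------------------------------------------

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("wearmotion_validation_error", "wearmotion_error")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("wearmotion_io_error", "wearmotion_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("wearmotion_degenerate_error", "wearmotion_error")))
}

stop_numerical <- function(msg) {
  stop(errorCondition(msg, class = c("wearmotion_numerical_error", "wearmotion_error")))
}

# ---- vocabulary --------------------------------------------------------

#' Body sites of the nine-sensor network
#'
#' The nine wearing positions, in the fixed reporting order: left forearm,
#' left upper arm, right forearm, right upper arm, waist, left calf, left
#' thigh, right calf, right thigh.
#'
#' @return Character vector of nine site labels.
#' @export
#' @examples
#' body_sites()
body_sites <- function() {
  c("left_forearm", "left_upper_arm", "right_forearm", "right_upper_arm",
    "waist", "left_calf", "left_thigh", "right_calf", "right_thigh")
}

#' Limb sites that move during walking
#'
#' The six sites in motion during a normal walk: both forearms, thighs and
#' calves. The waist and the upper arms stay quiet.
#'
#' @return Character vector of six site labels.
#' @export
limb_sites <- function() {
  c("left_forearm", "right_forearm", "left_thigh", "right_thigh",
    "left_calf", "right_calf")
}

#' Activity labels
#'
#' @return Character vector `c("stand", "walk", "jump")`, the fixed label
#'   order used by confusion matrices and reports.
#' @export
activity_labels <- function() c("stand", "walk", "jump")

# ---- stream container --------------------------------------------------

STREAM_COLS <- c("site", "t", "ax", "ay", "az", "gx", "gy", "gz")

#' Construct and validate an IMU stream
#'
#' An `imu_stream` is a data frame with one row per time-stamped six-axis
#' sample from one body site: columns `site`, `t` (seconds), `ax`, `ay`,
#' `az` (acceleration, raw sensor units), `gx`, `gy`, `gz` (angular rate,
#' rad/s), optionally `label` (activity ground truth) and `trial` (recording
#' index). Validation is total: any malformed input raises a typed error and
#' no partially valid stream is ever returned.
#'
#' @param samples Data frame with the columns above.
#' @param dt Nominal sampling interval in seconds. If `NULL`, inferred as
#'   the median gap between consecutive distinct timestamps (0.2 s when the
#'   stream has fewer than two ticks).
#' @return The validated data frame with class `imu_stream` and a `dt`
#'   attribute.
#' @export
#' @examples
#' s <- imu_stream(data.frame(
#'   site = "waist", t = c(0, 0.2), ax = 0, ay = 0, az = 100,
#'   gx = 0, gy = 0, gz = 0))
#' stream_dt(s)
imu_stream <- function(samples, dt = NULL) {
  if (!is.data.frame(samples)) {
    stop_validation("`samples` must be a data frame")
  }
  missing_cols <- setdiff(STREAM_COLS, names(samples))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("stream is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  samples$site <- as.character(samples$site)
  bad_site <- which(!(samples$site %in% body_sites()))
  if (length(bad_site) > 0) {
    stop_validation(sprintf("unknown site '%s' at row %d",
                            samples$site[bad_site[1]], bad_site[1]))
  }
  num_cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  for (cc in num_cols) {
    v <- samples[[cc]]
    if (!is.numeric(v)) stop_validation(sprintf("column '%s' is not numeric", cc))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop_validation(sprintf("non-finite value in column '%s' at row %d", cc, bad[1]))
    }
  }
  if (any(samples$t < 0)) stop_validation("timestamps must be non-negative")
  if (nrow(samples) > 1 && any(diff(samples$t) < 0)) {
    stop_validation(sprintf("timestamps are not non-decreasing at row %d",
                            which(diff(samples$t) < 0)[1] + 1L))
  }
  if (anyDuplicated(samples[, c("site", "t")]) > 0) {
    stop_validation(sprintf("duplicate sample for site '%s' at t = %g",
                            samples$site[anyDuplicated(samples[, c("site", "t")])],
                            samples$t[anyDuplicated(samples[, c("site", "t")])]))
  }
  if ("label" %in% names(samples)) {
    samples$label <- as.character(samples$label)
    bad <- which(!(samples$label %in% activity_labels()))
    if (length(bad) > 0) {
      stop_validation(sprintf("unknown activity label '%s' at row %d",
                              samples$label[bad[1]], bad[1]))
    }
  }
  if (is.null(dt)) {
    ticks <- unique(samples$t)
    dt <- if (length(ticks) >= 2) stats::median(diff(ticks)) else 0.2
  }
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop_validation("`dt` must be a single positive number")
  }
  rownames(samples) <- NULL
  structure(samples, dt = dt, class = c("imu_stream", "data.frame"))
}

#' Nominal sampling interval of a stream
#'
#' @param stream An [imu_stream()].
#' @return The sampling interval in seconds.
#' @export
stream_dt <- function(stream) {
  dt <- attr(stream, "dt", exact = TRUE)
  if (is.null(dt)) 0.2 else dt
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d samples, %d site(s), dt = %g s\n",
              nrow(x), length(unique(x$site)), stream_dt(x)))
  if ("label" %in% names(x)) {
    tab <- table(factor(x$label, levels = activity_labels()))
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# ---- CSV i/o -----------------------------------------------------------

#' Read an IMU stream from CSV
#'
#' Reads the tabular stream format written by the acquisition host: header
#' `site,t,ax,ay,az,gx,gy,gz` with an optional trailing `label` column,
#' UTF-8, `.` decimal separator. Rows with unparseable numbers are rejected
#' with an error naming the row, never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param angular_units Units of the gyroscope columns in the file:
#'   `"deg"` (degrees/second, the sensor's native output and the default)
#'   or `"rad"`. Values are converted to rad/s on read.
#' @param dt Sampling interval override; inferred from timestamps if `NULL`.
#' @return An [imu_stream()].
#' @export
read_stream <- function(path, angular_units = c("deg", "rad"), dt = NULL) {
  angular_units <- match.arg(angular_units)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(STREAM_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("CSV is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  num_cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]) & raw[[cc]] != "")
    if (length(bad) > 0) {
      stop_validation(sprintf("unparseable value '%s' in column '%s' at data row %d",
                              raw[[cc]][bad[1]], cc, bad[1]))
    }
    if (anyNA(v) && nrow(raw) > 0) {
      stop_validation(sprintf("missing value in column '%s' at data row %d",
                              cc, which(is.na(v))[1]))
    }
    raw[[cc]] <- v
  }
  if (angular_units == "deg") {
    for (cc in c("gx", "gy", "gz")) raw[[cc]] <- raw[[cc]] * pi / 180
  }
  keep <- intersect(c(STREAM_COLS, "label", "trial"), names(raw))
  out <- raw[, keep, drop = FALSE]
  if ("trial" %in% names(out)) out$trial <- as.integer(out$trial)
  imu_stream(out, dt = dt)
}

#' Write an IMU stream to CSV
#'
#' Inverse of [read_stream()]: `read_stream(write_stream(s, path))`
#' reproduces `s` to numeric round-trip precision. The `label` column, when
#' present, is preserved verbatim.
#'
#' @param stream An [imu_stream()].
#' @param path Output path.
#' @param angular_units Units to write the gyroscope columns in (`"deg"`,
#'   the reader's default dialect, or `"rad"`).
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, angular_units = c("deg", "rad")) {
  angular_units <- match.arg(angular_units)
  stream <- imu_stream(as.data.frame(stream), dt = stream_dt(stream))
  out <- as.data.frame(stream)
  if (angular_units == "deg") {
    for (cc in c("gx", "gy", "gz")) out[[cc]] <- out[[cc]] * 180 / pi
  }
  keep <- intersect(c(STREAM_COLS, "label", "trial"), names(out))
  ok <- tryCatch({
    utils::write.csv(out[, keep, drop = FALSE], path, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to: %s", path))
  invisible(path)
}
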