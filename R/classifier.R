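# Threshold classifier: absolute-value processing per axis, any-axis
# activation against threshold A, active-sensor counting across the nine
# sites, and the count-band rule stand/walk/jump.

#' Threshold-classifier configuration
#'
#' The classifier counts, per window, the body sites whose any-axis
#' absolute acceleration exceeds the threshold `a`; the count `i` maps to a
#' label: walk when `i1 <= i <= i2`, jump when `i >= i3`, stand otherwise.
#' All four values are calibration parameters. The defaults place `a`
#' between the standing band maximum (200) and the walking band minimum
#' (2000) in raw sensor units, and take walking to move the six limb sites
#' (`i1 = 3`, `i2 = 6`) and jumping to move more (`i3 = 7`).
#'
#' @param a Acceleration threshold, raw sensor units (`> 0`).
#' @param i1,i2,i3 Active-sensor count bounds; require
#'   `0 < i1 <= i2 < i3 <= 9`.
#' @param window Window length in sampling ticks (`>= 1`); one decision is
#'   emitted per window.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(a = 1000, i1 = 3, i2 = 6, i3 = 7, window = 1) {
  if (!is.finite(a) || a <= 0) stop_validation("threshold a must be positive")
  i1 <- as.integer(i1); i2 <- as.integer(i2); i3 <- as.integer(i3)
  window <- as.integer(window)
  if (!(0 < i1 && i1 <= i2 && i2 < i3 && i3 <= 9)) {
    stop_validation("count bounds must satisfy 0 < i1 <= i2 < i3 <= 9")
  }
  if (window < 1) stop_validation("window must be at least 1 tick")
  structure(list(a = a, i1 = i1, i2 = i2, i3 = i3, window = window),
            class = "threshold_config")
}

#' Absolute-value processing of an acceleration triple
#'
#' @param a Acceleration triple (or matrix with three columns).
#' @return Componentwise absolute values.
#' @export
abs_process <- function(a) abs(a)

#' Is a site active at this sample?
#'
#' A site is in motion when any axis magnitude strictly exceeds the
#' threshold; equality is inactive.
#'
#' @param v Magnitude triple from [abs_process()].
#' @param a Threshold (`> 0`).
#' @return Logical.
#' @export
site_active <- function(v, a) {
  if (!is.finite(a) || a <= 0) stop_validation("threshold a must be positive")
  max(v) > a
}

#' Count active sites in one window
#'
#' A site counts as active when [site_active()] holds for any of its
#' samples within the window; each site counts at most once.
#'
#' @param window_samples Data frame with columns `site`, `ax`, `ay`, `az`
#'   covering one window.
#' @param a Threshold.
#' @return Integer count `i` in `0..9`.
#' @export
count_active <- function(window_samples, a) {
  if (nrow(window_samples) == 0) return(0L)
  vmax <- pmax(abs(window_samples$ax), abs(window_samples$ay),
               abs(window_samples$az))
  length(unique(window_samples$site[vmax > a]))
}

#' Label from an active-site count
#'
#' @param i Active-site count(s), each in `0..9`.
#' @param cfg A [threshold_config()].
#' @return Character label(s): `"walk"` when `i1 <= i <= i2`, `"jump"` when
#'   `i >= i3`, `"stand"` otherwise (including the gap `i2 < i < i3`).
#' @export
classify_count <- function(i, cfg = threshold_config()) {
  if (!inherits(cfg, "threshold_config")) cfg <- do.call(threshold_config, cfg)
  if (any(i < 0 | i > 9)) stop_validation("count i must lie in 0..9")
  ifelse(i >= cfg$i3, "jump",
         ifelse(i >= cfg$i1 & i <= cfg$i2, "walk", "stand"))
}

#' Classify a stream window by window
#'
#' Groups the stream's distinct timestamps into consecutive, non-overlapping
#' windows of `cfg$window` ticks (a trailing partial window is classified as
#' long as it holds at least one sample), counts the active sites per
#' window, and applies the count rule. Sites absent from a window count as
#' inactive.
#'
#' @param stream An [imu_stream()] (raw or [smooth_stream()]-ed).
#' @param cfg A [threshold_config()].
#' @return Data frame of window decisions: `t_start`, `t_end`, `i`,
#'   `label`, one logical `active_<site>` column per site, and — when the
#'   stream carries ground truth — a `truth` column holding the window's
#'   majority label (ties resolved toward stand).
#' @export
classify_stream <- function(stream, cfg = threshold_config()) {
  df <- as.data.frame(stream)
  if (nrow(df) == 0 || length(unique(df$site)) == 0) {
    stop_validation("cannot classify a stream with no samples")
  }
  ticks <- sort(unique(df$t))
  wid <- ceiling(match(df$t, ticks) / cfg$window)
  nwin <- max(wid)
  sites <- body_sites()
  vmax <- pmax(abs(df$ax), abs(df$ay), abs(df$az))
  active <- vmax > cfg$a
  wf <- factor(wid, levels = seq_len(nwin))
  sf <- factor(df$site, levels = sites)
  act <- tapply(active, list(wf, sf), any)
  act[is.na(act)] <- FALSE
  i <- as.integer(rowSums(act))
  out <- data.frame(
    t_start = as.numeric(tapply(df$t, wf, min)),
    t_end   = as.numeric(tapply(df$t, wf, max)),
    i = i,
    label = classify_count(i, cfg),
    stringsAsFactors = FALSE
  )
  colnames(act) <- paste0("active_", sites)
  out <- cbind(out, as.data.frame(act))
  if ("label" %in% names(df)) {
    out$truth <- as.character(tapply(df$label, wf, majority_label))
  }
  rownames(out) <- NULL
  out
}

#' Full classification pipeline
#'
#' Kalman-smooth the acceleration channels (optional, on by default), then
#' run the windowed threshold classifier.
#'
#' @param stream An [imu_stream()].
#' @param cfg A [threshold_config()].
#' @param kalman Apply [smooth_stream()] first?
#' @param q,r Kalman noise variances forwarded to [smooth_stream()].
#' @return Window decisions as from [classify_stream()].
#' @export
classify_pipeline <- function(stream, cfg = threshold_config(), kalman = TRUE,
                              q = NULL, r = NULL) {
  if (kalman) stream <- smooth_stream(stream, q = q, r = r)
  classify_stream(stream, cfg)
}
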