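# Confusion-matrix construction and recognition-rate arithmetic, plus the
# end-to-end synthetic recognition experiment.

#' Round half away from zero
#'
#' Reported rates use commercial (half-up) rounding, not the banker's
#' rounding of [round()].
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Majority label of a window or trial
#'
#' @param labels Character vector of activity labels.
#' @return The most frequent label; ties resolve in the order stand, walk,
#'   jump.
#' @export
majority_label <- function(labels) {
  tab <- table(factor(labels, levels = activity_labels()))
  names(tab)[which.max(tab)]
}

#' Confusion matrix from truth/prediction sequences
#'
#' @param truth,predicted Equal-length sequences of activity labels; rows
#'   of the result are truth, columns predictions, both in the fixed order
#'   stand, walk, jump.
#' @return A 3x3 integer matrix of class `confusion_matrix`.
#' @export
#' @examples
#' confusion_from_decisions(rep("stand", 10), rep("stand", 10))
confusion_from_decisions <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_validation("truth and predicted must have equal length")
  }
  labs <- activity_labels()
  if (!all(truth %in% labs) || !all(predicted %in% labs)) {
    stop_validation("labels must be one of stand/walk/jump")
  }
  cm <- table(factor(truth, levels = labs), factor(predicted, levels = labs))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(truth = labs, predicted = labs))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Build a confusion matrix from printed counts
#'
#' Convenience constructor for count tables reported row-wise
#' (truth stand, walk, jump) x (predicted stand, walk, jump).
#'
#' @param counts Numeric length-9 vector or 3x3 matrix, row-major by truth.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix_from_counts <- function(counts) {
  m <- matrix(as.integer(counts), 3, 3, byrow = is.null(dim(counts)),
              dimnames = list(truth = activity_labels(),
                              predicted = activity_labels()))
  if (any(m < 0)) stop_validation("counts must be non-negative")
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  rr <- recognition_rates(x)
  cat(sprintf("per-class recognition rate: %s; mean %.2f%%\n",
              paste(sprintf("%s %.2f%%", names(rr$per_class), rr$per_class),
                    collapse = ", "),
              rr$mean))
  invisible(x)
}

#' Per-class recognition rates and their mean
#'
#' The rate of class `c` is `100 * counts[c, c] / rowsum_c`, reported at
#' two decimals (half-up). The mean is the unweighted arithmetic mean of
#' the three per-class rates — computed from the unrounded rates, then
#' rounded — not the pooled accuracy; with unequal row totals the two
#' differ.
#'
#' @param cm A `confusion_matrix`.
#' @return List with `per_class` (named, rounded), `mean` (rounded),
#'   `per_class_raw` and `mean_raw` (full precision), and `pooled`
#'   (overall accuracy percent, full precision).
#' @export
recognition_rates <- function(cm) {
  totals <- rowSums(cm)
  if (any(totals <= 0)) stop_validation("every true class needs at least one trial")
  raw <- 100 * diag(cm) / totals
  names(raw) <- rownames(cm)
  list(per_class = round_half_up(raw, 2),
       mean = round_half_up(mean(raw), 2),
       per_class_raw = raw,
       mean_raw = mean(raw),
       pooled = 100 * sum(diag(cm)) / sum(totals))
}

#' Unweighted mean of a subset of per-class rates
#'
#' @param rates Non-empty numeric vector of per-class rates (percent).
#' @return Their unweighted mean, rounded to two decimals (half-up).
#' @export
#' @examples
#' k_class_mean(c(100 * 590 / 600, 100 * 580 / 600))
k_class_mean <- function(rates) {
  if (length(rates) == 0) stop_validation("need at least one rate")
  if (!all(is.finite(rates))) stop_validation("rates must be finite")
  round_half_up(mean(rates), 2)
}

#' Synthetic recognition experiment
#'
#' The desk-scale analogue of a volunteer study: simulate `n_per_class`
#' independent trials per activity (each trial one schedule segment of
#' `ticks_per_trial` ticks), classify with one decision window per trial,
#' take each trial's majority window label, and tabulate trials against
#' ground truth.
#'
#' @param n_per_class Trials per activity class.
#' @param ticks_per_trial Sampling ticks per trial.
#' @param dt Sampling interval, seconds.
#' @param cfg A [threshold_config()]; its `window` is set to
#'   `ticks_per_trial` so windows align with trials.
#' @param kalman Smooth acceleration channels before classifying?
#' @param noise_sd,confusable,confuse_frac Forwarded to
#'   [generate_activity_stream()].
#' @param seed Integer seed for the whole experiment.
#' @return List with `confusion` (a `confusion_matrix`), `rates` (from
#'   [recognition_rates()]), `band_containment` (percent), and `n_trials`.
#' @export
run_recognition_experiment <- function(n_per_class = 1000, ticks_per_trial = 2,
                                       dt = 0.2, cfg = threshold_config(),
                                       kalman = TRUE, noise_sd = 0,
                                       confusable = FALSE, confuse_frac = 0.1,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  labs <- rep(activity_labels(), each = n_per_class)
  labs <- sample(labs)                      # interleave trial order
  schedule <- data.frame(label = labs, duration = ticks_per_trial * dt)
  stream <- generate_activity_stream(schedule, dt = dt, seed = NULL,
                                     noise_sd = noise_sd,
                                     confusable = confusable,
                                     confuse_frac = confuse_frac)
  containment <- check_band_containment(stream)
  cfg$window <- as.integer(ticks_per_trial)
  dec <- classify_pipeline(stream, cfg, kalman = kalman)
  cm <- confusion_from_decisions(dec$truth, dec$label)
  list(confusion = cm, rates = recognition_rates(cm),
       band_containment = containment, n_trials = nrow(dec))
}
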