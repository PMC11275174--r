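# Linear Kalman filter: general matrix predict/update plus the scalar
# random-walk smoother applied per acceleration channel ahead of the
# threshold classifier.

as_mat <- function(x, name) {
  if (is.null(x)) return(NULL)
  m <- as.matrix(x)
  if (!is.numeric(m) || !all(is.finite(m))) {
    stop_validation(sprintf("matrix '%s' must be finite numeric", name))
  }
  m
}

is_psd <- function(m, tol = 1e-10) {
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) return(FALSE)
  all(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values >= -tol)
}

#' Kalman model matrices
#'
#' State-space model `x_k = A x_{k-1} + B u_{k-1} + w`, `z_k = H x_k + v`,
#' with process noise covariance `Q` and observation noise covariance `R`
#' (the noises enter only through their covariances).
#'
#' @param A State-transition matrix (n x n); scalars are accepted.
#' @param H Observation matrix (m x n).
#' @param Q Process-noise covariance (n x n, symmetric PSD).
#' @param R Observation-noise covariance (m x m, symmetric positive
#'   definite).
#' @param B Control-input matrix (n x p), or `NULL` for no control.
#' @return A `kalman_model` list.
#' @export
kalman_model <- function(A, H, Q, R, B = NULL) {
  A <- as_mat(A, "A"); H <- as_mat(H, "H")
  Q <- as_mat(Q, "Q"); R <- as_mat(R, "R"); B <- as_mat(B, "B")
  n <- nrow(A)
  if (ncol(A) != n) stop_validation("A must be square")
  if (ncol(H) != n) stop_validation("H must have as many columns as states")
  if (!identical(dim(Q), c(n, n))) stop_validation("Q must be n x n")
  if (!identical(dim(R), c(nrow(H), nrow(H)))) stop_validation("R must be m x m")
  if (!is.null(B) && nrow(B) != n) stop_validation("B must have n rows")
  if (!is_psd(Q)) stop_validation("Q must be symmetric positive semi-definite")
  if (!is_psd(R) ||
      any(eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop_validation("R must be symmetric positive definite")
  }
  structure(list(A = A, H = H, Q = Q, R = R, B = B), class = "kalman_model")
}

#' Kalman filter state
#'
#' @param x State estimate (length-n numeric).
#' @param P Estimate covariance (n x n symmetric PSD); scalars accepted.
#' @return A `kalman_state` list.
#' @export
kalman_state <- function(x, P) {
  x <- as.numeric(x)
  P <- as_mat(P, "P")
  if (!all(is.finite(x))) stop_validation("state x must be finite")
  if (!identical(dim(P), c(length(x), length(x)))) {
    stop_validation("P must be n x n for an n-state x")
  }
  if (!is_psd(P)) stop_validation("P must be symmetric positive semi-definite")
  structure(list(x = x, P = P), class = "kalman_state")
}

#' Kalman prediction step
#'
#' `x_pred = A x + B u`, `P_pred = A P A' + Q`; the returned covariance is
#' symmetrized to machine precision.
#'
#' @param state A [kalman_state()].
#' @param model A [kalman_model()].
#' @param u Control input (ignored when the model has no `B`).
#' @return The predicted `kalman_state`.
#' @export
kf_predict <- function(state, model, u = NULL) {
  x <- model$A %*% state$x
  if (!is.null(model$B)) {
    if (is.null(u)) u <- numeric(ncol(model$B))
    if (length(u) != ncol(model$B)) stop_validation("control u has wrong length")
    x <- x + model$B %*% u
  }
  P <- model$A %*% state$P %*% t(model$A) + model$Q
  P <- (P + t(P)) / 2
  structure(list(x = as.numeric(x), P = P), class = "kalman_state")
}

#' Kalman update step
#'
#' Gain `K = P H' (H P H' + R)^{-1}`, then `x <- x + K (z - H x)` and the
#' covariance contracts to `(I - K H) P` (computed in Joseph form for
#' numerical robustness; the two agree at the optimal gain).
#'
#' @param state The predicted [kalman_state()].
#' @param model A [kalman_model()].
#' @param z Observation vector.
#' @return The updated `kalman_state`.
#' @export
kf_update <- function(state, model, z) {
  H <- model$H
  if (length(z) != nrow(H)) stop_validation("observation z has wrong length")
  P <- state$P
  S <- H %*% P %*% t(H) + model$R
  S <- (S + t(S)) / 2
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop_numerical(sprintf("innovation covariance is singular (det = %g)", det(S)))
  })
  K <- P %*% t(H) %*% Sinv
  x <- state$x + as.numeric(K %*% (z - H %*% state$x))
  IKH <- diag(nrow(P)) - K %*% H
  Pn <- IKH %*% P %*% t(IKH) + K %*% model$R %*% t(K)
  Pn <- (Pn + t(Pn)) / 2
  structure(list(x = x, P = Pn), class = "kalman_state")
}

#' Scalar random-walk smoothing of one channel
#'
#' Causal scalar Kalman filter with `A = H = 1`, `B = 0`: prediction
#' inflates the variance by `q`, the update blends in each observation with
#' gain `p / (p + r)`. Optional segment boundaries reset the filter state,
#' so independent recordings do not bleed into each other.
#'
#' @param z Numeric series to smooth.
#' @param q Process-noise variance.
#' @param r Observation-noise variance.
#' @param x0,p0 Initial state and variance; default to the first
#'   observation of each segment and `r`.
#' @param segments Optional vector (same length as `z`) of segment ids; the
#'   filter restarts whenever the id changes.
#' @return The filtered series, same length as `z`.
#' @export
kf_smooth_series <- function(z, q, r, x0 = NULL, p0 = NULL, segments = NULL) {
  n <- length(z)
  if (n == 0) return(numeric(0))
  if (!all(is.finite(z))) stop_validation("series must be finite")
  if (q < 0 || r <= 0) stop_validation("need q >= 0 and r > 0")
  if (is.null(segments)) segments <- rep(1L, n)
  if (length(segments) != n) stop_validation("segments must match series length")
  out <- numeric(n)
  x <- NA_real_; p <- NA_real_; prev <- NULL
  for (k in seq_len(n)) {
    if (is.null(prev) || segments[k] != prev) {
      x <- if (is.null(x0)) z[k] else x0
      p <- if (is.null(p0)) r else p0
      prev <- segments[k]
    }
    p <- p + q
    gain <- p / (p + r)
    x <- x + gain * (z[k] - x)
    p <- (1 - gain) * p
    out[k] <- x
  }
  out
}

#' Kalman-smooth the acceleration channels of a stream
#'
#' Applies the scalar random-walk filter of [kf_smooth_series()]
#' independently to `ax`, `ay`, `az` of every site. When the stream carries
#' a `trial` column the filter restarts at each trial boundary. The
#' observation-noise variance defaults to the sample variance of the first
#' 10 samples of each site channel (floored at 1e-8), and the process noise
#' to `0.01 * r`, a deliberately smooth setting.
#'
#' @param stream An [imu_stream()].
#' @param q,r Process and observation noise variances; `NULL` selects the
#'   defaults above per channel.
#' @return The stream with smoothed acceleration channels; gyro channels
#'   and metadata untouched.
#' @export
smooth_stream <- function(stream, q = NULL, r = NULL) {
  df <- as.data.frame(stream)
  if (nrow(df) == 0) return(stream)
  seg <- if ("trial" %in% names(df)) df$trial else rep(1L, nrow(df))
  for (site in unique(df$site)) {
    idx <- which(df$site == site)
    for (cc in c("ax", "ay", "az")) {
      z <- df[[cc]][idx]
      r_c <- r
      if (is.null(r_c)) {
        r_c <- if (length(z) >= 2) stats::var(utils::head(z, 10)) else 0
        r_c <- max(r_c, 1e-8)
      }
      q_c <- if (is.null(q)) 0.01 * r_c else q
      df[[cc]][idx] <- kf_smooth_series(z, q = q_c, r = r_c, segments = seg[idx])
    }
  }
  imu_stream(df, dt = stream_dt(stream))
}
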