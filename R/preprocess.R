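#' Linear detrending
#'
#' Removes the per-column least-squares line against the time index, so
#' each output column has zero mean and zero slope. Applied before
#' temporal filtering in the standard denoising order.
#'
#' @param series T x N numeric matrix (T >= 3).
#' @return Detrended matrix of the same dimensions.
#' @export
detrend_linear <- function(series) {
  series <- as.matrix(series)
  t_points <- nrow(series)
  if (t_points < 3) stop("detrending requires at least 3 time points")
  tt <- seq_len(t_points)
  X <- cbind(1, tt - mean(tt))
  series - X %*% qr.solve(X, series)
}

#' Ideal bandpass filter
#'
#' Forward/inverse discrete-Fourier masking: frequency components with
#' `low_hz <= f <= high_hz` (boundary inclusive) are kept, everything
#' else — including the DC term when `low_hz > 0` — is zeroed. The
#' ideal mask makes results bit-reproducible and the operation
#' idempotent; the default band 0.01-0.08 Hz is the standard
#' resting-state fMRI band.
#'
#' @param series T x N matrix.
#' @param tr sampling interval (repetition time), seconds.
#' @param low_hz,high_hz passband edges; requires
#'   `0 <= low_hz < high_hz < 0.5/tr`.
#' @return Filtered matrix, same dimensions.
#' @export
bandpass_filter <- function(series, tr, low_hz = 0.01, high_hz = 0.08) {
  series <- as.matrix(series)
  nyquist <- 0.5 / tr
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyquist)
    stop("high_hz (", high_hz, " Hz) must be below Nyquist (", nyquist, " Hz)")
  t_points <- nrow(series)
  k <- seq(0, t_points - 1)
  k <- pmin(k, t_points - k)    # fold on integer bin indices: the mask must
  freqs <- k / (t_points * tr)  # be exactly Hermitian-symmetric or the
  keep <- freqs >= low_hz & freqs <= high_hz  # filter stops being idempotent
  out <- apply(series, 2, function(x) Re(fft(fft(x) * keep, inverse = TRUE)) / t_points)
  matrix(out, t_points, ncol(series), dimnames = dimnames(series))
}

#' Friston 24-parameter motion regressors
#'
#' Expands a 6-parameter rigid-body motion trace into the 24-regressor
#' set `[R(t), R(t-1), R(t)^2, R(t-1)^2]`; lagged columns are
#' zero-padded at the first volume.
#'
#' @param motion T x 6 matrix (3 translations, 3 rotations).
#' @return T x 24 matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have exactly 6 parameters")
  if (nrow(motion) < 2) stop("motion trace must cover at least 2 volumes")
  lagged <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lagged, motion^2, lagged^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag"),
                     paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lagsq"))
  out
}

#' Nuisance regression
#'
#' Ordinary-least-squares residuals of each signal column on an
#' intercept plus the supplied regressors (e.g. white-matter, CSF and
#' global signals and the Friston-24 set). Rank-deficient regressor
#' sets are handled by dropping dependent columns with a warning naming
#' them.
#'
#' @param series T x N matrix.
#' @param regressors T x K matrix.
#' @return Residual matrix, same dimensions as `series`; residuals are
#'   orthogonal to every retained regressor.
#' @export
regress_nuisance <- function(series, regressors) {
  series <- as.matrix(series)
  regressors <- as.matrix(regressors)
  t_points <- nrow(series)
  stopifnot(nrow(regressors) == t_points)
  if (t_points <= ncol(regressors) + 1)
    stop("need more time points than regressors")
  X <- cbind(intercept = 1, regressors)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    warning("dropping rank-deficient regressor(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(X)
  }
  res <- series - X %*% qr.coef(qrx, series)
  dimnames(res) <- dimnames(series)
  res
}

#' Head-motion quality control
#'
#' A subject is excluded if the maximum absolute rotation exceeds 2.0
#' degrees, the maximum absolute translation in any orthogonal
#' direction exceeds 2.0 mm, or the mean relative (volume-to-volume)
#' root-mean-square displacement of the three translations exceeds
#' 0.2 mm. Relative RMS is computed from translations only; rotations
#' enter through the max-rotation rule.
#'
#' @param motion T x 6 matrix (translations mm, rotations degrees).
#' @param max_trans_mm,max_rot_deg,max_mean_rms_mm exclusion thresholds.
#' @return List: `include` (logical), `reasons` (character vector among
#'   `"translation"`, `"rotation"`, `"meanRMS"`), and the measured
#'   `max_trans`, `max_rot`, `mean_rms`.
#' @export
motion_qc <- function(motion, max_trans_mm = 2.0, max_rot_deg = 2.0,
                      max_mean_rms_mm = 0.2) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  trans <- motion[, 1:3, drop = FALSE]
  rot <- motion[, 4:6, drop = FALSE]
  max_trans <- max(abs(trans))
  max_rot <- max(abs(rot))
  d <- diff(trans)
  mean_rms <- if (nrow(motion) > 1) mean(sqrt(rowSums(d^2))) else 0
  reasons <- c(
    if (max_trans > max_trans_mm) "translation",
    if (max_rot > max_rot_deg) "rotation",
    if (mean_rms > max_mean_rms_mm) "meanRMS"
  )
  list(include = length(reasons) == 0, reasons = reasons %||% character(0),
       max_trans = max_trans, max_rot = max_rot, mean_rms = mean_rms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motion QC report for a cohort
#'
#' @param motion_list named list of motion traces.
#' @return Data frame: `subject_id`, `max_trans`, `max_rot`, `mean_rms`,
#'   `decision`, `reasons`.
#' @export
motion_qc_report <- function(motion_list) {
  rows <- lapply(names(motion_list), function(id) {
    q <- motion_qc(motion_list[[id]])
    data.frame(subject_id = id, max_trans = q$max_trans, max_rot = q$max_rot,
               mean_rms = q$mean_rms,
               decision = if (q$include) "include" else "exclude",
               reasons = paste(q$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full time-series denoising
#'
#' Applies, in order: linear detrending, ideal bandpass filtering, and
#' nuisance regression (intercept + supplied nuisance signals + the
#' Friston-24 expansion of the motion trace). The order follows the
#' conventional listing (filtering before regression); set
#' `order = "regress_first"` to regress before filtering.
#'
#' @param series T x N matrix.
#' @param tr repetition time, seconds.
#' @param motion optional T x 6 motion trace.
#' @param nuisance optional T x K matrix of nuisance signals.
#' @param low_hz,high_hz bandpass edges.
#' @param order `"filter_first"` (default) or `"regress_first"`.
#' @return Denoised T x N matrix.
#' @details When filtering precedes regression, the regressors are
#'   passed through the same bandpass before the fit: regressing
#'   full-band confounds from band-limited data removes the shared
#'   variance only partially and can reintroduce stopband noise, so
#'   data and confound model must live in the same frequency band.
#' @export
preprocess_timeseries <- function(series, tr, motion = NULL, nuisance = NULL,
                                  low_hz = 0.01, high_hz = 0.08,
                                  order = c("filter_first", "regress_first")) {
  order <- match.arg(order)
  regs <- NULL
  if (!is.null(nuisance)) regs <- cbind(regs, as.matrix(nuisance))
  if (!is.null(motion)) regs <- cbind(regs, friston24(motion))
  x <- detrend_linear(series)
  if (order == "filter_first") {
    x <- bandpass_filter(x, tr, low_hz, high_hz)
    if (!is.null(regs)) {
      regs <- bandpass_filter(regs, tr, low_hz, high_hz)
      x <- regress_nuisance(x, regs)
    }
  } else {
    if (!is.null(regs)) x <- regress_nuisance(x, regs)
    x <- bandpass_filter(x, tr, low_hz, high_hz)
  }
  x
}
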