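#' Discard initial volumes of a BOLD series
#'
#' Removes the first \code{n} volumes, the standard guard against T1
#' saturation effects at the start of an acquisition. Motion tables must be
#' truncated identically by the caller (\code{\link{run_pipeline}} does so).
#'
#' @param series a \code{\link{bold_series}}.
#' @param n number of leading volumes to drop (default 10).
#' @return a \code{bold_series} with \code{t - n} volumes.
#' @export
drop_initial_volumes <- function(series, n = 10L) {
  t <- n_volumes(series)
  if (n < 0) stop("'n' must be nonnegative")
  if (n >= t) stop(sprintf("cannot drop %d volumes from a series of %d", n, t))
  if (n == 0L) return(series)
  series$data <- series$data[, , , -seq_len(n), drop = FALSE]
  series$volume_kept <- series$volume_kept[-seq_len(n)]
  series
}

#' Construct a motion-parameter table
#'
#' @param translations t x 3 numeric matrix of rigid-body translations (mm).
#' @param rotations t x 3 numeric matrix of rigid-body rotations (radians).
#' @return object of class \code{motion_table}.
#' @export
motion_table <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L)
    stop("translations and rotations must each have 3 columns")
  if (nrow(translations) != nrow(rotations))
    stop("translations and rotations must have the same number of rows")
  structure(list(translations = translations, rotations = rotations),
            class = "motion_table")
}

#' Framewise displacement (Power convention)
#'
#' FD at frame i (i >= 2) is the sum of absolute backward differences of the
#' six rigid-body parameters, rotations converted to arc length on a sphere
#' of radius \code{head_radius_mm}. The first frame is 0 by convention.
#'
#' @param motion a \code{\link{motion_table}}.
#' @param head_radius_mm sphere radius used to convert rotations (radians)
#'   into mm of displacement; 50 mm is the standard assumption.
#' @param threshold_mm scrubbing threshold stored with the series (default
#'   0.2 mm).
#' @return object of class \code{fd_series}: fields \code{fd} (mm, length t)
#'   and \code{threshold_mm}.
#' @export
compute_fd <- function(motion, head_radius_mm = 50, threshold_mm = 0.2) {
  tr <- motion$translations
  ro <- motion$rotations
  if (nrow(tr) < 2L) stop("need at least 2 motion rows to compute FD")
  if (any(!is.finite(tr)) || any(!is.finite(ro)))
    stop("motion parameters contain non-finite values")
  dtr <- abs(diff(tr))
  dro <- abs(diff(ro)) * head_radius_mm
  fd <- c(0, rowSums(dtr) + rowSums(dro))
  structure(list(fd = fd, threshold_mm = threshold_mm), class = "fd_series")
}

#' Screen a session for gross head motion
#'
#' Sessions in which any volume exceeds the stated translation or rotation
#' limit are excluded from analysis outright (before scrubbing, which only
#' removes individual volumes).
#'
#' @param motion a \code{\link{motion_table}} (rotations in radians).
#' @param trans_limit_mm maximum tolerated absolute translation (default 1.5).
#' @param rot_limit_deg maximum tolerated absolute rotation in degrees
#'   (default 1.5); motion-file rotations are converted from radians.
#' @return list with \code{pass} (logical) and \code{offending_frames}
#'   (integer vector of 1-based frame indices violating either limit).
#' @export
screen_gross_motion <- function(motion, trans_limit_mm = 1.5,
                                rot_limit_deg = 1.5) {
  rot_deg <- abs(motion$rotations) * 180 / pi
  bad <- apply(abs(motion$translations) > trans_limit_mm, 1, any) |
    apply(rot_deg > rot_limit_deg, 1, any)
  list(pass = !any(bad), offending_frames = which(bad))
}

#' Friston 24-parameter motion regressor matrix
#'
#' The 24 columns are the six rigid-body parameters, their one-volume-lagged
#' copies (first row zero-filled), and the squares of both sets.
#'
#' @param motion a \code{\link{motion_table}}.
#' @return t x 24 numeric matrix, columns ordered (6 params, 6 lagged,
#'   6 squared, 6 lagged-squared).
#' @export
build_friston24 <- function(motion) {
  p <- cbind(motion$translations, motion$rotations)
  if (nrow(p) < 2L) stop("need at least 2 motion rows")
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag, p^2, lag^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Regress nuisance signals out of every voxel
#'
#' Each voxel time course is replaced by its ordinary-least-squares residual
#' against the design \code{[intercept | regressors]}. The intercept is
#' always added, so output voxel series have zero mean and are orthogonal to
#' every regressor column.
#'
#' @param series a \code{\link{bold_series}}.
#' @param regressors t x k numeric matrix (e.g. Friston-24 plus WM/CSF mean
#'   signals); must have full column rank after intercept augmentation.
#' @return a \code{bold_series} of residuals.
#' @export
nuisance_regress <- function(series, regressors) {
  t <- n_volumes(series)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != t)
    stop("regressor rows must equal the number of volumes")
  if (ncol(regressors) >= t)
    stop("more regressors than time points")
  X <- cbind(intercept = 1, regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  d <- dim(series$data)
  Y <- matrix(series$data, prod(d[1:3]), d[4])
  res <- qr.resid(qrX, t(Y))
  series$data <- array(t(res), d)
  series
}

#' Scrub high-motion volumes
#'
#' Volumes whose framewise displacement exceeds the threshold are removed;
#' the remaining frames are concatenated in time order (no interpolation or
#' imputation), which is what every downstream metric sees.
#'
#' @param series a \code{\link{bold_series}}.
#' @param fd an \code{fd_series} from \code{\link{compute_fd}}, same length
#'   as the series.
#' @return a \code{bold_series} of the kept frames; attributes
#'   \code{retained_fraction} (kept / total) and \code{kept} (logical vector
#'   over the input frames) record what was removed.
#' @export
scrub <- function(series, fd) {
  t <- n_volumes(series)
  if (length(fd$fd) != t)
    stop("FD length must equal the number of volumes")
  keep <- fd$fd <= fd$threshold_mm
  if (!any(keep)) stop("scrubbing removed every volume")
  series$data <- series$data[, , , keep, drop = FALSE]
  series$volume_kept <- series$volume_kept[keep]
  attr(series, "retained_fraction") <- mean(keep)
  attr(series, "kept") <- keep
  series
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain mask: the DFT of each voxel series is computed, bins
#' outside \code{[low_hz, high_hz]} (including the zero-frequency bin) are
#' zeroed, and the series is inverse-transformed. Exact band edges, zero
#' phase shift, zero output mean.
#'
#' @param series a \code{\link{bold_series}}.
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.01 and 0.1);
#'   \code{high_hz} must be below the Nyquist frequency \code{1/(2 TR)}.
#' @return the filtered \code{bold_series}.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1) {
  t <- n_volumes(series)
  nyq <- 1 / (2 * series$tr_seconds)
  if (low_hz >= high_hz) stop("'low_hz' must be below 'high_hz'")
  if (high_hz >= nyq)
    stop(sprintf("'high_hz' (%g Hz) must be below Nyquist (%g Hz)",
                 high_hz, nyq))
  freq <- dft_freq(t, series$tr_seconds)
  pass <- freq >= low_hz & freq <= high_hz
  d <- dim(series$data)
  Y <- t(matrix(series$data, prod(d[1:3]), t))  # t x V
  F <- stats::mvfft(Y)
  F[!pass, ] <- 0
  out <- Re(stats::mvfft(F, inverse = TRUE)) / t
  series$data <- array(t(out), d)
  series
}

# Internal: absolute frequency (Hz) of each DFT bin of an n-point series.
dft_freq <- function(n, tr_seconds) {
  k <- 0:(n - 1)
  k <- pmin(k, n - k)           # fold negative frequencies
  k / (n * tr_seconds)
}
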