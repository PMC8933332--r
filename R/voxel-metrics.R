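#' Construct a metric map
#'
#' 3D map of one voxel-wise resting-state metric. Voxels outside the brain
#' mask, and voxels flagged as unusable (zero-variance series, isolated
#' voxels), carry \code{NA} as an explicit sentinel so they can never be
#' confused with a true zero.
#'
#' @param values 3D numeric array; \code{NA} outside the mask.
#' @param metric_name one of \code{"ALFF"}, \code{"fALFF"}, \code{"ReHo"},
#'   \code{"DC"}.
#' @param standardized has \code{\link{zscore_map}} been applied?
#' @param smoothed_fwhm_mm FWHM (mm) of smoothing already applied (0 = none).
#' @return object of class \code{metric_map}.
#' @export
metric_map <- function(values, metric_name,
                       standardized = FALSE, smoothed_fwhm_mm = 0) {
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  metric_name <- match.arg(metric_name, c("ALFF", "fALFF", "ReHo", "DC"))
  structure(list(values = values, metric_name = metric_name,
                 standardized = standardized,
                 smoothed_fwhm_mm = smoothed_fwhm_mm),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map> %s, %s grid, %d in-mask voxels%s%s\n",
              x$metric_name, paste(dim(x$values), collapse = "x"),
              sum(!is.na(x$values)),
              if (x$standardized) ", z-scored" else "",
              if (x$smoothed_fwhm_mm > 0)
                sprintf(", smoothed %gmm" , x$smoothed_fwhm_mm) else ""))
  invisible(x)
}

# Internal: one-sided amplitude spectrum of each column of the t x V matrix.
# Scaling 2/t makes a pure on-bin tone's single-bin amplitude equal its
# sinusoid amplitude. Returns list(amp = bins x V, freq = Hz per bin) over
# positive frequencies up to Nyquist.
amplitude_spectrum <- function(X, tr_seconds) {
  n <- nrow(X)
  X <- sweep(X, 2, colMeans(X))
  F <- stats::mvfft(X)
  kmax <- floor(n / 2)
  amp <- 2 * Mod(F[2:(kmax + 1), , drop = FALSE]) / n
  list(amp = amp, freq = (1:kmax) / (n * tr_seconds))
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel: demean, discrete Fourier transform, and sum of one-sided
#' spectral amplitudes over bins falling in \code{[low_hz, high_hz]}.
#' Computed on the nuisance-regressed, unfiltered series (band-pass
#' filtering would make it trivial).
#'
#' @param series a \code{\link{bold_series}}, not band-passed, >= 32 frames.
#' @param mask 3D logical brain mask.
#' @param low_hz,high_hz band edges in Hz (defaults 0.01, 0.1).
#' @return a \code{\link{metric_map}} ("ALFF").
#' @export
alff <- function(series, mask, low_hz = 0.01, high_hz = 0.1) {
  if (n_volumes(series) < 32L)
    stop("ALFF needs at least 32 kept frames")
  sp <- amplitude_spectrum(series_matrix(series, mask), series$tr_seconds)
  band <- sp$freq >= low_hz & sp$freq <= high_hz
  if (!any(band))
    stop(sprintf(
      "no DFT bin falls in [%g, %g] Hz: bin spacing is %g Hz for %d frames at TR %gs",
      low_hz, high_hz, sp$freq[1], n_volumes(series), series$tr_seconds))
  metric_map(map_array(colSums(sp$amp[band, , drop = FALSE]), mask), "ALFF")
}

#' Fractional ALFF (fALFF)
#'
#' In-band amplitude sum divided by the amplitude sum over the entire
#' measurable range (all positive-frequency bins up to Nyquist; the zero bin
#' is removed by demeaning). Dimensionless, in [0, 1]. Voxels with zero
#' total power get the \code{NA} sentinel.
#'
#' @inheritParams alff
#' @return a \code{\link{metric_map}} ("fALFF").
#' @export
falff <- function(series, mask, low_hz = 0.01, high_hz = 0.1) {
  if (n_volumes(series) < 32L)
    stop("fALFF needs at least 32 kept frames")
  sp <- amplitude_spectrum(series_matrix(series, mask), series$tr_seconds)
  band <- sp$freq >= low_hz & sp$freq <= high_hz
  if (!any(band))
    stop("no DFT bin falls in the requested band")
  total <- colSums(sp$amp)
  inband <- colSums(sp$amp[band, , drop = FALSE])
  vals <- ifelse(total > 0, inband / total, NA_real_)
  if (anyNA(vals))
    warning(sum(is.na(vals)), " voxel(s) with zero total power flagged NA")
  metric_map(map_array(vals, mask), "fALFF")
}

# Neighborhood offset tables: 7 = faces, 19 = + edges, 27 = full cube.
neighborhood_offsets <- function(neighborhood) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d2 <- rowSums(g^2)
  keep <- switch(as.character(neighborhood),
                 "7"  = d2 <= 1,
                 "19" = d2 <= 2,
                 "27" = d2 <= 3,
                 stop("'neighborhood' must be 7, 19 or 27"))
  g[keep, , drop = FALSE]
}

#' Regional homogeneity (ReHo)
#'
#' Kendall's coefficient of concordance (W) between each voxel's band-passed
#' time course and those of its in-mask neighbors (26 neighbors for the
#' default 27-voxel cube). With K series of n frames, each ranked over time,
#' \deqn{W = 12 S / (K^2 (n^3 - n)), \quad
#'       S = \sum_t (R_t - K(n+1)/2)^2,}
#' where \eqn{R_t} is the cross-series rank sum at frame t. Ties get average
#' ranks; no tie-correction term is applied in the denominator (exact ties
#' have measure zero in band-passed real-valued data). At mask edges only
#' in-mask neighbors enter (K < 27 allowed); voxels with fewer than 2
#' members get the \code{NA} sentinel.
#'
#' @param series a band-passed \code{\link{bold_series}}.
#' @param mask 3D logical brain mask.
#' @param neighborhood cluster size: 7, 19 or 27 (default).
#' @return a \code{\link{metric_map}} ("ReHo") with values in (0, 1].
#' @export
reho <- function(series, mask, neighborhood = 27) {
  offs <- neighborhood_offsets(neighborhood)
  X <- series_matrix(series, mask)
  n <- nrow(X)
  V <- ncol(X)
  R <- apply(X, 2, rank)                       # time-ranks per voxel
  dims <- dim(mask)
  idx <- which(mask)
  pos <- arrayInd(idx, dims)
  vox_id <- array(0L, dims)
  vox_id[idx] <- seq_along(idx)
  Rsum <- matrix(0, n, V)
  K <- integer(V)
  for (i in seq_len(nrow(offs))) {
    npos <- sweep(pos, 2, offs[i, ], "+")
    ok <- npos[, 1] >= 1 & npos[, 1] <= dims[1] &
          npos[, 2] >= 1 & npos[, 2] <= dims[2] &
          npos[, 3] >= 1 & npos[, 3] <= dims[3]
    nid <- integer(V)
    nid[ok] <- vox_id[npos[ok, , drop = FALSE]]
    sel <- which(nid > 0L)
    if (length(sel)) {
      Rsum[, sel] <- Rsum[, sel] + R[, nid[sel]]
      K[sel] <- K[sel] + 1L
    }
  }
  S <- colSums((Rsum - rep(K * (n + 1) / 2, each = n))^2)
  W <- 12 * S / (K^2 * (n^3 - n))
  W[K < 2L] <- NA_real_
  if (any(K < 2L))
    warning(sum(K < 2L), " isolated voxel(s) flagged NA")
  metric_map(map_array(W, mask), "ReHo")
}

#' Degree centrality (DC)
#'
#' For each in-mask voxel, the number of other in-mask voxels whose Pearson
#' correlation with it exceeds \code{r_threshold} (strict inequality; the
#' self-correlation is excluded). Zero-variance voxels contribute
#' correlation 0 everywhere and are flagged with the \code{NA} sentinel.
#'
#' The conventional joint criterion "r > .25 and p <= .001" reduces to the
#' r-threshold alone for the frame counts this package targets (at 230+
#' frames, r > 0.25 implies p well below 0.001); set
#' \code{p_threshold} to also require significance at short series lengths.
#'
#' @param series a band-passed \code{\link{bold_series}}.
#' @param mask 3D logical mask (gray matter or whole brain).
#' @param r_threshold correlation threshold (default 0.25).
#' @param p_threshold optional; if non-NULL the effective threshold is the
#'   larger of \code{r_threshold} and the two-sided critical r at this p.
#' @return a \code{\link{metric_map}} ("DC") of nonnegative integer counts.
#' @export
dc <- function(series, mask, r_threshold = 0.25, p_threshold = NULL) {
  X <- series_matrix(series, mask)
  n <- nrow(X)
  if (n < 10L) stop("DC needs at least 10 kept frames")
  if (ncol(X) < 2L) stop("DC needs at least 2 in-mask voxels")
  thr <- r_threshold
  if (!is.null(p_threshold)) {
    tcrit <- stats::qt(1 - p_threshold / 2, df = n - 2)
    thr <- max(thr, tcrit / sqrt(n - 2 + tcrit^2))
  }
  sds <- apply(X, 2, stats::sd)
  bad <- sds == 0
  Xs <- sweep(X, 2, colMeans(X))
  denom <- sqrt(colSums(Xs^2))
  denom[bad] <- 1
  Xs <- sweep(Xs, 2, denom, "/")
  Xs[, bad] <- 0                      # zero-variance: correlations become 0
  C <- crossprod(Xs)                  # correlation matrix (diag 1 for good)
  counts <- colSums(C > thr)
  counts[!bad] <- counts[!bad] - 1L   # remove self-correlation
  counts[bad] <- NA_real_
  if (any(bad))
    warning(sum(bad), " zero-variance voxel(s) flagged NA")
  metric_map(map_array(counts, mask), "DC")
}

#' Z-score standardization of a metric map
#'
#' Subtracts the whole-brain (in-mask) mean and divides by the whole-brain
#' SD, leaving sentinel voxels untouched. Makes maps comparable across
#' sessions and subjects before concordance analysis.
#'
#' @param map a \code{\link{metric_map}}.
#' @param mask 3D logical brain mask.
#' @return the standardized \code{metric_map} (\code{standardized = TRUE}).
#' @export
zscore_map <- function(map, mask) {
  v <- map$values[mask]
  v <- v[!is.na(v)]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant map")
  map$values <- (map$values - mean(v)) / s
  map$standardized <- TRUE
  map
}

#' Smoothing kernel specification
#'
#' @param fwhm_mm Gaussian full width at half maximum in mm (default 3).
#' @param voxel_size_mm length-3 positive numeric, voxel edges in mm.
#' @return object of class \code{smoothing_spec}.
#' @export
smoothing_spec <- function(fwhm_mm = 3, voxel_size_mm = c(3, 3, 3)) {
  if (fwhm_mm <= 0) stop("'fwhm_mm' must be positive")
  if (fwhm_mm / min(voxel_size_mm) < 0.5)
    stop("FWHM below half the smallest voxel edge is not resolvable")
  structure(list(fwhm_mm = fwhm_mm, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "smoothing_spec")
}

# Internal: shift a 3D array by s along one axis, zero-filling.
shift_axis <- function(a, s, axis) {
  if (s == 0) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  ix <- function(which_axis, i) if (which_axis == axis) i else TRUE
  out[ix(1, dst), ix(2, dst), ix(3, dst)] <-
    a[ix(1, src), ix(2, src), ix(3, src)]
  out
}

#' Gaussian spatial smoothing within a mask
#'
#' Separable Gaussian convolution with per-axis
#' \eqn{\sigma = FWHM / (voxel\_size \cdot 2\sqrt{2\ln 2})} voxels.
#' The kernel is renormalized over the mask (out-of-mask voxels carry no
#' weight), so constant fields are preserved exactly and in-mask mass is
#' conserved for maps supported away from the mask edge.
#'
#' @param map a \code{\link{metric_map}}.
#' @param spec a \code{\link{smoothing_spec}}.
#' @param mask 3D logical brain mask.
#' @return the smoothed \code{metric_map}.
#' @export
smooth_map <- function(map, spec, mask) {
  sigma_vox <- spec$fwhm_mm / (spec$voxel_size_mm * 2 * sqrt(2 * log(2)))
  vals <- map$values
  finite_mask <- mask & !is.na(vals)
  num <- ifelse(finite_mask, vals, 0)
  den <- ifelse(finite_mask, 1, 0)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    num_new <- array(0, dim(vals))
    den_new <- array(0, dim(vals))
    for (i in seq_along(k)) {
      sh <- i - 1L - r
      num_new <- num_new + k[i] * shift_axis(num, sh, axis)
      den_new <- den_new + k[i] * shift_axis(den, sh, axis)
    }
    num <- num_new
    den <- den_new
  }
  out <- array(NA_real_, dim(vals))
  ok <- finite_mask & den > 0
  out[ok] <- num[ok] / den[ok]
  map$values <- out
  map$smoothed_fwhm_mm <- spec$fwhm_mm
  map
}
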