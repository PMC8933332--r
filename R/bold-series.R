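#' Construct a BOLD time-series object
#'
#' Container for one subject-session 4D resting-state acquisition: a
#' \code{x * y * z * t} numeric array plus its sampling interval (TR) and
#' opaque spatial metadata. All temporal operations in the package
#' (\code{\link{drop_initial_volumes}}, \code{\link{nuisance_regress}},
#' \code{\link{scrub}}, \code{\link{bandpass}}) consume and return this type.
#'
#' @param data 4D numeric array (x, y, z, t) of BOLD intensities, t >= 2.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param spatial_meta optional affine/orientation record, carried opaquely
#'   (e.g. an \code{RNifti} image header); never interpreted by this package.
#' @return An object of class \code{bold_series} with fields \code{data},
#'   \code{tr_seconds}, \code{voxel_size_mm}, \code{spatial_meta} and
#'   \code{volume_kept} (logical per volume, all \code{TRUE} at construction).
#' @export
bold_series <- function(data, tr_seconds, voxel_size_mm = c(3, 3, 3),
                        spatial_meta = NULL) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("a bold_series needs at least 2 volumes")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("'tr_seconds' must be a single positive number")
  if (any(!is.finite(data)))
    stop("'data' contains non-finite values")
  structure(
    list(data = data, tr_seconds = tr_seconds,
         voxel_size_mm = as.numeric(voxel_size_mm),
         spatial_meta = spatial_meta,
         volume_kept = rep(TRUE, dim(data)[4])),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d grid, %d volumes, TR = %gs (%d kept)\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$volume_kept)))
  invisible(x)
}

#' Number of volumes in a BOLD series
#' @param series a \code{\link{bold_series}}.
#' @return integer number of time points currently in the series.
#' @export
n_volumes <- function(series) dim(series$data)[4]

# Internal: t x V matrix of in-mask voxel time courses, column order =
# which(mask) linear order. Used by every voxel-wise metric.
series_matrix <- function(series, mask) {
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  t(m[as.vector(mask), , drop = FALSE])
}

# Internal: scatter a per-in-mask-voxel vector back into a 3D array,
# NA (the sentinel) outside the mask.
map_array <- function(values, mask) {
  out <- array(NA_real_, dim(mask))
  out[mask] <- values
  out
}
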