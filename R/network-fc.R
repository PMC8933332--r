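#' Construct a triple-network ROI atlas
#'
#' Fifteen named region masks partitioned into the three core resting-state
#' networks: default mode (DMN, 4 ROIs), central executive (CEN, 4 ROIs) and
#' salience (SN, 7 ROIs). The atlas is an input: any set of 15 binary masks
#' with these network counts is accepted (the synthetic generator ships a
#' desk-scale default).
#'
#' @param rois list of 15 entries, each a list with \code{name} (character),
#'   \code{network} (one of "DMN", "CEN", "SN") and \code{mask} (3D logical).
#' @param brain_mask optional 3D logical; if given, every ROI must be
#'   nonempty within it.
#' @return object of class \code{network_atlas}.
#' @export
network_atlas <- function(rois, brain_mask = NULL) {
  if (length(rois) != 15L) stop("a triple-network atlas has exactly 15 ROIs")
  networks <- vapply(rois, `[[`, "", "network")
  if (!all(networks %in% c("DMN", "CEN", "SN")))
    stop("ROI networks must be DMN, CEN or SN")
  counts <- table(factor(networks, levels = c("DMN", "CEN", "SN")))
  if (counts[["DMN"]] != 4L || counts[["CEN"]] != 4L || counts[["SN"]] != 7L)
    stop("network sizes must be DMN=4, CEN=4, SN=7 (got ",
         paste(counts, collapse = "/"), ")")
  for (r in rois) {
    m <- r$mask
    if (!is.null(brain_mask)) m <- m & brain_mask
    if (!any(m)) stop("ROI '", r$name, "' is empty within the brain mask")
  }
  structure(list(rois = rois,
                 names = vapply(rois, `[[`, "", "name"),
                 networks = networks),
            class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  cat("<network_atlas> 15 ROIs:",
      paste(sprintf("%s(%s)", x$names, x$networks), collapse = ", "), "\n")
  invisible(x)
}

#' Union mask of one network's ROIs
#' @param atlas a \code{\link{network_atlas}}.
#' @param network "DMN", "CEN" or "SN".
#' @return 3D logical mask.
#' @export
network_mask <- function(atlas, network) {
  sel <- which(atlas$networks == network)
  if (!length(sel)) stop("unknown network label: ", network)
  Reduce(`|`, lapply(atlas$rois[sel], `[[`, "mask"))
}

#' Mean BOLD time series of each atlas ROI
#'
#' Unweighted voxel mean at each kept frame, in atlas order.
#'
#' @param series a preprocessed (band-passed) \code{\link{bold_series}}.
#' @param atlas a \code{\link{network_atlas}}.
#' @param brain_mask optional 3D logical mask intersected with each ROI.
#' @return t x 15 numeric matrix, columns named by ROI.
#' @export
roi_mean_series <- function(series, atlas, brain_mask = NULL) {
  out <- vapply(atlas$rois, function(r) {
    m <- r$mask
    if (!is.null(brain_mask)) m <- m & brain_mask
    if (!any(m)) stop("ROI '", r$name, "' is empty within the brain mask")
    rowMeans(series_matrix(series, m))
  }, numeric(n_volumes(series)))
  colnames(out) <- atlas$names
  out
}

#' ROI-pair functional connectivity matrix
#'
#' Pearson correlation between every pair of ROI mean time series, with the
#' Fisher r-to-z transform (\code{atanh}) applied off-diagonal. Degenerate
#' r = +/-1 is clipped to 1 - 1e-12 in magnitude before the transform so z
#' stays finite.
#'
#' @param roi_series t x 15 matrix from \code{\link{roi_mean_series}}.
#' @param networks character vector of length 15 giving each ROI's network
#'   (carried along for \code{\link{internetwork_block}}).
#' @return object of class \code{fc_matrix}: fields \code{r} (15 x 15,
#'   unit diagonal), \code{z} (diagonal \code{NA}), \code{roi_order},
#'   \code{networks}.
#' @export
fc_matrix <- function(roi_series, networks = NULL) {
  if (nrow(roi_series) < 10L) stop("need at least 10 frames for FC")
  sds <- apply(roi_series, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI series: ",
         paste(colnames(roi_series)[sds == 0], collapse = ", "))
  r <- stats::cor(roi_series)
  rc <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(rc)
  diag(z) <- NA_real_
  diag(r) <- 1
  structure(list(r = r, z = z, roi_order = colnames(roi_series),
                 networks = networks),
            class = "fc_matrix")
}

#' Vectorized internetwork connectivity block
#'
#' Extracts the Fisher-z cross-block between two different networks,
#' flattened in fixed row-major atlas order (rows = first network's ROIs,
#' columns = second network's). Block lengths for the 4/4/7 atlas:
#' DMN x CEN = 16, DMN x SN = 28, CEN x SN = 28.
#'
#' @param fc an \code{fc_matrix} built with \code{networks} set.
#' @param net_a,net_b distinct network labels.
#' @param use_z return Fisher-z values (default) or raw r.
#' @return numeric vector of cross-network connectivity values.
#' @export
internetwork_block <- function(fc, net_a, net_b, use_z = TRUE) {
  if (is.null(fc$networks))
    stop("fc_matrix was built without network labels")
  if (identical(net_a, net_b)) stop("'net_a' and 'net_b' must differ")
  ia <- which(fc$networks == net_a)
  ib <- which(fc$networks == net_b)
  if (!length(ia)) stop("unknown network label: ", net_a)
  if (!length(ib)) stop("unknown network label: ", net_b)
  m <- if (use_z) fc$z else fc$r
  as.vector(t(m[ia, ib, drop = FALSE]))  # row-major
}
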