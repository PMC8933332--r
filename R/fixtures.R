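# Reference per-subject stability tables from a published two-session
# (1-week interval) 7T resting-state study of 16 subjects: voxel-based CCC
# of each metric in each network, and Spearman stability of each network
# pair. Packaged verbatim as regression fixtures for the aggregation and
# labeling code; the raw imaging data behind them is not required anywhere.

#' Reference per-subject CCC stability table
#'
#' Published voxel-based concordance correlation coefficients (one value per
#' subject, network and metric; 16 subjects x 12 columns) from a
#' two-session resting-state study, shipped as a regression fixture for
#' \code{\link{aggregate_stability}}.
#'
#' @return data.frame with columns \code{subject_id}, then
#'   \code{<network>_<metric>} for network in DMN/CEN/SN and metric in
#'   ALFF/fALFF/ReHo/DC.
#' @export
reference_ccc_table <- function() {
  vals <- rbind(
    c(0.72, 0.19, 0.77, 0.40,  0.75, 0.02, 0.75, 0.25,  0.74, -0.20, 0.70, 0.24),
    c(0.93, 0.76, 0.87, 0.75,  0.88, 0.69, 0.88, 0.73,  0.92,  0.67, 0.89, 0.81),
    c(0.84, 0.44, 0.64, 0.47,  0.69, 0.44, 0.56, 0.62,  0.87,  0.35, 0.76, 0.78),
    c(0.93, 0.80, 0.92, 0.74,  0.85, 0.62, 0.89, 0.80,  0.91,  0.66, 0.88, 0.84),
    c(0.76, 0.74, 0.93, 0.87,  0.83, 0.52, 0.84, 0.80,  0.76,  0.41, 0.84, 0.81),
    c(0.96, 0.70, 0.90, 0.61,  0.90, 0.51, 0.84, 0.65,  0.93,  0.37, 0.85, 0.67),
    c(0.90, 0.61, 0.84, 0.76,  0.85, 0.56, 0.82, 0.77,  0.90,  0.41, 0.79, 0.64),
    c(0.93, 0.62, 0.81, 0.71,  0.90, 0.50, 0.73, 0.70,  0.95,  0.46, 0.79, 0.64),
    c(0.96, 0.85, 0.91, 0.89,  0.94, 0.90, 0.94, 0.90,  0.92,  0.75, 0.84, 0.90),
    c(0.93, 0.75, 0.92, 0.83,  0.92, 0.63, 0.90, 0.71,  0.95,  0.58, 0.81, 0.67),
    c(0.95, 0.75, 0.91, 0.76,  0.95, 0.76, 0.93, 0.77,  0.92,  0.69, 0.86, 0.78),
    c(0.89, 0.59, 0.89, 0.75,  0.87, 0.61, 0.91, 0.67,  0.90,  0.59, 0.87, 0.78),
    c(0.93, 0.73, 0.92, 0.71,  0.93, 0.69, 0.87, 0.71,  0.89,  0.73, 0.83, 0.66),
    c(0.91, 0.72, 0.91, 0.72,  0.81, 0.72, 0.80, 0.73,  0.90,  0.75, 0.69, 0.87),
    c(0.91, 0.60, 0.74, 0.32,  0.92, 0.73, 0.83, 0.63,  0.95,  0.83, 0.91, 0.72),
    c(0.95, 0.68, 0.93, 0.88,  0.91, 0.64, 0.89, 0.88,  0.95,  0.61, 0.91, 0.92))
  cols <- as.vector(outer(c("ALFF", "fALFF", "ReHo", "DC"),
                          c("DMN", "CEN", "SN"),
                          function(m, n) paste(n, m, sep = "_")))
  out <- data.frame(subject_id = sprintf("Sub%02d", 1:16), vals,
                    stringsAsFactors = FALSE)
  names(out) <- c("subject_id", cols)
  out
}

#' Reference per-subject internetwork stability table
#'
#' Published Spearman coefficients for the stability of each network-pair
#' connectivity block across two sessions (16 subjects x 3 pairs), shipped
#' as a regression fixture. All were reported significant after FDR
#' correction (p < .01).
#'
#' @return data.frame with columns \code{subject_id}, \code{DMN_SN},
#'   \code{DMN_CEN}, \code{SN_CEN}.
#' @export
reference_internetwork_table <- function() {
  vals <- rbind(
    c(0.58, 0.71, 0.69), c(0.47, 0.61, 0.61), c(0.59, 0.53, 0.60),
    c(0.63, 0.76, 0.80), c(0.81, 0.79, 0.74), c(0.56, 0.12, 0.80),
    c(0.71, 0.69, 0.72), c(0.61, 0.82, 0.91), c(0.80, 0.60, 0.68),
    c(0.85, 0.69, 0.89), c(0.94, 0.94, 0.91), c(0.61, 0.59, 0.90),
    c(0.87, 0.41, 0.67), c(0.84, 0.78, 0.90), c(0.36, 0.34, 0.71),
    c(0.85, 0.60, 0.85))
  out <- data.frame(subject_id = sprintf("Sub%02d", 1:16), vals,
                    stringsAsFactors = FALSE)
  names(out) <- c("subject_id", "DMN_SN", "DMN_CEN", "SN_CEN")
  out
}

#' Packaged reference stability tables
#'
#' Convenience wrapper returning both reference tables, wide and in tidy
#' long form ready for \code{\link{aggregate_stability}}.
#'
#' @return list with elements \code{ccc} (16 x 13 wide), \code{internetwork}
#'   (16 x 4 wide), \code{ccc_long} and \code{internetwork_long} (tidy
#'   \code{\link{stability_record}} tables).
#' @export
generate_fixture_tables <- function() {
  ccc_wide <- reference_ccc_table()
  inter_wide <- reference_internetwork_table()
  long1 <- do.call(rbind, lapply(names(ccc_wide)[-1], function(col) {
    parts <- strsplit(col, "_", fixed = TRUE)[[1]]
    stability_record(ccc_wide$subject_id, parts[1], parts[2], ccc_wide[[col]])
  }))
  long2 <- do.call(rbind, lapply(names(inter_wide)[-1], function(col) {
    pair <- sub("_", "/", col, fixed = TRUE)
    stability_record(inter_wide$subject_id, pair, pair, inter_wide[[col]])
  }))
  list(ccc = ccc_wide, internetwork = inter_wide,
       ccc_long = long1, internetwork_long = long2)
}
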