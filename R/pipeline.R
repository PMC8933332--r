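#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. Exactly one of
#' \code{synthetic} (a \code{\link{synthetic_spec}}) or \code{manifest}
#' (path to an on-disk dataset written by \code{\link{write_dataset}}, or
#' any directory with the same layout) must be given.
#'
#' @param synthetic a \code{\link{synthetic_spec}}, or NULL.
#' @param manifest dataset directory path, or NULL.
#' @param n_drop leading volumes to discard (default 10).
#' @param low_hz,high_hz analysis band in Hz (defaults 0.01, 0.1).
#' @param fd_threshold_mm scrubbing threshold (default 0.2).
#' @param head_radius_mm rotation-to-mm conversion radius for FD
#'   (default 50).
#' @param trans_limit_mm,rot_limit_deg gross-motion exclusion limits
#'   (defaults 1.5 mm / 1.5 degrees).
#' @param dc_r_threshold degree-centrality correlation threshold
#'   (default 0.25).
#' @param dc_p_threshold optional joint significance threshold for DC.
#' @param fwhm_mm smoothing kernel FWHM (default 3).
#' @param base_alpha family-wise level for the Bonferroni-adjusted CCC CI
#'   (default 0.05).
#' @param q_fdr FDR level for internetwork Spearman stability
#'   (default 0.01).
#' @param scrub_spectral compute ALFF/fALFF on the scrubbed, concatenated
#'   series (TRUE) instead of the unscrubbed residual series (default
#'   FALSE). Amplitude metrics require regular sampling: concatenating
#'   across scrubbed gaps breaks sinusoid phase continuity and leaks
#'   session-specific energy across frequency bins, so by default scrubbing
#'   is applied only on the correlation branch (ReHo, DC, ROI FC), where
#'   frame deletion is well defined.
#' @param ccc_on_smoothed run the voxel CCC on smoothed standardized maps
#'   (default TRUE) or on standardized-only maps.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(synthetic = NULL, manifest = NULL,
                       n_drop = 10L, low_hz = 0.01, high_hz = 0.1,
                       fd_threshold_mm = 0.2, head_radius_mm = 50,
                       trans_limit_mm = 1.5, rot_limit_deg = 1.5,
                       dc_r_threshold = 0.25, dc_p_threshold = NULL,
                       fwhm_mm = 3, base_alpha = 0.05, q_fdr = 0.01,
                       scrub_spectral = FALSE, ccc_on_smoothed = TRUE) {
  if (is.null(synthetic) == is.null(manifest))
    stop("exactly one of 'synthetic' or 'manifest' must be given")
  stopifnot(fd_threshold_mm > 0, fwhm_mm > 0, dc_r_threshold > 0,
            base_alpha > 0, q_fdr > 0, low_hz > 0, high_hz > low_hz)
  structure(list(synthetic = synthetic, manifest = manifest,
                 n_drop = as.integer(n_drop), low_hz = low_hz,
                 high_hz = high_hz, fd_threshold_mm = fd_threshold_mm,
                 head_radius_mm = head_radius_mm,
                 trans_limit_mm = trans_limit_mm,
                 rot_limit_deg = rot_limit_deg,
                 dc_r_threshold = dc_r_threshold,
                 dc_p_threshold = dc_p_threshold, fwhm_mm = fwhm_mm,
                 base_alpha = base_alpha, q_fdr = q_fdr,
                 scrub_spectral = scrub_spectral,
                 ccc_on_smoothed = ccc_on_smoothed),
            class = "run_config")
}

network_pairs <- function() {
  list(c("DMN", "SN"), c("DMN", "CEN"), c("CEN", "SN"))
}

metric_names <- function() c("ALFF", "fALFF", "ReHo", "DC")

# Internal: full temporal-preprocessing + metric chain for one session.
# Returns the four standardized (and optionally smoothed) metric maps, the
# FC matrix and the retained frame fraction.
process_session <- function(series, motion, masks, atlas, config) {
  brain <- masks$brain
  series <- drop_initial_volumes(series, config$n_drop)
  if (config$n_drop > 0L) {
    motion <- motion_table(
      motion$translations[-seq_len(config$n_drop), , drop = FALSE],
      motion$rotations[-seq_len(config$n_drop), , drop = FALSE])
  }
  X24 <- build_friston24(motion)
  wm_mean <- rowMeans(series_matrix(series, masks$wm))
  csf_mean <- rowMeans(series_matrix(series, masks$csf))
  series <- nuisance_regress(series, cbind(X24, wm = wm_mean,
                                           csf = csf_mean))
  fd <- compute_fd(motion, config$head_radius_mm, config$fd_threshold_mm)
  scrubbed <- scrub(series, fd)
  spectral <- if (config$scrub_spectral) scrubbed else series

  maps <- list(
    ALFF = alff(spectral, brain, config$low_hz, config$high_hz),
    fALFF = falff(spectral, brain, config$low_hz, config$high_hz))
  bp <- bandpass(scrubbed, config$low_hz, config$high_hz)
  maps$ReHo <- reho(bp, brain)
  maps$DC <- dc(bp, brain, config$dc_r_threshold, config$dc_p_threshold)

  sspec <- smoothing_spec(config$fwhm_mm, series$voxel_size_mm)
  maps <- lapply(maps, function(m) {
    m <- zscore_map(m, brain)
    if (config$ccc_on_smoothed) m <- smooth_map(m, sspec, brain)
    m
  })
  fcm <- fc_matrix(roi_mean_series(bp, atlas, brain), atlas$networks)
  list(maps = maps, fc = fcm,
       retained_fraction = attr(scrubbed, "retained_fraction"))
}

#' Run the full stability pipeline
#'
#' Executes, for every subject and session: initial-volume removal,
#' Friston-24 + WM/CSF nuisance regression, FD computation and scrubbing,
#' the four voxel-wise metrics (ALFF/fALFF on the unfiltered residual
#' branch; ReHo/DC and ROI connectivity on the 0.01-0.1 Hz branch),
#' z-scoring and smoothing; then per subject the voxel-based CCC of each
#' metric in each network and the Spearman stability of each internetwork
#' block, with Bonferroni-adjusted CCC confidence intervals and FDR
#' correction of the Spearman p-values; finally group aggregation.
#'
#' Subjects failing the gross-motion screen in either session are excluded
#' (and listed in the report); the run aborts only if every subject fails.
#'
#' @param config a \code{\link{run_config}}.
#' @param dataset optionally, an already-generated/loaded dataset (as
#'   returned by \code{\link{generate_dataset}} or
#'   \code{\link{read_dataset}}); by default it is produced from the
#'   config.
#' @param verbose emit per-subject progress messages.
#' @return object of class \code{study_report}: \code{ccc_records} and
#'   \code{spearman_records} data.frames, \code{aggregates} (list
#'   \code{ccc}, \code{internetwork}), \code{excluded_subjects},
#'   \code{retained_fractions}, \code{alpha}, and a \code{provenance} list
#'   (config, seed, package version).
#' @export
run_pipeline <- function(config, dataset = NULL, verbose = FALSE) {
  if (is.null(dataset)) {
    dataset <- if (!is.null(config$synthetic)) generate_dataset(config$synthetic)
               else read_dataset(config$manifest)
  }
  subjects <- dataset$subjects
  atlas <- dataset$atlas
  masks <- dataset$masks

  screened <- vapply(subjects, function(su) {
    all(vapply(1:2, function(ses) {
      m <- su[[paste0("motion", ses)]]
      screen_gross_motion(m, config$trans_limit_mm,
                          config$rot_limit_deg)$pass
    }, logical(1)))
  }, logical(1))
  excluded <- names(subjects)[!screened]
  if (length(excluded) && verbose)
    message("excluded for gross motion: ", paste(excluded, collapse = ", "))
  subjects <- subjects[screened]
  if (!length(subjects)) stop("every subject failed the gross-motion screen")

  n_sub <- length(subjects)
  alpha <- bonferroni_alpha(config$base_alpha,
                            n_sub * length(metric_names()) *
                              length(unique(atlas$networks)))

  ccc_rows <- list()
  sp_rows <- list()
  retained <- list()
  net_masks <- lapply(stats::setNames(nm = unique(atlas$networks)),
                      function(nw) network_mask(atlas, nw))
  for (id in names(subjects)) {
    su <- subjects[[id]]
    if (verbose) message("processing ", id)
    s1 <- process_session(su$session1, su$motion1, masks, atlas, config)
    s2 <- process_session(su$session2, su$motion2, masks, atlas, config)
    retained[[id]] <- c(session1 = s1$retained_fraction,
                        session2 = s2$retained_fraction)
    for (nw in names(net_masks)) {
      for (mt in metric_names()) {
        cr <- voxel_ccc(s1$maps[[mt]], s2$maps[[mt]], net_masks[[nw]],
                        alpha = alpha)
        ccc_rows[[length(ccc_rows) + 1L]] <- data.frame(
          subject_id = id, unit = nw, measure = mt,
          estimate = cr$rho_c, precision_rho = cr$precision_rho,
          accuracy_chi = cr$accuracy_chi, n_voxels = cr$n,
          ci_low = cr$ci_low, ci_high = cr$ci_high,
          corrected = is.finite(cr$ci_low) && cr$ci_low > 0,
          label = label_strength(cr$rho_c), stringsAsFactors = FALSE)
      }
    }
    for (pr in network_pairs()) {
      pair <- paste(pr, collapse = "/")
      b1 <- internetwork_block(s1$fc, pr[1], pr[2])
      b2 <- internetwork_block(s2$fc, pr[1], pr[2])
      sp <- spearman_stability(b1, b2)
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        subject_id = id, unit = pair, measure = pair,
        estimate = sp$rho, p_value = sp$p,
        label = label_strength(sp$rho), stringsAsFactors = FALSE)
    }
  }
  ccc_records <- do.call(rbind, ccc_rows)
  sp_records <- do.call(rbind, sp_rows)
  fdr <- fdr_correct(sp_records$p_value, config$q_fdr)
  sp_records$p_adjusted <- fdr$p_adjusted
  sp_records$corrected <- fdr$rejected

  report <- list(
    ccc_records = ccc_records,
    spearman_records = sp_records,
    aggregates = list(ccc = aggregate_stability(ccc_records),
                      internetwork = aggregate_stability(sp_records)),
    excluded_subjects = excluded,
    retained_fractions = retained,
    alpha = alpha,
    provenance = list(
      config = config,
      seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
      package_version = as.character(utils::packageVersion("netstab"))))
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects, %d CCC records, %d internetwork records\n",
              length(unique(x$ccc_records$subject_id)),
              nrow(x$ccc_records), nrow(x$spearman_records)))
  if (length(x$excluded_subjects))
    cat("  excluded:", paste(x$excluded_subjects, collapse = ", "), "\n")
  cat("  network-level mean CCC:\n")
  ag <- x$aggregates$ccc
  print(data.frame(ag[c("unit", "measure")], mean = round(ag$mean, 2),
                   sd = round(ag$sd, 2)), row.names = FALSE)
  invisible(x)
}
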