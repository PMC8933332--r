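#' Write a dataset to disk in standard formats
#'
#' Lays out a generated (or loaded) dataset as NIfTI-1 volumes plus plain
#' text: one 4D \code{.nii.gz} per subject/session, 3D mask volumes, a
#' whitespace-delimited 6-column motion file per session (translations mm,
#' rotations radians), a tab-separated atlas manifest (ROI name, network,
#' center voxel, radius), a top-level \code{manifest.tsv} and
#' \code{dataset.json} (TR, voxel size, grid), and the ground truth as
#' structured JSON.
#'
#' @param dataset as returned by \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  spec <- dataset$spec
  vox <- if (!is.null(spec)) spec$voxel_size_mm else
    dataset$subjects[[1]]$session1$voxel_size_mm
  tr <- dataset$subjects[[1]]$session1$tr_seconds

  write_nii <- function(arr, path, time_step = NULL) {
    img <- RNifti::asNifti(arr)
    pd <- if (is.null(time_step)) vox else c(vox, time_step)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path)
  }
  for (m in c("brain", "wm", "csf"))
    write_nii(dataset$masks[[m]] * 1L, file.path(dir, paste0(m, ".nii.gz")))

  manifest <- NULL
  for (id in names(dataset$subjects)) {
    su <- dataset$subjects[[id]]
    for (ses in 1:2) {
      bold_path <- sprintf("%s_session%d.nii.gz", id, ses)
      motion_path <- sprintf("%s_session%d_motion.txt", id, ses)
      write_nii(su[[paste0("session", ses)]]$data,
                file.path(dir, bold_path), time_step = tr)
      mot <- su[[paste0("motion", ses)]]
      utils::write.table(cbind(mot$translations, mot$rotations),
                         file.path(dir, motion_path),
                         row.names = FALSE, col.names = FALSE)
      manifest <- rbind(manifest,
                        data.frame(subject_id = id, session = ses,
                                   bold_path = bold_path,
                                   motion_path = motion_path))
    }
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  layout <- if (!is.null(spec)) spec$roi_layout else NULL
  if (!is.null(layout)) {
    atl <- do.call(rbind, lapply(layout, function(r)
      data.frame(roi_name = r$name, network = r$network,
                 center_x = r$center[1], center_y = r$center[2],
                 center_z = r$center[3], radius = r$radius)))
    utils::write.table(atl, file.path(dir, "atlas.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta <- list(tr_seconds = tr, voxel_size_mm = vox,
               grid_shape = dim(dataset$masks$brain))
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)

  gt <- dataset$ground_truth
  gt_json <- list(
    fidelity = gt$fidelity,
    connectivity = gt$connectivity,
    fd_series = gt$fd_series,
    amplitude_maps = lapply(gt$amplitude_maps, function(a)
      list(dim = dim(a), values = as.vector(a))))
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a dataset directory
#'
#' Counterpart of \code{\link{write_dataset}}: reads the manifest, NIfTI
#' volumes and masks, motion text files and the atlas manifest back into
#' the in-memory dataset structure consumed by \code{\link{run_pipeline}}.
#'
#' @param dir dataset directory.
#' @return list with \code{subjects}, \code{masks}, \code{atlas},
#'   \code{ground_truth} (if present) and \code{spec = NULL}.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  masks <- lapply(c(brain = "brain", wm = "wm", csf = "csf"), function(m)
    array(as.vector(RNifti::readNifti(
      file.path(dir, paste0(m, ".nii.gz")))) > 0.5,
      meta$grid_shape))

  subjects <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    ses <- manifest$session[i]
    vol <- RNifti::readNifti(file.path(dir, manifest$bold_path[i]))
    mot <- as.matrix(utils::read.table(file.path(dir,
                                                 manifest$motion_path[i])))
    subjects[[id]][[paste0("session", ses)]] <-
      bold_series(array(as.vector(vol), dim(vol)), meta$tr_seconds,
                  meta$voxel_size_mm)
    subjects[[id]][[paste0("motion", ses)]] <-
      motion_table(mot[, 1:3], mot[, 4:6])
  }
  atl <- utils::read.table(file.path(dir, "atlas.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  rois <- lapply(seq_len(nrow(atl)), function(i)
    list(name = atl$roi_name[i], network = atl$network[i],
         mask = sphere_mask(meta$grid_shape,
                            c(atl$center_x[i], atl$center_y[i],
                              atl$center_z[i]), atl$radius[i])))
  atlas <- network_atlas(rois, masks$brain)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(subjects = subjects, masks = masks, atlas = atlas,
       ground_truth = gt, spec = NULL)
}

#' Write a study report to disk
#'
#' Tab-separated per-subject tables (voxel CCC with confidence intervals;
#' internetwork Spearman with adjusted p), the two aggregate tables, and a
#' JSON provenance block (configuration, its hash, seed, package version).
#'
#' @param report a \code{study_report} from \code{\link{run_pipeline}}.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create directory: ", outdir)
  tsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tsv(report$ccc_records, "ccc_records.tsv")
  tsv(report$spearman_records, "spearman_records.tsv")
  tsv(report$aggregates$ccc, "aggregate_ccc.tsv")
  tsv(report$aggregates$internetwork, "aggregate_internetwork.tsv")

  cfg <- report$provenance$config
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               force = TRUE, null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  prov <- list(config = cfg,
               config_md5 = unname(tools::md5sum(tmp)),
               seed = report$provenance$seed,
               alpha = report$alpha,
               excluded_subjects = report$excluded_subjects,
               package_version = report$provenance$package_version)
  unlink(tmp)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(outdir)
}

#' Read report tables back from disk
#'
#' @param dir directory written by \code{\link{write_report}}.
#' @return list of data.frames \code{ccc_records},
#'   \code{spearman_records}, \code{aggregate_ccc},
#'   \code{aggregate_internetwork}, plus \code{provenance}.
#' @export
read_report <- function(dir) {
  rt <- function(name)
    utils::read.table(file.path(dir, name), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  list(ccc_records = rt("ccc_records.tsv"),
       spearman_records = rt("spearman_records.tsv"),
       aggregate_ccc = rt("aggregate_ccc.tsv"),
       aggregate_internetwork = rt("aggregate_internetwork.tsv"),
       provenance = jsonlite::read_json(file.path(dir, "provenance.json"),
                                        simplifyVector = TRUE))
}

#' Write metric maps as NIfTI volumes
#'
#' @param maps named list of \code{\link{metric_map}}s.
#' @param dir output directory.
#' @param voxel_size_mm voxel edges in mm for the header.
#' @param prefix filename prefix (e.g. subject/session).
#' @return invisibly, the written paths.
#' @export
write_metric_maps <- function(maps, dir, voxel_size_mm = c(3, 3, 3),
                              prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(maps), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".nii.gz"))
    img <- RNifti::asNifti(maps[[nm]]$values)
    RNifti::pixdim(img) <- voxel_size_mm
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}
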