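#' Specification of a synthetic two-session BOLD dataset
#'
#' Declares the study conditions the generator emulates: a desk-scale grid,
#' 300 volumes at TR = 3 s per session (two sessions per subject, matching
#' a one-week test-retest design), 15 spherical ROIs assigned 4/4/7 to the
#' DMN/CEN/SN, latent network signals band-limited to 0.01-0.1 Hz with a
#' known 15 x 15 correlation structure, a per-subject spatial amplitude map
#' shared across sessions, an out-of-band nuisance component, white noise,
#' and motion traces with occasional spikes.
#'
#' \code{session_fidelity} is the fraction of voxel-level signal variance
#' shared between the two sessions: latent signals are mixed as
#' \code{sqrt(f) * shared + sqrt(1 - f) * session-unique}, so 1 makes the
#' sessions' signals identical and 0 makes them independent.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape 3 positive integers, voxels per axis (default
#'   \code{c(16, 16, 10)}: the full pipeline runs in seconds while every ROI
#'   keeps over 20 voxels).
#' @param n_volumes volumes per session (default 300; 10 are conventionally
#'   dropped downstream, leaving 290).
#' @param tr_seconds repetition time (default 3).
#' @param voxel_size_mm voxel edge lengths in mm (default 3).
#' @param session_fidelity real in [0, 1]; see above (default 0.9).
#' @param roi_layout list of 15 ROI definitions (\code{name},
#'   \code{network}, \code{center} voxel, \code{radius} in voxels); default
#'   \code{\link{default_roi_layout}}.
#' @param latent_connectivity 15 x 15 symmetric positive-semidefinite
#'   correlation matrix with unit diagonal; default
#'   \code{\link{default_latent_connectivity}}.
#' @param amplitude_range min/max of the per-voxel low-frequency amplitude
#'   scale (default \code{c(0.8, 1.2)}).
#' @param local_fluctuation fraction of each ROI voxel's in-band signal
#'   variance carried by a voxel-specific low-frequency component rather
#'   than the shared ROI network signal (default 0.3). Regional signals
#'   explain only part of a voxel's spontaneous variance in vivo; without a
#'   local component every ROI voxel would be an exact amplitude-scaled
#'   copy of its network signal and fidelity would act only at the ROI
#'   level. Background voxels are purely local by construction.
#' @param noise_sd white-noise SD (default 0.3).
#' @param nuisance_amp amplitude of the shared out-of-band (> 0.1 Hz)
#'   nuisance oscillation, relative to unit signal scale (default 0.1, i.e.
#'   about 1 percent of signal power).
#' @param motion_spike_rate per-frame probability of a motion spike large
#'   enough to be scrubbed (default 0.03).
#' @param spectrum in-band spectral shape of the latent signals:
#'   \code{"flat"} comb (default) or \code{"one_over_f"}.
#' @param seed integer master seed; per-subject/per-session streams are
#'   derived from it by fixed counter offsets, so identical specs reproduce
#'   bit-identical datasets.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_subjects,
                           grid_shape = c(16L, 16L, 10L),
                           n_volumes = 300L,
                           tr_seconds = 3,
                           voxel_size_mm = c(3, 3, 3),
                           session_fidelity = 0.9,
                           roi_layout = default_roi_layout(),
                           latent_connectivity = default_latent_connectivity(),
                           amplitude_range = c(0.8, 1.2),
                           local_fluctuation = 0.3,
                           noise_sd = 0.3,
                           nuisance_amp = 0.1,
                           motion_spike_rate = 0.03,
                           spectrum = c("flat", "one_over_f"),
                           seed = 1L) {
  spectrum <- match.arg(spectrum)
  if (n_subjects < 1L) stop("'n_subjects' must be at least 1")
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    stop("'grid_shape' must be 3 integers >= 4")
  if (n_volumes < 64L) stop("'n_volumes' must be at least 64")
  if (session_fidelity < 0 || session_fidelity > 1)
    stop("'session_fidelity' must lie in [0, 1]")
  if (motion_spike_rate < 0 || motion_spike_rate > 1)
    stop("'motion_spike_rate' must lie in [0, 1]")
  if (length(roi_layout) != 15L) stop("'roi_layout' must define 15 ROIs")
  C <- latent_connectivity
  if (!isTRUE(all.equal(C, t(C))) || any(abs(diag(C) - 1) > 1e-12))
    stop("'latent_connectivity' must be symmetric with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf(
      "'latent_connectivity' is not positive semidefinite: smallest eigenvalue %.3e",
      min(ev)))
  if (amplitude_range[1] <= 0 || amplitude_range[2] < amplitude_range[1])
    stop("'amplitude_range' must be positive and ordered")
  if (local_fluctuation < 0 || local_fluctuation >= 1)
    stop("'local_fluctuation' must lie in [0, 1)")
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = as.integer(grid_shape),
    n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
    voxel_size_mm = voxel_size_mm, session_fidelity = session_fidelity,
    roi_layout = roi_layout, latent_connectivity = C,
    amplitude_range = amplitude_range,
    local_fluctuation = local_fluctuation, noise_sd = noise_sd,
    nuisance_amp = nuisance_amp, motion_spike_rate = motion_spike_rate,
    spectrum = spectrum, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Default desk-scale triple-network ROI layout
#'
#' Fifteen spheres of radius 1.8 voxels (27 voxels each) on a lattice with
#' centers 4 voxels apart inside the default 16 x 16 x 10 grid, so the
#' masks are pairwise disjoint. ROI names follow the standard
#' triple-network nomenclature.
#'
#' @return list of 15 entries: \code{name}, \code{network}, \code{center},
#'   \code{radius}.
#' @export
default_roi_layout <- function() {
  centers <- rbind(
    c(4, 4, 4),  c(8, 4, 4),  c(12, 4, 4),
    c(4, 8, 4),  c(8, 8, 4),  c(12, 8, 4),
    c(4, 12, 4), c(8, 12, 4), c(12, 12, 4),
    c(4, 4, 7),  c(8, 4, 7),  c(12, 4, 7),
    c(4, 8, 7),  c(8, 8, 7),  c(12, 8, 7))
  names <- c("MPFC", "LP(L)", "LP(R)", "PCC",
             "lPFC", "rPFC", "PPC(L)", "PPC(R)",
             "ACC", "Insula(L)", "Insula(R)", "RPFC(L)", "RPFC(R)",
             "SMG(L)", "SMG(R)")
  networks <- c(rep("DMN", 4), rep("CEN", 4), rep("SN", 7))
  lapply(seq_len(15), function(i)
    list(name = names[i], network = networks[i],
         center = centers[i, ], radius = 1.8))
}

#' Default latent inter-ROI correlation matrix
#'
#' Block structure over the 4/4/7 network partition: within-network
#' correlation 0.5, between-network 0.2, unit diagonal. Positive definite.
#'
#' @param within,between block correlation levels.
#' @return 15 x 15 correlation matrix.
#' @export
default_latent_connectivity <- function(within = 0.5, between = 0.2) {
  net <- c(rep(1, 4), rep(2, 4), rep(3, 7))
  C <- outer(net, net, function(a, b) ifelse(a == b, within, between))
  diag(C) <- 1
  C
}

# Internal: sphere mask around a center (1-based voxel coordinates).
sphere_mask <- function(grid_shape, center, radius) {
  co <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
        (co[, 3] - center[3])^2
  array(d2 <= radius^2, grid_shape)
}

# Derived sub-seed for a (subject, stream, session) unit; kept below 2^31.
derive_seed <- function(master, subject, stream, session = 0L) {
  (as.double(master) + 100003 * subject + 1009 * stream + 101 * session) %%
    2147483647
}

# Internal: n_draws independent band-limited signals on the DFT bin grid
# of (n_volumes, tr): sinusoids with Gaussian random amplitudes and phases
# (a stationary Gaussian process restricted to the comb). Exact band
# control, no filter edge effects; expected variance 1 per draw, while the
# realized per-draw power fluctuates naturally, so mixing draws across
# sessions decorrelates spectral amplitude monotonically in the mixing
# weight. Returns t x n_draws matrix.
comb_signals <- function(n_draws, n_volumes, tr, low_hz, high_hz, spectrum) {
  df <- 1 / (n_volumes * tr)
  k <- seq(ceiling(low_hz / df), floor(high_hz / df))
  if (!length(k)) stop("no frequency bin in band for this series length")
  f <- k * df
  w <- if (spectrum == "one_over_f") 1 / f else rep(1, length(f))
  w <- w / sqrt(sum(w^2))                         # E[var] = 1
  tt <- (0:(n_volumes - 1)) * tr
  arg <- outer(tt, 2 * pi * f)                    # t x bins
  nb <- length(f)
  A <- matrix(stats::rnorm(nb * n_draws), nb, n_draws)
  B <- matrix(stats::rnorm(nb * n_draws), nb, n_draws)
  cos(arg) %*% (w * A) + sin(arg) %*% (w * B)
}

# Internal: mix 15 independent signal columns to the target correlation via
# Cholesky with a 1e-8 diagonal jitter for borderline-PSD inputs.
mix_latents <- function(Z, C) {
  L <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-8, nrow(C))))
  Z %*% L
}

#' Generate a synthetic two-session dataset
#'
#' Builds everything the pipeline consumes, with known ground truth: per
#' subject two \code{\link{bold_series}} (sessions 1 and 2), brain/WM/CSF
#' masks, a \code{\link{network_atlas}}, per-session motion tables, and a
#' ground-truth record (amplitude maps, the connectivity matrix actually
#' used, the fidelity, and the true FD series).
#'
#' Voxel series are \code{amplitude * latent + nuisance + noise}: ROI
#' voxels share their ROI's latent network signal (drawn with the requested
#' inter-ROI correlation via square-root factorization); non-ROI brain
#' voxels get independent latent signals, keeping degree-centrality ground
#' truth interpretable. All latent and nuisance components are mixed across
#' sessions by the fidelity rule, so fidelity 1 with zero noise gives
#' bit-identical session signals.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{subjects} (each: \code{session1},
#'   \code{session2}, \code{motion1}, \code{motion2}), \code{masks}
#'   (\code{brain}, \code{wm}, \code{csf}), \code{atlas},
#'   \code{ground_truth} and the \code{spec}.
#' @export
generate_dataset <- function(spec) {
  gs <- spec$grid_shape
  nt <- spec$n_volumes
  tr <- spec$tr_seconds
  f <- spec$session_fidelity

  # masks: rectangular brain with a 1-voxel margin; small WM and CSF slabs
  # in opposite corners, outside every ROI
  brain <- array(FALSE, gs)
  brain[2:(gs[1] - 1), 2:(gs[2] - 1), 2:(gs[3] - 1)] <- TRUE
  wm <- array(FALSE, gs)
  wm[(gs[1] - 2):(gs[1] - 1), 2:3, 2:3] <- TRUE
  csf <- array(FALSE, gs)
  csf[2:3, (gs[2] - 2):(gs[2] - 1), (gs[3] - 2):(gs[3] - 1)] <- TRUE
  wm <- wm & brain
  csf <- csf & brain

  roi_masks <- lapply(spec$roi_layout, function(r)
    sphere_mask(gs, r$center, r$radius))
  roi_total <- Reduce(`+`, lapply(roi_masks, function(m) m * 1L))
  if (any(roi_total > 1L)) stop("ROI masks overlap")
  if (any(roi_total[!brain] > 0L)) stop("ROI masks extend outside the brain mask")
  atlas <- network_atlas(lapply(seq_along(roi_masks), function(i)
    list(name = spec$roi_layout[[i]]$name,
         network = spec$roi_layout[[i]]$network,
         mask = roi_masks[[i]])), brain_mask = brain)

  brain_idx <- which(brain)
  n_brain <- length(brain_idx)
  roi_of_voxel <- integer(n_brain)          # 0 = background brain voxel
  for (i in seq_along(roi_masks))
    roi_of_voxel[roi_masks[[i]][brain]] <- i
  bg <- which(roi_of_voxel == 0L)

  subjects <- vector("list", spec$n_subjects)
  names(subjects) <- sprintf("sub%02d", seq_len(spec$n_subjects))
  amplitude_maps <- vector("list", spec$n_subjects)
  fd_truth <- vector("list", spec$n_subjects)

  for (s in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, s, 1L))
    amp <- stats::runif(n_brain, spec$amplitude_range[1],
                        spec$amplitude_range[2])
    amap <- array(NA_real_, gs)
    amap[brain_idx] <- amp
    amplitude_maps[[s]] <- amap

    # shared component (stream 2) and session-unique components (streams
    # 3 and 4): ROI latents, background latents, nuisance phase
    in_roi <- which(roi_of_voxel > 0L)
    draw_all <- function(stream, session) {
      set.seed(derive_seed(spec$seed, s, stream, session))
      Zroi <- mix_latents(
        comb_signals(15L, nt, tr, 0.01, 0.1, spec$spectrum),
        spec$latent_connectivity)
      Zbg <- comb_signals(length(bg), nt, tr, 0.01, 0.1, spec$spectrum)
      Zloc <- comb_signals(length(in_roi), nt, tr, 0.01, 0.1, spec$spectrum)
      nuis <- comb_signals(1L, nt, tr, 0.11, min(0.15, 0.9 / (2 * tr)),
                           "flat")
      list(roi = Zroi, bg = Zbg, loc = Zloc, nuis = nuis)
    }
    shared <- draw_all(2L, 0L)
    set.seed(derive_seed(spec$seed, s, 6L, 0L))
    motion_shared <- simulate_motion(nt, spec$motion_spike_rate)
    sessions <- vector("list", 2L)
    fd_truth[[s]] <- vector("list", 2L)
    wS <- sqrt(f); wU <- sqrt(1 - f)
    for (ses in 1:2) {
      uniq <- draw_all(3L, ses)
      lat_roi <- wS * shared$roi + wU * uniq$roi
      lat_bg <- wS * shared$bg + wU * uniq$bg
      lat_loc <- wS * shared$loc + wU * uniq$loc
      nuis <- wS * shared$nuis + wU * uniq$nuis

      lam <- spec$local_fluctuation
      sig <- matrix(0, nt, n_brain)
      sig[, bg] <- lat_bg
      sig[, in_roi] <- sqrt(1 - lam) *
        lat_roi[, roi_of_voxel[in_roi], drop = FALSE] + sqrt(lam) * lat_loc
      sig <- sweep(sig, 2, amp, "*")
      sig <- sig + as.vector(nuis) * spec$nuisance_amp
      if (spec$noise_sd > 0) {
        set.seed(derive_seed(spec$seed, s, 5L, ses))
        sig <- sig + matrix(stats::rnorm(nt * n_brain, 0, spec$noise_sd),
                            nt, n_brain)
      }
      flat <- matrix(0, prod(gs), nt)
      flat[brain_idx, ] <- t(sig)
      sessions[[ses]] <- bold_series(array(flat, c(gs, nt)), tr,
                                     spec$voxel_size_mm)

      # motion is mixed across sessions by the same fidelity rule as the
      # signals: at fidelity 1 the whole acquisition (and hence scrubbing
      # and nuisance regression) is replicated exactly
      set.seed(derive_seed(spec$seed, s, 6L, ses))
      motion_uniq <- simulate_motion(nt, spec$motion_spike_rate)
      mot <- motion_table(
        wS * motion_shared$translations + wU * motion_uniq$translations,
        wS * motion_shared$rotations + wU * motion_uniq$rotations)
      subjects[[s]][[paste0("motion", ses)]] <- mot
      fd_truth[[s]][[ses]] <- compute_fd(mot)$fd
    }
    subjects[[s]]$session1 <- sessions[[1]]
    subjects[[s]]$session2 <- sessions[[2]]
  }

  ground_truth <- list(amplitude_maps = amplitude_maps,
                       connectivity = spec$latent_connectivity,
                       fidelity = f, fd_series = fd_truth)
  list(subjects = subjects,
       masks = list(brain = brain, wm = wm, csf = csf),
       atlas = atlas, ground_truth = ground_truth, spec = spec)
}

# Internal: slow-drift motion trace with occasional one-frame spikes large
# enough (0.3 mm) to exceed the 0.2 mm scrubbing threshold.
simulate_motion <- function(nt, spike_rate) {
  translations <- apply(matrix(stats::rnorm(nt * 3, 0, 0.01), nt, 3), 2,
                        cumsum)
  rotations <- apply(matrix(stats::rnorm(nt * 3, 0, 2e-4), nt, 3), 2,
                     cumsum)
  spikes <- which(stats::runif(nt) < spike_rate & seq_len(nt) > 1L)
  for (j in spikes)
    translations[j, 1] <- translations[j, 1] + 0.3 * sample(c(-1, 1), 1)
  motion_table(translations, rotations)
}
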