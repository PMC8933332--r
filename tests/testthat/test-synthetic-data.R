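small_spec <- function(...) {
  synthetic_spec(n_subjects = 1, n_volumes = 80, seed = 11, ...)
}

test_that("identical specs reproduce bit-identical datasets", {
  d1 <- generate_dataset(small_spec())
  d2 <- generate_dataset(small_spec())
  expect_identical(d1$subjects$sub01$session1$data,
                   d2$subjects$sub01$session1$data)
  expect_identical(d1$subjects$sub01$session2$data,
                   d2$subjects$sub01$session2$data)
  expect_identical(d1$subjects$sub01$motion1, d2$subjects$sub01$motion1)
  expect_identical(d1$ground_truth$amplitude_maps,
                   d2$ground_truth$amplitude_maps)
  d3 <- generate_dataset(synthetic_spec(n_subjects = 1, n_volumes = 80,
                                        seed = 12))
  expect_false(identical(d1$subjects$sub01$session1$data,
                         d3$subjects$sub01$session1$data))
})

test_that("perfect fidelity with zero noise duplicates the session exactly", {
  d <- generate_dataset(small_spec(session_fidelity = 1, noise_sd = 0))
  expect_identical(d$subjects$sub01$session1$data,
                   d$subjects$sub01$session2$data)
  expect_identical(d$subjects$sub01$motion1, d$subjects$sub01$motion2)
})

test_that("non-positive-semidefinite connectivity is rejected with a diagnostic", {
  C <- default_latent_connectivity()
  C[1, 2] <- C[2, 1] <- 0.99
  C[1, 3] <- C[3, 1] <- 0.99
  C[2, 3] <- C[3, 2] <- -0.9
  expect_error(synthetic_spec(n_subjects = 1, latent_connectivity = C),
               "eigenvalue")
  asym <- default_latent_connectivity()
  asym[1, 2] <- 0.9
  expect_error(synthetic_spec(n_subjects = 1, latent_connectivity = asym),
               "symmetric")
})

test_that("masks, ROIs and ground truth satisfy the declared invariants", {
  d <- generate_dataset(small_spec())
  roi_sum <- Reduce(`+`, lapply(d$atlas$rois, function(r) r$mask * 1L))
  expect_lte(max(roi_sum), 1L)                      # pairwise disjoint
  expect_true(all(roi_sum[!d$masks$brain] == 0L))   # inside the brain
  expect_true(all(vapply(d$atlas$rois, function(r) sum(r$mask) >= 20,
                         logical(1))))
  amp <- d$ground_truth$amplitude_maps[[1]]
  expect_true(all(is.na(amp[!d$masks$brain])))
  expect_true(all(amp[d$masks$brain] >= 0.8 & amp[d$masks$brain] <= 1.2))
  fd <- d$ground_truth$fd_series[[1]][[1]]
  expect_equal(fd[1], 0)
  expect_true(all(fd >= 0))
})

test_that("noise-free voxel spectra are confined to the 0.01-0.1 Hz band", {
  d <- generate_dataset(synthetic_spec(n_subjects = 1, noise_sd = 0,
                                       seed = 4))
  s <- d$subjects$sub01$session1
  X <- netstab:::series_matrix(s, d$masks$brain)
  sp <- netstab:::amplitude_spectrum(X[, seq(1, ncol(X), by = 40)], 3)
  band <- sp$freq >= 0.01 & sp$freq <= 0.1
  power_frac <- colSums(sp$amp[band, ]^2) / colSums(sp$amp^2)
  expect_true(all(power_frac >= 0.95))
})

test_that("long noise-free simulations recover the latent connectivity", {
  # scaled-down grid (10x10x6, radius-1.2 ROIs) so a 4096-volume series
  # stays cheap; sampling error of band-limited correlations ~ 1/sqrt(bins)
  centers <- as.matrix(expand.grid(x = c(3, 5.5, 8), y = c(3, 5.5, 8),
                                   z = c(2.5, 4.5)))[1:15, ]
  layout <- lapply(1:15, function(i)
    list(name = sprintf("roi%02d", i),
         network = c(rep("DMN", 4), rep("CEN", 4), rep("SN", 7))[i],
         center = centers[i, ], radius = 1.2))
  base <- list(n_subjects = 1, n_volumes = 4096, noise_sd = 0,
               grid_shape = c(10, 10, 6), roi_layout = layout, seed = 2)

  spec_id <- do.call(synthetic_spec,
                     c(base, list(latent_connectivity = diag(15))))
  d <- generate_dataset(spec_id)
  r <- cor(roi_mean_series(d$subjects$sub01$session1, d$atlas))
  expect_lte(max(abs(r[upper.tri(r)])), 0.1)

  spec_c <- do.call(synthetic_spec, base)
  dc_ <- generate_dataset(spec_c)
  rc <- cor(roi_mean_series(dc_$subjects$sub01$session1, dc_$atlas))
  expect_lte(max(abs(rc - spec_c$latent_connectivity)), 0.1)
})

test_that("motion traces contain scrubbable spikes at the requested rate", {
  d <- generate_dataset(small_spec(motion_spike_rate = 0.2,
                                   session_fidelity = 1))
  fd <- compute_fd(d$subjects$sub01$motion1)
  expect_gt(sum(fd$fd > fd$threshold_mm), 0)
  d0 <- generate_dataset(small_spec(motion_spike_rate = 0))
  fd0 <- compute_fd(d0$subjects$sub01$motion1)
  expect_equal(sum(fd0$fd > 0.25), 0)
})

test_that("downstream ALFF stability increases with session fidelity", {
  means <- vapply(c(0.2, 0.5, 0.9), function(f) {
    spec <- synthetic_spec(n_subjects = 5, session_fidelity = f, seed = 7)
    rep <- run_pipeline(run_config(synthetic = spec))
    mean(rep$ccc_records$estimate[rep$ccc_records$measure == "ALFF"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("datasets round-trip through the on-disk layout", {
  d <- generate_dataset(small_spec())
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "atlas.tsv")))
  back <- read_dataset(dir)
  expect_equal(back$subjects$sub01$session1$data,
               d$subjects$sub01$session1$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$subjects$sub01$motion2$rotations,
               d$subjects$sub01$motion2$rotations, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$masks$brain, d$masks$brain)
  expect_equal(back$atlas$networks, d$atlas$networks)
  expect_identical(back$atlas$rois[[3]]$mask, d$atlas$rois[[3]]$mask)
})
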