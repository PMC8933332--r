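test_that("ALFF of a pure on-bin tone equals its amplitude and scales linearly", {
  n <- 290; tr <- 3
  f_on <- 44 / (n * tr)                  # on-grid bin near 0.05 Hz
  x <- tone(f_on, n, tr, amplitude = 2)
  s <- series_from_matrix(cbind(x, 2 * x))
  m <- alff(s, all_mask(s))
  expect_equal(m$values[1, 1, 1], 2, tolerance = 1e-6)
  expect_equal(m$values[2, 1, 1], 2 * m$values[1, 1, 1], tolerance = 1e-12)

  const <- series_from_matrix(cbind(rep(3, n), rep(3, n)))
  expect_equal(max(abs(alff(const, all_mask(const))$values)), 0)

  short <- series_from_matrix(matrix(rnorm(20), 20, 1))
  expect_error(alff(short, all_mask(short)), "32")
})

test_that("fALFF is the in-band amplitude fraction, bounded by [0, 1]", {
  n <- 290; tr <- 3
  inb <- tone(44 / (n * tr), n, tr)
  outb <- tone(131 / (n * tr), n, tr)    # ~0.15 Hz, on-grid
  s <- series_from_matrix(cbind(inb, outb))
  m <- falff(s, all_mask(s))
  expect_equal(m$values[1, 1, 1], 1, tolerance = 1e-6)
  expect_lt(m$values[2, 1, 1], 0.01)

  # flat series gets the NA sentinel with a warning
  s2 <- series_from_matrix(cbind(inb, rep(1, n)))
  expect_warning(m2 <- falff(s2, all_mask(s2)), "zero total power")
  expect_true(is.na(m2$values[2, 1, 1]))

  # white noise: expected fALFF is the in-band fraction of positive bins
  set.seed(404)
  W <- matrix(rnorm(n * 120), n, 120)
  sw <- series_from_matrix(W)
  mw <- falff(sw, all_mask(sw))
  kmax <- floor(n / 2)
  freq <- (1:kmax) / (n * tr)
  frac <- mean(freq >= 0.01 & freq <= 0.1)
  expect_equal(mean(mw$values), frac, tolerance = 0.01)
  expect_true(all(mw$values >= 0 & mw$values <= 1))

  # ratio consistency: fALFF * total amplitude = ALFF identically
  ma <- alff(sw, all_mask(sw))
  sp <- netstab:::amplitude_spectrum(netstab:::series_matrix(sw, all_mask(sw)), tr)
  expect_equal(as.vector(mw$values) * colSums(sp$amp), as.vector(ma$values),
               tolerance = 1e-10)
})

test_that("ReHo equals Kendall's W: perfect concordance, hand case, null level", {
  # 27 identical series give W = 1
  base <- rnorm(60)
  arr <- array(rep(base, each = 27), c(3, 3, 3, 60))
  s <- bold_series(arr, 3)
  m <- reho(s, array(TRUE, c(3, 3, 3)))
  expect_equal(m$values[2, 2, 2], 1)

  # hand-computed 3-series, 4-frame case: rank table gives S = 29,
  # W = 12 * 29 / (3^2 * (4^3 - 4)) = 0.644444...
  M <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(1, 3, 2, 4))
  sline <- series_from_matrix(M)
  mline <- reho(sline, all_mask(sline))
  expect_equal(mline$values[2, 1, 1], 29 * 12 / 540, tolerance = 1e-12)
  expect_equal(mline$values[2, 1, 1], oracle_kendall_w(M), tolerance = 1e-12)

  # independent series: W near the null expectation 1/K
  set.seed(7)
  arr2 <- array(rnorm(5 * 5 * 5 * 290), c(5, 5, 5, 290))
  s2 <- bold_series(arr2, 3)
  m2 <- reho(s2, array(TRUE, c(5, 5, 5)))
  expect_lt(m2$values[3, 3, 3], 0.08)
  expect_true(all(m2$values > 0 & m2$values <= 1))

  # full-volume agreement with the brute-force oracle, every voxel
  mask <- array(TRUE, c(5, 5, 5))
  pos <- which(mask)
  co <- arrayInd(pos, c(5, 5, 5))
  for (v in c(1, 32, 63, 125)) {
    nb <- which(abs(co[, 1] - co[v, 1]) <= 1 & abs(co[, 2] - co[v, 2]) <= 1 &
                abs(co[, 3] - co[v, 3]) <= 1)
    X <- t(apply(co[nb, , drop = FALSE], 1,
                 function(p) arr2[p[1], p[2], p[3], ]))
    expect_equal(m2$values[co[v, 1], co[v, 2], co[v, 3]],
                 oracle_kendall_w(t(X)), tolerance = 1e-12)
  }
})

test_that("degree centrality counts supra-threshold correlations exactly", {
  n <- 120
  base <- rnorm(n)
  M <- matrix(rep(base, 9), n, 9)
  s <- series_from_matrix(M)
  m <- dc(s, all_mask(s))
  expect_equal(as.vector(m$values), rep(8, 9))   # N - 1 everywhere

  # orthogonal on-grid sinusoids are uncorrelated: DC = 0
  tt <- 0:(n - 1)
  Mo <- sapply(1:6, function(k) sin(2 * pi * k * tt / n))
  so <- series_from_matrix(Mo)
  expect_equal(as.vector(dc(so, all_mask(so))$values), rep(0, 6))

  # seeded random volume equals the brute-force count per voxel
  set.seed(55)
  Mr <- matrix(rnorm(n * 200), n, 200)
  sr <- series_from_matrix(Mr)
  expect_equal(as.vector(dc(sr, all_mask(sr))$values), oracle_dc(Mr))

  # invariance to per-voxel affine rescaling
  Ma <- sweep(sweep(Mr, 2, runif(200, 0.5, 2), "*"), 2, rnorm(200), "+")
  sa <- series_from_matrix(Ma)
  expect_equal(dc(sa, all_mask(sa))$values, dc(sr, all_mask(sr))$values)

  # zero-variance voxel flagged, others unaffected
  Mz <- cbind(Mr[, 1:5], 0)
  sz <- series_from_matrix(Mz)
  expect_warning(mz <- dc(sz, all_mask(sz)), "zero-variance")
  expect_true(is.na(mz$values[6, 1, 1]))
  expect_equal(as.vector(mz$values)[1:5], oracle_dc(Mr[, 1:5]))
})

test_that("z-scoring standardizes the in-mask distribution and is idempotent", {
  set.seed(12)
  mask <- array(TRUE, c(4, 4, 3))
  m <- metric_map(array(rnorm(48, 5, 2), c(4, 4, 3)), "ALFF")
  z <- zscore_map(m, mask)
  expect_lt(abs(mean(z$values)), 1e-10)
  expect_equal(sd(z$values), 1, tolerance = 1e-10)
  expect_equal(zscore_map(z, mask)$values, z$values, tolerance = 1e-10)

  affine <- metric_map(3 * m$values + 7, "ALFF")
  expect_equal(zscore_map(affine, mask)$values, z$values, tolerance = 1e-10)

  flat <- metric_map(array(2, c(4, 4, 3)), "ALFF")
  expect_error(zscore_map(flat, mask), "constant")
})

test_that("Gaussian smoothing preserves constants, has the right kernel shape, conserves mass", {
  mask <- array(TRUE, c(31, 15, 15))
  spec <- smoothing_spec(fwhm_mm = 3, voxel_size_mm = c(1, 1, 1))

  const <- metric_map(array(4, c(31, 15, 15)), "ALFF")
  expect_equal(smooth_map(const, spec, mask)$values, const$values,
               tolerance = 1e-12)

  imp <- array(0, c(31, 15, 15)); imp[16, 8, 8] <- 1
  sm <- smooth_map(metric_map(imp, "ALFF"), spec, mask)
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  for (d in 1:3)
    expect_equal(sm$values[16 + d, 8, 8] / sm$values[16, 8, 8],
                 exp(-d^2 / (2 * sigma^2)), tolerance = 1e-6)
  expect_equal(sum(sm$values), 1, tolerance = 0.01)   # mass conservation

  tiny <- smoothing_spec(fwhm_mm = 0.5, voxel_size_mm = c(1, 1, 1))
  sm2 <- smooth_map(metric_map(imp, "ALFF"), tiny, mask)
  expect_equal(sm2$values, imp, tolerance = 1e-3)     # FWHM -> 0 limit

  expect_error(smoothing_spec(1, c(3, 3, 3)), "resolvable")
})
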