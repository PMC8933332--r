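test_that("concordance correlation matches hand-evaluated moments", {
  r <- ccc(c(1, 2, 3, 4), c(2, 3, 4, 5))
  # population moments: var 1.25 each, cov 1.25, mean shift 1
  expect_equal(r$var_x, 1.25); expect_equal(r$var_y, 1.25)
  expect_equal(r$cov_xy, 1.25)
  expect_equal(r$rho_c, 2 * 1.25 / (1.25 + 1.25 + 1), tolerance = 1e-12)
  expect_equal(r$rho_c, 5 / 7, tolerance = 1e-12)
  expect_equal(r$precision_rho, 1, tolerance = 1e-12)
  expect_equal(r$scale_omega, 1, tolerance = 1e-12)
  expect_equal(r$location_v2, 1 / 1.25, tolerance = 1e-12)
  expect_equal(r$accuracy_chi, 2 / (2 + 0.8), tolerance = 1e-12)

  x <- rnorm(20)
  perfect <- ccc(x, x)
  expect_equal(perfect$rho_c, 1, tolerance = 1e-12)
  expect_equal(perfect$accuracy_chi, 1, tolerance = 1e-12)
})

test_that("concordance invariants hold on random draws", {
  set.seed(88)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -1, 1) * x + rnorm(n, mean = runif(1, -2, 2))
    a <- ccc(x, y)
    expect_equal(a$rho_c, a$accuracy_chi * a$precision_rho,
                 tolerance = 1e-10)
    expect_lte(abs(a$rho_c), abs(a$precision_rho) + 1e-12)
    expect_equal(a$rho_c, ccc(y, x)$rho_c, tolerance = 1e-12)
    # Eq-8 sample counterpart: the n vs n-1 normalization cancels
    expect_equal(a$rc, a$rho_c, tolerance = 1e-12)
    expect_lte(a$ci_low, a$rho_c + 1e-12)
    expect_gte(a$ci_high, a$rho_c - 1e-12)
  }
})

test_that("concordance recovers an engineered population value", {
  set.seed(606)
  n <- 10000
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)  # equal moments: rho_c = rho = 0.8
  expect_equal(ccc(x, y)$rho_c, 0.8, tolerance = 0.01)
})

test_that("degenerate concordance inputs are handled explicitly", {
  expect_error(ccc(rep(1, 5), rep(2, 5)), "constant")
  expect_warning(r <- ccc(rep(1, 5), c(1, 2, 3, 4, 5)), "constant")
  expect_equal(r$rho_c, 0)
})

test_that("voxel-based concordance pairs sessions voxel by voxel", {
  set.seed(9)
  mask <- array(TRUE, c(5, 5, 4))
  v <- array(rnorm(100), c(5, 5, 4))
  m1 <- metric_map(v, "ALFF")
  expect_equal(voxel_ccc(m1, m1, mask)$rho_c, 1, tolerance = 1e-12)

  shifted <- metric_map(v + 0.5, "ALFF")
  r <- voxel_ccc(m1, shifted, mask)
  expect_equal(r$precision_rho, 1, tolerance = 1e-12)
  expect_lt(r$rho_c, 1)
  expect_equal(r$rho_c,
               2 * r$cov_xy / (r$var_x + r$var_y + 0.25), tolerance = 1e-12)

  # sentinel voxels are excluded from the pairing
  v2 <- v; v2[1, 1, 1] <- NA
  r2 <- voxel_ccc(metric_map(v2, "ALFF"), m1, mask)
  expect_equal(r2$n, 99)
  small <- array(TRUE, c(5, 5, 4)) & FALSE; small[1:2, 1, 1] <- TRUE
  expect_error(voxel_ccc(m1, m1, small), "10")
})

test_that("Bonferroni adjustment reproduces the study-level threshold", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  n_tests <- 16 * 4 * 3
  expect_equal(n_tests, 192)
  expect_equal(round(bonferroni_alpha(0.05, n_tests), 5), 0.00026)
})

test_that("Spearman stability matches a rank-then-Pearson oracle", {
  set.seed(123)
  x <- rnorm(28); y <- 0.5 * x + rnorm(28)
  s <- spearman_stability(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  tstat <- s$rho * sqrt(26 / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tstat), 26), tolerance = 1e-12)

  expect_equal(spearman_stability(x, x)$rho, 1)
  expect_equal(spearman_stability(x, -x)$rho, -1)
  expect_equal(spearman_stability(x, 10 + 3 * x)$rho, 1)  # monotone invariance
  expect_error(spearman_stability(rep(1, 6), rnorm(6)), "constant")

  # exact permutation branch for short tie-free blocks
  xe <- c(3, 1, 4, 1.5, 9, 2.6); ye <- c(2, 1, 5, 3, 8, 4)
  se <- spearman_stability(xe, ye, exact = TRUE)
  ref <- cor.test(xe, ye, method = "spearman", exact = TRUE)
  expect_equal(se$p, ref$p.value, tolerance = 1e-12)
})

test_that("FDR control follows hand-executed Benjamini-Hochberg", {
  p <- c(0.001, 0.008, 0.039, 0.041)
  out <- fdr_correct(p, q = 0.05)
  expect_equal(out$p_adjusted, c(0.004, 0.016, 0.041, 0.041),
               tolerance = 1e-12)
  expect_true(all(out$rejected))

  out2 <- fdr_correct(c(0.2), q = 0.05)
  expect_equal(out2$p_adjusted, 0.2)
  expect_true(all(fdr_correct(rep(0, 5), 0.01)$rejected))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("strength labels follow the published scale at printed precision", {
  expect_equal(label_strength(c(0.90, 0.66, 1.00, 0.39, 0.40, 0.70, 0.99)),
               c("strong", "moderate", "perfect", "weak", "moderate",
                 "strong", "strong"))
  # magnitudes label negative coefficients
  expect_equal(label_strength(-0.20), "weak")
  expect_equal(label_strength(-0.75), "strong")
  # rounding to printed precision decides boundary cases
  expect_equal(label_strength(0.395), "moderate")
  expect_equal(label_strength(0.996), "perfect")
  expect_error(label_strength(1.2), "-1, 1")
})

test_that("aggregation reproduces published group summaries from the fixture", {
  fx <- generate_fixture_tables()
  expect_equal(dim(fx$ccc), c(16L, 13L))
  expect_equal(dim(fx$internetwork), c(16L, 4L))
  # spot values
  expect_equal(fx$ccc$DMN_ALFF[1], 0.72)
  expect_equal(fx$ccc$SN_fALFF[1], -0.20)
  expect_equal(fx$internetwork$DMN_SN[11], 0.94)

  ag <- aggregate_stability(fx$ccc_long)
  row <- ag[ag$unit == "DMN" & ag$measure == "ALFF", ]
  expect_equal(round(row$mean, 2), 0.90)
  expect_equal(row$min, 0.72)
  expect_equal(row$max, 0.96)
  expect_equal(row$n_subjects, 16L)
  expect_equal(round(ag[ag$unit == "CEN" & ag$measure == "fALFF", "mean"], 2),
               0.60)
  expect_equal(round(ag[ag$unit == "CEN" & ag$measure == "fALFF", "sd"], 2),
               0.19)

  one <- aggregate_stability(stability_record("s1", "DMN", "ALFF", 0.8))
  expect_equal(one$mean, 0.8)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
})
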