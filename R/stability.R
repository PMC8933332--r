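#' Lin's concordance correlation coefficient
#'
#' Agreement between two paired measurements, penalizing departure from the
#' 45-degree identity line as well as decorrelation:
#' \deqn{\rho_c = \frac{2\sigma_{yx}}{\sigma_x^2 + \sigma_y^2 +
#'   (\mu_y - \mu_x)^2}}
#' with population (1/n) moments. It factors into accuracy times precision,
#' \eqn{\rho_c = \chi_a \rho}, where \eqn{\rho} is the Pearson correlation
#' and
#' \deqn{\chi_a = \frac{2}{\varpi + 1/\varpi + v^2}, \quad
#'       v^2 = \frac{(\mu_y - \mu_x)^2}{\sigma_x \sigma_y}, \quad
#'       \varpi = \sigma_y / \sigma_x.}
#' The sample counterpart \eqn{r_c} (n-1 moments) is returned alongside; the
#' normalization cancels so both coincide. The confidence interval uses the
#' Fisher z transform of \eqn{r_c} with Lin's (1989) asymptotic standard
#' error, back-transformed.
#'
#' @param x,y equal-length numeric vectors (n >= 3), at least one
#'   nonconstant. If exactly one is constant the coefficient is 0 by
#'   convention (with a warning).
#' @param alpha two-sided CI level; the default 0.00026 is the Bonferroni
#'   adjustment 0.05/192 for 16 subjects x 4 metrics x 3 networks.
#' @return object of class \code{ccc_result}: \code{rho_c},
#'   \code{precision_rho}, \code{accuracy_chi}, \code{location_v2},
#'   \code{scale_omega}, \code{mu_x}, \code{mu_y}, \code{var_x},
#'   \code{var_y}, \code{cov_xy}, \code{rc} (sample counterpart), \code{n},
#'   \code{ci_low}, \code{ci_high}, \code{alpha}.
#' @export
ccc <- function(x, y, alpha = 0.00026) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input")
  mu_x <- mean(x); mu_y <- mean(y)
  var_x <- mean((x - mu_x)^2)          # population (1/n) moments
  var_y <- mean((y - mu_y)^2)
  cov_xy <- mean((x - mu_x) * (y - mu_y))
  if (var_x == 0 && var_y == 0)
    stop("both vectors are constant; concordance undefined")
  if (var_x == 0 || var_y == 0) {
    warning("one vector is constant; concordance set to 0")
    return(structure(list(rho_c = 0, precision_rho = NA_real_,
                          accuracy_chi = NA_real_, location_v2 = NA_real_,
                          scale_omega = NA_real_, mu_x = mu_x, mu_y = mu_y,
                          var_x = var_x, var_y = var_y, cov_xy = cov_xy,
                          rc = 0, n = n, ci_low = NA_real_,
                          ci_high = NA_real_, alpha = alpha),
                     class = "ccc_result"))
  }
  rho_c <- 2 * cov_xy / (var_x + var_y + (mu_y - mu_x)^2)
  rho <- cov_xy / sqrt(var_x * var_y)
  omega <- sqrt(var_y) / sqrt(var_x)
  v2 <- (mu_y - mu_x)^2 / sqrt(var_x * var_y)
  chi_a <- 2 / (omega + 1 / omega + v2)
  # sample counterpart via Pearson's r; with matching (1/n) variance
  # normalization the two routes coincide identically
  r <- stats::cor(x, y)
  rc <- 2 * r * sqrt(var_x) * sqrt(var_y) / (var_x + var_y + (mu_y - mu_x)^2)
  ci <- ccc_ci(rc, rho, v2, n, alpha)
  structure(list(rho_c = rho_c, precision_rho = rho, accuracy_chi = chi_a,
                 location_v2 = v2, scale_omega = omega,
                 mu_x = mu_x, mu_y = mu_y, var_x = var_x, var_y = var_y,
                 cov_xy = cov_xy, rc = rc, n = n,
                 ci_low = ci[1], ci_high = ci[2], alpha = alpha),
            class = "ccc_result")
}

# Lin's (1989) asymptotic CI on the Fisher-z scale, back-transformed.
# u^2 is the squared standardized location shift (= v2 above).
ccc_ci <- function(rc, rho, u2, n, alpha) {
  eps <- 1e-12
  rc_c <- max(min(rc, 1 - eps), -(1 - eps))
  z <- atanh(rc_c)
  if (abs(rho) < eps || 1 - rc_c^2 < eps) return(c(NA_real_, NA_real_))
  se2 <- ((1 - rho^2) * rc_c^2 / ((1 - rc_c^2) * rho^2) +
          4 * rc_c^3 * (1 - rc_c) * u2 / (rho * (1 - rc_c^2)^2) -
          2 * rc_c^4 * u2^2 / (rho^2 * (1 - rc_c^2)^2)) / (n - 2)
  se <- sqrt(max(se2, 0))
  q <- stats::qnorm(1 - alpha / 2)
  tanh(c(z - q * se, z + q * se))
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf(
    "<ccc_result> rho_c = %.4f (accuracy %.4f x precision %.4f), n = %d, %g%% CI [%.4f, %.4f]\n",
    x$rho_c, x$accuracy_chi, x$precision_rho, x$n,
    100 * (1 - x$alpha), x$ci_low, x$ci_high))
  invisible(x)
}

#' Voxel-based concordance of two session maps
#'
#' Pairs each usable voxel of a network mask across the two sessions and
#' computes \code{\link{ccc}} on the paired values: the subject-level
#' intersession stability of one metric within one network.
#'
#' @param map_s1,map_s2 \code{\link{metric_map}}s from sessions 1 and 2 on
#'   the same grid (conventionally standardized and smoothed).
#' @param network_mask 3D logical mask (e.g. \code{\link{network_mask}}).
#' @param alpha CI level passed to \code{\link{ccc}}.
#' @return a \code{ccc_result}; sentinel (\code{NA}) voxels in either map
#'   are excluded from the pairing. Fewer than 10 usable voxels is an error.
#' @export
voxel_ccc <- function(map_s1, map_s2, network_mask, alpha = 0.00026) {
  if (!identical(dim(map_s1$values), dim(map_s2$values)))
    stop("session maps are on different grids")
  x <- map_s1$values[network_mask]
  y <- map_s2$values[network_mask]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10L)
    stop("fewer than 10 usable voxels in the network mask")
  ccc(x[ok], y[ok], alpha = alpha)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param base_alpha family-wise level (default 0.05).
#' @param n_tests number of tests (e.g. 16 subjects x 4 metrics x
#'   3 networks = 192, giving 0.05/192 = 0.00026).
#' @return adjusted per-test alpha.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_tests) {
  if (n_tests < 1L) stop("'n_tests' must be at least 1")
  base_alpha / n_tests
}

#' Spearman stability of an internetwork block
#'
#' Rank correlation between the same network-pair connectivity block
#' measured in two sessions (Spearman rather than Pearson because the
#' blocks are short: 16 or 28 values). Average ranks on ties; two-sided p
#' from the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}, or the
#' exact permutation distribution for n <= 10 when \code{exact = TRUE}.
#'
#' @param block_s1,block_s2 equal-length numeric vectors (n >= 5).
#' @param exact use the exact null distribution (only for n <= 10,
#'   tie-free data).
#' @return list with \code{rho} and \code{p}.
#' @export
spearman_stability <- function(block_s1, block_s2, exact = FALSE) {
  n <- length(block_s1)
  if (length(block_s2) != n) stop("blocks must have equal length")
  if (n < 5L) stop("need at least 5 paired values")
  if (stats::sd(block_s1) == 0 || stats::sd(block_s2) == 0)
    stop("constant block; rank correlation undefined")
  rho <- stats::cor(rank(block_s1), rank(block_s2))
  if (exact && n <= 10L) {
    p <- stats::cor.test(block_s1, block_s2, method = "spearman",
                         exact = TRUE)$p.value
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @param q target FDR level (default 0.01).
#' @return list with \code{rejected} (logical), \code{p_adjusted} (BH
#'   step-up adjusted p-values) and \code{q}.
#' @export
fdr_correct <- function(p_values, q = 0.01) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(rejected = adj <= q, p_adjusted = adj, q = q)
}

#' Qualitative strength of a correlation coefficient
#'
#' Dancey-Reidy scale on the magnitude, applied at 2-decimal printed
#' precision: below .40 weak, .40-.69 moderate, .70-.99 strong, 1.00
#' perfect. The scale is defined for magnitudes; negative coefficients are
#' labeled by |coefficient| and the sign is carried in the estimate itself.
#'
#' @param coefficient numeric vector in [-1, 1].
#' @return character vector: "weak", "moderate", "strong" or "perfect".
#' @export
label_strength <- function(coefficient) {
  if (any(abs(coefficient) > 1 + 1e-9, na.rm = TRUE))
    stop("coefficients must lie in [-1, 1]")
  a <- round(abs(coefficient), 2)    # half-even, printed precision
  out <- character(length(a))
  out[a < 0.40] <- "weak"
  out[a >= 0.40 & a <= 0.69] <- "moderate"
  out[a >= 0.70 & a <= 0.99] <- "strong"
  out[a == 1.00] <- "perfect"
  out[is.na(a)] <- NA_character_
  out
}

#' Build a tidy table of stability records
#'
#' @param subject_id,unit,measure character vectors (recycled): analysis
#'   unit is a network for CCC records or a network pair for Spearman
#'   records; measure is a metric name or pair name.
#' @param estimate numeric stability coefficients.
#' @param p_value optional raw p-values.
#' @param corrected optional logical: survived multiplicity correction.
#' @return data.frame with a \code{label} column from
#'   \code{\link{label_strength}}.
#' @export
stability_record <- function(subject_id, unit, measure, estimate,
                             p_value = NA_real_, corrected = NA) {
  data.frame(subject_id = subject_id, unit = unit, measure = measure,
             estimate = estimate, p_value = p_value, corrected = corrected,
             label = label_strength(estimate),
             stringsAsFactors = FALSE)
}

#' Aggregate stability records by unit and measure
#'
#' Group means, SDs (n-1 denominator), ranges and counts, one row per
#' unit x measure combination — the summary the per-network stability
#' figures report. Values are kept at full precision; round only at report
#' time.
#'
#' @param records data.frame as built by \code{\link{stability_record}}.
#' @return data.frame with columns \code{unit}, \code{measure}, \code{mean},
#'   \code{sd}, \code{min}, \code{max}, \code{n_subjects}. Single-record
#'   groups get \code{sd = 0} and \code{sd_defined = FALSE}.
#' @export
aggregate_stability <- function(records) {
  key <- interaction(records$unit, records$measure, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    data.frame(unit = g$unit[1], measure = g$measure[1],
               mean = mean(g$estimate),
               sd = if (nrow(g) > 1) stats::sd(g$estimate) else 0,
               min = min(g$estimate), max = max(g$estimate),
               n_subjects = nrow(g),
               sd_defined = nrow(g) > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$unit, out$measure), , drop = FALSE]
}
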