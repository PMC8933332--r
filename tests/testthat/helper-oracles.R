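# Independent brute-force oracles and small constructors used across the
# suite. These deliberately follow textbook formulations, not the package's
# vectorized implementations.

# Kendall's W of a t x K matrix of series: rank each column over time, sum
# ranks per frame, normalized squared deviation of the rank sums.
oracle_kendall_w <- function(X) {
  n <- nrow(X)
  K <- ncol(X)
  R <- apply(X, 2, rank)
  Rsum <- rowSums(R)
  S <- sum((Rsum - mean(Rsum))^2)
  12 * S / (K^2 * (n^3 - n))
}

# Degree centrality per column of a t x V matrix by explicit pairwise
# correlation counting.
oracle_dc <- function(X, thr = 0.25) {
  V <- ncol(X)
  C <- stats::cor(X)
  vapply(seq_len(V), function(v) sum(C[v, -v] > thr), numeric(1))
}

# Least-squares residuals via the normal equations.
oracle_resid <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  y - X1 %*% beta
}

# Wrap a t x V matrix of voxel series as a bold_series on a V x 1 x 1 grid.
series_from_matrix <- function(M, tr = 3) {
  arr <- array(0, c(ncol(M), 1, 1, nrow(M)))
  arr[, 1, 1, ] <- t(M)
  bold_series(arr, tr)
}

all_mask <- function(series) array(TRUE, dim(series$data)[1:3])

# A sinusoid sampled on the acquisition grid; freq in Hz.
tone <- function(freq, n = 290, tr = 3, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * (0:(n - 1)) * tr + phase)
}

# One-sided amplitude ratio of a frequency component before/after an
# operation, measured by projection onto the tone.
tone_amplitude <- function(x, freq, tr = 3) {
  n <- length(x)
  tt <- (0:(n - 1)) * tr
  2 * sqrt(mean(x * sin(2 * pi * freq * tt))^2 +
           mean(x * cos(2 * pi * freq * tt))^2)
}
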