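# Independent oracles and small generators used across the suite.
# Everything here is written with base R only, so that the quantities the
# package computes can be checked against code that shares nothing with it.

# plug-in transfer entropy from exhaustive joint counts (base R only);
# mirrors the definition sum p(f,p,x) log[ p(f|p,x) / p(f|p) ] with
# equal-width binning over each series' observed range
oracle_te_binned <- function(source, dest, n_bins, log_base = exp(1)) {
  bin <- function(v) {
    r <- range(v)
    if (r[2] == r[1]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  }
  bf <- bin(dest)[-1]
  bp <- bin(dest)[-length(dest)]
  bx <- bin(source)[-length(source)]
  N <- length(bf)
  te <- 0
  for (key in unique(paste(bf, bp, bx))) {
    idx <- which(paste(bf, bp, bx) == key)
    n_fpx <- length(idx)
    n_fp <- sum(bf == bf[idx[1]] & bp == bp[idx[1]])
    n_px <- sum(bp == bp[idx[1]] & bx == bx[idx[1]])
    n_p <- sum(bp == bp[idx[1]])
    te <- te + n_fpx / N * log(n_fpx * n_p / (n_fp * n_px), base = log_base)
  }
  te
}

# conditional-entropy route, H(F|P) - H(F|P,X), again from scratch
oracle_te_cond_ent <- function(source, dest, n_bins, log_base = exp(1)) {
  bin <- function(v) {
    r <- range(v)
    if (r[2] == r[1]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  }
  bf <- bin(dest)[-1]
  bp <- bin(dest)[-length(dest)]
  bx <- bin(source)[-length(source)]
  N <- length(bf)
  H <- function(keys) {
    p <- table(keys) / N
    -sum(p * log(p, base = log_base))
  }
  (H(paste(bf, bp)) - H(bp)) - (H(paste(bf, bp, bx)) - H(paste(bp, bx)))
}

# chaotic 1D map, optionally driven (the unidirectional test system:
# x autonomous, y receives x)
logistic_series <- function(n, r = 3.8, x0 = runif(1, 0.2, 0.8)) {
  x <- numeric(n)
  x[1] <- x0
  for (t in 2:n) x[t] <- r * x[t - 1] * (1 - x[t - 1])
  x
}

logistic_pair <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0.2, 0.8); y[1] <- runif(1, 0.2, 0.8)
  for (t in 2:n) {
    x[t] <- x[t - 1] * (3.8 - 3.8 * x[t - 1])
    y[t] <- y[t - 1] * (3.5 - 3.5 * y[t - 1] - 0.2 * x[t - 1])
  }
  list(x = x, y = y)
}

# linear-Gaussian system y(t+1) = a y(t) + c x(t) + e with known
# transfer entropy 0.5 * log((c^2 var_x + var_e) / var_e)
gaussian_ar_pair <- function(n, a = 0.5, cc = 1, sd_x = 1, sd_e = 1) {
  x <- rnorm(n, 0, sd_x)
  y <- numeric(n)
  for (t in 1:(n - 1)) y[t + 1] <- a * y[t] + cc * x[t] + rnorm(1, 0, sd_e)
  list(x = x, y = y,
       te_true = 0.5 * log((cc^2 * sd_x^2 + sd_e^2) / sd_e^2))
}

# exact parametric trajectories for the kinematics oracles
circle_trajectory <- function(R = 1, omega = 2 * pi, rate = 60, t_end = 1) {
  tt <- seq(0, t_end, by = 1 / rate)
  tibble::tibble(t = tt, x = R * cos(omega * tt), y = R * sin(omega * tt),
                 z = 0)
}

helix_trajectory <- function(rate = 60, t_end = 2) {
  tt <- seq(0, t_end, by = 1 / rate)
  tibble::tibble(t = tt, x = cos(tt), y = sin(tt), z = tt)
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small trajectory table for pipeline-level tests
tiny_group <- function(n_pairs = 4, mode = "none", seed = 1, ...) {
  simulate_group(sim_config(coupling_mode = mode, ...),
                 n_pairs = n_pairs, seed = seed)
}
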