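# valid tuple start indices t such that the window
# {t - history + 1, ..., t, t + 1} lies within one segment.
# bounds are 0-based segment start indices; n is the series length.
.valid_tuples <- function(n, bounds = NULL, history = 1L) {
  if (is.null(bounds)) bounds <- 0L
  starts <- as.integer(bounds) + 1L          # 1-based segment starts
  ends <- c(starts[-1] - 1L, n)              # 1-based segment ends
  unlist(purrr::map2(starts, ends, function(s, e) {
    lo <- s + history - 1L
    hi <- e - 1L
    if (hi < lo) integer(0) else lo:hi
  }), use.names = FALSE)
}

#' Plug-in Shannon entropy of a binned series
#'
#' Partitions the observed range `[min, max]` into `n_bins` equal-width
#' bins, estimates the probability of each by its relative occupancy, and
#' returns the plug-in (maximum-likelihood) entropy `H = -sum(p log p)`,
#' with empty bins contributing zero. A constant series occupies one bin
#' and has `H = 0`.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @param log_base Base of the logarithm: `exp(1)` for nats (default), `2`
#'   for bits.
#' @return Entropy (scalar, >= 0).
#' @examples
#' shannon_entropy_binned(rep(c(0, 1), 500), 2)  # ~ log(2)
#' @export
shannon_entropy_binned <- function(x, n_bins, log_base = exp(1)) {
  stopifnot(length(x) >= 1, n_bins >= 2, all(is.finite(x)))
  counts <- tabulate(.bin_index(x, n_bins), nbins = n_bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p, base = log_base))
}

.bin_index <- function(x, n_bins) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(1L, length(x)))
  i <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin.int(i, n_bins)
}

.new_te_result <- function(value, estimator, n_effective, direction = NA,
                           ...) {
  structure(list(value = value, estimator = estimator,
                 n_effective = n_effective, direction = direction,
                 settings = list(...)),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  dir <- if (is.na(x$direction[1])) "" else paste0(" [", x$direction, "]")
  cat(sprintf("Transfer entropy%s: %.6g nats (%s, n_eff = %d)\n",
              dir, x$value, x$estimator, x$n_effective))
  invisible(x)
}

#' Transfer entropy by the binning (plug-in) estimator
#'
#' Estimates the transfer entropy from `source` to `dest` with destination
#' history length 1: the information the source's present adds about the
#' destination's next value beyond the destination's own present. Both
#' series are partitioned into `n_bins` equal-width bins over their own
#' observed ranges; the estimate is the plug-in functional of the joint
#' occupancy counts of `(y(t+1), y(t), x(t))`. It is algebraically equal to
#' the difference of conditional entropies
#' `H(Y(t+1) | Y(t)) - H(Y(t+1) | Y(t), X(t))`; `form = "conditional"`
#' computes it that way as an internal cross-check. Tuples whose
#' `(t, t+1)` transition crosses a segment boundary of a concatenated
#' ensemble are excluded.
#'
#' @param source,dest Numeric vectors of equal length (>= 3). The binning
#'   estimator is univariate.
#' @param n_bins Bins per variable (default 8).
#' @param bounds Optional 0-based segment start indices (as stored on a
#'   [build_ensemble()] result) marking concatenation joins.
#' @param log_base `exp(1)` for nats, `2` for bits.
#' @param form `"direct"` (joint-count plug-in of the TE sum) or
#'   `"conditional"` (difference of conditional entropies).
#' @return A `te_result`; its `value` is nonnegative.
#' @export
transfer_entropy_binned <- function(source, dest, n_bins = 8, bounds = NULL,
                                    log_base = exp(1),
                                    form = c("direct", "conditional")) {
  form <- match.arg(form)
  if (!is.null(dim(source)) || !is.null(dim(dest)))
    abort("the binning estimator accepts univariate series only")
  n <- length(dest)
  stopifnot(length(source) == n, n >= 3)
  tt <- .valid_tuples(n, bounds, history = 1L)
  if (length(tt) < 2) abort("insufficient data: fewer than 2 valid tuples")
  bf <- .bin_index(dest, n_bins)[tt + 1L]   # y(t+1)
  bp <- .bin_index(dest, n_bins)[tt]        # y(t)
  bx <- .bin_index(source, n_bins)[tt]      # x(t)
  N <- length(tt)
  tup <- tibble(f = bf, p = bp, x = bx)
  if (form == "direct") {
    tab <- dplyr::count(tup, .data$f, .data$p, .data$x, name = "n_fpx")
    tab <- dplyr::left_join(tab, dplyr::count(tup, .data$f, .data$p,
                                              name = "n_fp"),
                            by = c("f", "p"))
    tab <- dplyr::left_join(tab, dplyr::count(tup, .data$p, .data$x,
                                              name = "n_px"),
                            by = c("p", "x"))
    tab <- dplyr::left_join(tab, dplyr::count(tup, .data$p, name = "n_p"),
                            by = "p")
    te <- sum(tab$n_fpx / N *
                log(tab$n_fpx * tab$n_p / (tab$n_fp * tab$n_px),
                    base = log_base))
  } else {
    hent <- function(counts) {
      pr <- counts / N
      -sum(pr * log(pr, base = log_base))
    }
    te <- (hent(dplyr::count(tup, .data$f, .data$p)$n) -
             hent(dplyr::count(tup, .data$p)$n)) -
          (hent(dplyr::count(tup, .data$f, .data$p, .data$x)$n) -
             hent(dplyr::count(tup, .data$p, .data$x)$n))
  }
  .new_te_result(max(te, 0), "binning", N, n_bins = n_bins,
                 log_base = log_base, form = form)
}

# assemble (F, P, X) tuple blocks for KSG from (possibly multivariate)
# series, applying segment-boundary and history validity
.ksg_blocks <- function(source, dest, bounds, history) {
  src <- as.matrix(source); dst <- as.matrix(dest)
  n <- nrow(dst)
  if (nrow(src) != n) abort("source and dest must have equal length")
  tt <- .valid_tuples(n, bounds, history = as.integer(history))
  Fm <- dst[tt + 1L, , drop = FALSE]
  Pm <- do.call(cbind, purrr::map(0:(history - 1),
                                  ~ dst[tt - .x, , drop = FALSE]))
  Xm <- src[tt, , drop = FALSE]
  list(F = Fm, P = Pm, X = Xm, t = tt)
}

#' Transfer entropy by the KSG nearest-neighbour estimator
#'
#' Estimates transfer entropy as the Kraskov-Stoegbauer-Grassberger
#' (algorithm 1) conditional mutual information
#' `I(Y(t+1); X(t) | Y(t))`: for each tuple, the max-norm distance to its
#' `k`-th nearest neighbour in the joint space sets a local resolution;
#' neighbours strictly within that radius are counted in the marginal
#' spaces `(Y(t+1), Y(t))`, `(Y(t), X(t))` and `(Y(t))`, and
#' `TE = digamma(k) + < digamma(n_y + 1) - digamma(n_y,future + 1) -
#' digamma(n_y,x + 1) >`. Estimates are reported as computed and may be
#' slightly negative; significance is judged against the shuffled-partner
#' control, not by sign. Values are in nats.
#'
#' Source and destination may each be univariate or multivariate (e.g. 3D
#' velocity). A seeded uniform tie-breaking noise of amplitude `tie_noise`
#' is added to every coordinate before the neighbour searches (standard KSG
#' practice for repeated values; drawn from the current RNG stream).
#'
#' @param source,dest Numeric vectors or matrices (rows = time).
#' @param k Neighbour count (default 8).
#' @param bounds Optional 0-based segment start indices.
#' @param history Destination history length (default 1).
#' @param tie_noise Amplitude of the tie-breaking noise (0 disables).
#' @return A `te_result` (value in nats).
#' @examples
#' set.seed(1)
#' x <- rnorm(2000)
#' y <- c(0, 0.5 * 0 + x[-2000]) + rnorm(2000)  # y(t+1) ~ x(t)
#' transfer_entropy_ksg(x, y, k = 4)
#' @export
transfer_entropy_ksg <- function(source, dest, k = 8, bounds = NULL,
                                 history = 1, tie_noise = 1e-10) {
  res <- knn_sweep(source, dest, k_values = k, bounds = bounds,
                   history = history, tie_noise = tie_noise)
  attr(res, "results")[[1]]
}

#' Sensitivity sweep of KSG transfer entropy over the neighbour count
#'
#' Recomputes the KSG transfer entropy for each `k` in `k_values` on the
#' same data and boundary mask. All `k` share one pair of O(n^2) neighbour
#' passes, so the sweep costs little more than a single estimate. The
#' default grid is `2:15`.
#'
#' @inheritParams transfer_entropy_ksg
#' @param k_values Integer vector of neighbour counts (each >= 1).
#' @return A tibble of class `te_sweep` with columns `k, te, n_effective`,
#'   and a list-column-free attribute `results` (the `te_result` objects).
#' @export
knn_sweep <- function(source, dest, k_values = 2:15, bounds = NULL,
                      history = 1, tie_noise = 1e-10) {
  stopifnot(length(k_values) >= 1, all(k_values >= 1))
  ks <- sort(unique(as.integer(k_values)))
  bl <- .ksg_blocks(source, dest, bounds, history)
  n_eff <- nrow(bl$F)
  if (n_eff <= max(ks) + 1)
    abort(paste0("insufficient data: ", n_eff, " tuples for k = ",
                 max(ks)))
  if (tie_noise > 0) {
    jig <- function(M) M + matrix(runif(length(M), -tie_noise / 2,
                                        tie_noise / 2), nrow(M))
    bl$F <- jig(bl$F); bl$P <- jig(bl$P); bl$X <- jig(bl$X)
  }
  cnt <- .ksg_counts(bl$F, bl$P, bl$X, ks)
  res <- purrr::map(seq_along(ks), function(q) {
    te <- digamma(ks[q]) + mean(digamma(cnt$n_p[, q] + 1) -
                                digamma(cnt$n_fp[, q] + 1) -
                                digamma(cnt$n_px[, q] + 1))
    .new_te_result(te, "ksg", n_eff, k = ks[q], history = history,
                   tie_noise = tie_noise)
  })
  out <- tibble(k = ks, te = purrr::map_dbl(res, "value"),
                n_effective = n_eff)
  class(out) <- c("te_sweep", class(out))
  attr(out, "results") <- res
  out
}
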