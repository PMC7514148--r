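#' Delay-embed a series into its shadow manifold
#'
#' Builds the E-dimensional delay vectors
#' `(x(t), x(t - tau), ..., x(t - (E-1) tau))` for every time index `t`
#' whose whole lag window lies inside one segment of a (possibly
#' concatenated) series. The set of these points reconstructs the
#' attractor of the system generating `x` (its shadow manifold).
#'
#' @param x Numeric vector (univariate series, possibly a concatenated
#'   ensemble).
#' @param E Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1, default 1).
#' @param bounds Optional 0-based segment start indices.
#' @return An object of class `shadow_manifold`: list with `points`
#'   (m-by-E matrix), `time_index` (the `t` of each point), `E`, `tau`,
#'   `n_series`, `bounds`.
#' @export
build_shadow_manifold <- function(x, E, tau = 1, bounds = NULL) {
  stopifnot(E >= 1, tau >= 1)
  n <- length(x)
  if (n <= (E - 1) * tau) abort("series too short for this embedding")
  if (is.null(bounds)) bounds <- 0L
  starts <- as.integer(bounds) + 1L
  ends <- c(starts[-1] - 1L, n)
  tt <- unlist(purrr::map2(starts, ends, function(s, e) {
    lo <- s + (E - 1L) * tau
    if (e < lo) integer(0) else lo:e
  }), use.names = FALSE)
  if (length(tt) == 0) abort("insufficient data: no valid embedded points")
  pts <- vapply(0:(E - 1), function(j) x[tt - j * tau], numeric(length(tt)))
  pts <- matrix(pts, ncol = E)
  structure(list(points = pts, time_index = tt, E = E, tau = tau,
                 n_series = n, bounds = as.integer(bounds)),
            class = "shadow_manifold")
}

#' @export
print.shadow_manifold <- function(x, ...) {
  cat(sprintf("Shadow manifold: %d points, E = %d, tau = %d (series n = %d)\n",
              nrow(x$points), x$E, x$tau, x$n_series))
  invisible(x)
}

#' Choose the embedding dimension by simplex projection
#'
#' For each candidate `E`, delay-embeds the series, forecasts every point's
#' value one step ahead from the exponentially weighted average of its
#' `E + 1` nearest neighbours' futures (leave-self-out), and scores the
#' forecast by the Pearson correlation with the observed values. Returns
#' the `E` with the highest forecast skill (smallest `E` on ties).
#'
#' @param x Numeric series.
#' @param E_grid Candidate dimensions (default `1:10`).
#' @param tau Delay in samples.
#' @param bounds Optional 0-based segment start indices.
#' @param tp Forecast horizon in samples (default 1).
#' @param min_points Minimum embedded points required for every candidate.
#' @return A list of class `embedding_selection` with `E` (the choice) and
#'   `skills` (tibble of `E`, `skill`).
#' @export
select_embedding_dim <- function(x, E_grid = 1:10, tau = 1, bounds = NULL,
                                 tp = 1, min_points = 20) {
  stopifnot(length(E_grid) >= 1, all(E_grid >= 1))
  E_grid <- sort(unique(as.integer(E_grid)))
  n <- length(x)
  feas <- E_grid[(n - (E_grid - 1) * tau) >= min_points]
  if (length(feas) < length(E_grid))
    abort(paste0("series too short for the E grid; maximum feasible E is ",
                 if (length(feas)) max(feas) else "none"))
  skills <- purrr::map_dbl(E_grid, function(E) {
    mf <- build_shadow_manifold(x, E, tau, bounds)
    # points with a same-segment future tp ahead
    ok <- .future_in_segment(mf$time_index, tp, mf$n_series, mf$bounds)
    if (sum(ok) < min_points)
      abort(paste0("fewer than ", min_points, " forecastable points at E = ",
                   E))
    idx <- which(ok)
    target <- rep(NA_real_, nrow(mf$points))
    target[idx] <- x[mf$time_index[idx] + tp]
    est <- .xmap_estimate(mf$points, target, idx, idx, mf$time_index,
                          E + 1L, 0L)
    obs <- x[mf$time_index[idx] + tp]
    if (sd(est) == 0 || sd(obs) == 0) 0 else cor(obs, est)
  })
  best <- E_grid[which.max(skills)]
  if (max(skills) < 0.1)
    inform(paste0("low forecast skill at every E (max ",
                  sprintf("%.3f", max(skills)),
                  "); series may be unforecastable"))
  structure(list(E = best, skills = tibble(E = E_grid, skill = skills)),
            class = "embedding_selection")
}

#' @export
print.embedding_selection <- function(x, ...) {
  cat(sprintf("Simplex projection: selected E = %d (skill %.3f)\n", x$E,
              x$skills$skill[x$skills$E == x$E]))
  invisible(x)
}

.future_in_segment <- function(tidx, tp, n, bounds) {
  starts <- as.integer(bounds) + 1L
  ends <- c(starts[-1] - 1L, n)
  seg_end <- ends[findInterval(tidx, starts)]
  tidx + tp <= seg_end
}

#' Cross-map estimate of one series from another's shadow manifold
#'
#' For each manifold point of the (putative) effect series, finds its
#' `E + 1` nearest neighbours within the library (always excluding the
#' point itself, optionally a Theiler window of temporal neighbours),
#' weights them by `u_i = exp(-d_i / d_1)` normalised to sum to one, and
#' estimates the target series at the corresponding times. The skill is
#' the Pearson correlation between target and estimate; negative
#' correlations are clipped to zero (an anti-correlated estimate carries no
#' usable cross-map information), so skill lies in `[0, 1]`.
#'
#' @param manifold A `shadow_manifold` of the series believed to carry the
#'   imprint (the effect).
#' @param target Numeric vector, sample-aligned with the manifold's source
#'   series: the series to be estimated (the putative cause).
#' @param lib Optional integer indices (into the manifold's points) forming
#'   the library; default all points.
#' @param pred Optional indices of points to estimate at; default all.
#' @param exclude_radius Theiler exclusion: library points within this many
#'   samples of the prediction point's time index are skipped (0 =
#'   self-exclusion only).
#' @return The skill (scalar in `[0, 1]`) with attributes
#'   `raw_correlation` and `n_pred`.
#' @export
cross_map_skill <- function(manifold, target, lib = NULL, pred = NULL,
                            exclude_radius = 0) {
  stopifnot(inherits(manifold, "shadow_manifold"))
  m <- nrow(manifold$points)
  if (length(target) != manifold$n_series)
    abort("target must be sample-aligned with the manifold's source series")
  if (is.null(lib)) lib <- seq_len(m)
  if (is.null(pred)) pred <- seq_len(m)
  nnbr <- manifold$E + 1L
  if (length(lib) < manifold$E + 2L)
    abort("insufficient data: library smaller than E + 2 points")
  tvals <- target[manifold$time_index]
  est <- .xmap_estimate(manifold$points, tvals, as.integer(lib),
                        as.integer(pred), manifold$time_index, nnbr,
                        as.integer(exclude_radius))
  obs <- tvals[pred]
  ok <- is.finite(est) & is.finite(obs)
  r <- if (sum(ok) < 3 || sd(est[ok]) == 0 || sd(obs[ok]) == 0) 0
       else cor(obs[ok], est[ok])
  structure(max(r, 0), raw_correlation = r, n_pred = sum(ok))
}

#' Convergent cross mapping with a library-size sweep
#'
#' Runs CCM in both directions between two sample-aligned series. The
#' direction label follows the cause-recovery convention:
#' `C_{A->B}` is the (clipped) skill of estimating series A from the
#' shadow manifold of series B -- if A drives B, A's values are recoverable
#' from B's manifold, so a high `C_{A->B}` is evidence that A is the cause.
#'
#' For each library size `L`, the skill is averaged over sequential
#' windows of length `L` (`n - L + 1` of them for a series of length `n`;
#' above `window_cap` windows a uniform random subsample is used). The
#' library is restricted to manifold points inside the window; predictions
#' are made at all manifold points. The headline value is the mean skill at
#' the largest library size, annotated with a convergence diagnostic from
#' [assess_convergence()].
#'
#' @param series_a,series_b Numeric vectors of equal length (aligned, e.g.
#'   the two agents of a [build_ensemble()] result).
#' @param E_a,E_b Embedding dimensions; selected per series by
#'   [select_embedding_dim()] when `NULL`.
#' @param tau Delay in samples.
#' @param lib_sizes Library-size grid; default 10 log-spaced sizes from
#'   `max(20, 10 E)` to the usable length.
#' @param bounds Optional 0-based segment start indices (shared).
#' @param window_cap Maximum number of windows averaged per `L`.
#' @param E_grid Grid for automatic `E` selection.
#' @param convergence_tol Tolerance of the convergence diagnostic.
#' @return An object of class `ccm_result`: per direction, the `lib_sizes`
#'   grid, mean `skills`, `skill_at_lmax`, `E` and `convergence`; plus the
#'   direction `convention` string.
#' @export
ccm_sweep <- function(series_a, series_b, E_a = NULL, E_b = NULL, tau = 1,
                      lib_sizes = NULL, bounds = NULL, window_cap = 200,
                      E_grid = 1:10, convergence_tol = 0.02) {
  n <- length(series_a)
  stopifnot(length(series_b) == n)
  if (is.null(E_a)) E_a <- select_embedding_dim(series_a, E_grid, tau,
                                                bounds)$E
  if (is.null(E_b)) E_b <- select_embedding_dim(series_b, E_grid, tau,
                                                bounds)$E
  one_dir <- function(target_series, manifold_series, E, label) {
    mf <- build_shadow_manifold(manifold_series, E, tau, bounds)
    Ls <- lib_sizes
    if (is.null(Ls)) {
      lmin <- max(20, 10 * E)
      Ls <- unique(round(exp(seq(log(min(lmin, n)), log(n),
                                 length.out = 10))))
    }
    Ls <- sort(unique(pmin(Ls, n)))
    usable <- Ls[Ls >= E + 2]
    if (length(usable) < length(Ls))
      warn("dropped library sizes smaller than the embedding minimum")
    n_windows <- integer(length(usable))
    skills <- purrr::map_dbl(seq_along(usable), function(li) {
      L <- usable[li]
      n_win <- as.integer(n - L + 1)
      n_windows[li] <<- n_win
      wins <- seq_len(n_win)
      if (n_win > window_cap) wins <- sort(sample(wins, window_cap))
      vals <- purrr::map_dbl(wins, function(w) {
        lib <- which(mf$time_index >= w + (E - 1) * tau &
                       mf$time_index <= w + L - 1)
        if (length(lib) < E + 2) return(NA_real_)
        as.numeric(cross_map_skill(mf, target_series, lib = lib))
      })
      mean(vals, na.rm = TRUE)
    })
    list(direction = label, E = E, tau = tau, lib_sizes = usable,
         skills = skills, n_windows = n_windows,
         skill_at_lmax = skills[length(skills)],
         convergence = assess_convergence(skills, tol = convergence_tol))
  }
  structure(list(
    a_to_b = one_dir(series_a, series_b, E_b, "A->B"),
    b_to_a = one_dir(series_b, series_a, E_a, "B->A"),
    convention = paste("C_{A->B} = skill of estimating A from the shadow",
                       "manifold of B (cause recovered from effect)"),
    n = n), class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat("Convergent cross mapping (", x$convention, ")\n", sep = "")
  for (d in list(x$a_to_b, x$b_to_a))
    cat(sprintf("  C_{%s}: skill %.3f at L = %d (E = %d, %s)\n",
                d$direction, d$skill_at_lmax, max(d$lib_sizes), d$E,
                d$convergence))
  invisible(x)
}

#' Classify the library-size convergence of a cross-map sweep
#'
#' CCM's evidence criterion is that skill converges as the library grows.
#' Given the mean skills over an increasing library grid: `"converged"` if
#' the last two values differ by less than `tol` and the trend is
#' nondecreasing within `tol`; `"increasing"` if the skill is still rising
#' at the largest library; `"flat"` otherwise (tail settled but the trend
#' was not monotone within tolerance).
#'
#' @param skills Numeric vector of mean skills, ordered by library size
#'   (at least 3), or a `ccm_result` direction list.
#' @param tol Tolerance (default 0.02).
#' @return One of `"converged"`, `"increasing"`, `"flat"`.
#' @export
assess_convergence <- function(skills, tol = 0.02) {
  if (is.list(skills)) skills <- skills$skills
  if (length(skills) < 3) return(NA_character_)
  tail_diff <- skills[length(skills)] - skills[length(skills) - 1]
  if (tail_diff >= tol) return("increasing")
  if (all(diff(skills) > -tol)) "converged" else "flat"
}
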