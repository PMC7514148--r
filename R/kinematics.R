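#' Spline-resample one trajectory and differentiate analytically
#'
#' Fits an interpolating cubic spline independently through each coordinate
#' of a timestamped 3D trajectory and evaluates position, velocity and
#' acceleration on a uniform grid at `resample_rate`. Velocity and
#' acceleration are the first and second analytic derivatives of the spline,
#' not finite differences. Curvature is computed from them via
#' [compute_curvature()].
#'
#' The uniform grid has spacing `1/resample_rate` and is phase-anchored at
#' `anchor` (grid times are `anchor + k/resample_rate` for integer `k`),
#' covering the full span of the input times. Anchoring both members of a
#' pair at the same instant makes their grids sample-aligned.
#'
#' @param trajectory Data frame with columns `t, x, y, z` for a single
#'   agent: time in seconds (strictly increasing, at least 4 samples) and
#'   coordinates in meters.
#' @param resample_rate Target rate in Hz (default 180).
#' @param anchor Grid phase anchor in seconds; defaults to the first sample
#'   time.
#' @param speed_floor Speed (m/s) below which curvature is marked invalid at
#'   a sample (`curvature_valid = FALSE`) rather than divided through.
#' @return A tibble with columns `t, x, y, z, vx, vy, vz, ax, ay, az, speed,
#'   curvature, curvature_valid`.
#' @examples
#' tr <- tibble::tibble(t = seq(0, 1, by = 1/60),
#'                      x = cos(2 * pi * seq(0, 1, by = 1/60)),
#'                      y = sin(2 * pi * seq(0, 1, by = 1/60)), z = 0)
#' kin <- fit_spline_and_resample(tr, 180)
#' mean(kin$curvature)  # circle of radius 1 -> about 1
#' @export
fit_spline_and_resample <- function(trajectory, resample_rate = 180,
                                    anchor = NULL, speed_floor = 1e-6) {
  req <- c("t", "x", "y", "z")
  if (!all(req %in% names(trajectory)))
    abort("trajectory needs columns t, x, y, z")
  tt <- trajectory$t
  if (length(tt) < 4)
    abort("unusable trajectory: a cubic spline needs at least 4 samples")
  if (any(diff(tt) <= 0))
    abort("trajectory times must be strictly increasing")
  coords <- as.matrix(trajectory[, c("x", "y", "z")])
  if (!all(is.finite(tt)) || !all(is.finite(coords)))
    abort("trajectory times and coordinates must be finite")
  stopifnot(resample_rate > 0)
  if (is.null(anchor)) anchor <- tt[1]

  k0 <- ceiling((tt[1] - anchor) * resample_rate - 1e-9)
  k1 <- floor((tt[length(tt)] - anchor) * resample_rate + 1e-9)
  if (k1 < k0) abort("resample grid is empty over the trajectory span")
  grid <- anchor + (k0:k1) / resample_rate

  pos <- vel <- acc <- matrix(0, length(grid), 3)
  for (j in 1:3) {
    # "fmm" end condition: exact cubic through the boundary points, so
    # trajectories that are polynomials of degree <= 3 are reproduced
    # exactly, derivatives included
    f <- splinefun(tt, coords[, j], method = "fmm")
    pos[, j] <- f(grid)
    vel[, j] <- f(grid, deriv = 1)
    acc[, j] <- f(grid, deriv = 2)
  }
  curv <- compute_curvature(vel, acc, speed_floor = speed_floor)
  tibble(t = grid,
         x = pos[, 1], y = pos[, 2], z = pos[, 3],
         vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
         ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
         speed = curv$speed, curvature = curv$curvature,
         curvature_valid = curv$valid)
}

#' Trajectory curvature from velocity and acceleration
#'
#' Decomposes the acceleration at each sample into tangential and normal
#' components and forms the curvature:
#' `a_t = (a.v / |v|^2) v`, `a_n = a - a_t`, `rho = |a_n| / |v|^2` (units
#' 1/m). Curvature is nonnegative and equals `1/R` on a circle of radius
#' `R`. Samples with speed below `speed_floor` are flagged invalid (the
#' ratio would blow up) and carry `NA` curvature; downstream ensemble
#' construction drops them.
#'
#' @param velocity,acceleration Numeric n-by-3 matrices (m/s and m/s^2).
#' @param speed_floor Validity floor on speed in m/s.
#' @return A list with `curvature` (1/m, `NA` where invalid), `speed`,
#'   `tangential` and `normal` acceleration matrices, and logical `valid`.
#' @export
compute_curvature <- function(velocity, acceleration, speed_floor = 1e-6) {
  v <- as.matrix(velocity); a <- as.matrix(acceleration)
  stopifnot(ncol(v) == 3, ncol(a) == 3, nrow(v) == nrow(a))
  sp2 <- rowSums(v^2)
  sp <- sqrt(sp2)
  valid <- sp > speed_floor
  coef <- ifelse(valid, rowSums(a * v) / sp2, 0)
  a_t <- v * coef
  a_n <- a - a_t
  rho <- ifelse(valid, sqrt(rowSums(a_n^2)) / sp2, NA_real_)
  list(curvature = rho, speed = sp, tangential = a_t, normal = a_n,
       valid = valid)
}

#' Resample a group of pairs to uniform-rate kinematics
#'
#' Applies [fit_spline_and_resample()] to every (pair, agent) trajectory in
#' a trajectory table. Within each pair both agents' grids are anchored at
#' the start of the pair's co-presence window (the intersection of the two
#' raw time spans), so the grids are sample-aligned and [extract_overlap()]
#' can trim by simple index matching. Pairs whose raw spans do not intersect
#' are dropped with a warning.
#'
#' @param trajectories Trajectory tibble (`pair_id, agent, t, x, y, z,
#'   behavior`).
#' @inheritParams fit_spline_and_resample
#' @return A kinematics tibble: `pair_id, agent, behavior` plus the columns
#'   of [fit_spline_and_resample()], with attribute `resample_rate`.
#' @export
compute_kinematics <- function(trajectories, resample_rate = 180,
                               speed_floor = 1e-6) {
  split_df <- dplyr::group_split(dplyr::group_by(trajectories, .data$pair_id))
  out <- purrr::map(split_df, function(df) {
    pid <- df$pair_id[1]
    agents <- sort(unique(df$agent))
    if (!identical(as.integer(agents), c(1L, 2L))) {
      warn(paste0("pair ", pid, " does not have exactly agents 1 and 2; ",
                  "skipped"))
      return(NULL)
    }
    d1 <- df[df$agent == 1L, ]; d2 <- df[df$agent == 2L, ]
    t_start <- max(min(d1$t), min(d2$t))
    t_end <- min(max(d1$t), max(d2$t))
    if (t_end <= t_start) {
      warn(paste0("pair ", pid, " excluded: agents' time spans do not ",
                  "overlap"))
      return(NULL)
    }
    purrr::map2(list(d1, d2), 1:2, function(d, ag) {
      kin <- fit_spline_and_resample(d, resample_rate, anchor = t_start,
                                     speed_floor = speed_floor)
      dplyr::bind_cols(tibble(pair_id = pid, agent = ag,
                              behavior = d$behavior[1]), kin)
    })
  })
  res <- dplyr::bind_rows(purrr::compact(purrr::flatten(out)))
  if (nrow(res) == 0) abort("no analyzable pairs")
  attr(res, "resample_rate") <- resample_rate
  res
}

#' Trim each pair to its co-presence window
#'
#' Keeps, per pair, only the samples where both agents are present: the
#' intersection of the two agents' resampled time spans. Because
#' [compute_kinematics()] anchors both grids at the overlap start, the
#' retained samples align one-to-one and both agents end up with equal
#' length. Pairs with an empty intersection are dropped with a warning.
#' The operation is idempotent.
#'
#' @param kinematics A kinematics tibble from [compute_kinematics()].
#' @return The trimmed kinematics tibble (attribute `resample_rate` kept).
#' @export
extract_overlap <- function(kinematics) {
  rate <- attr(kinematics, "resample_rate")
  if (is.null(rate)) rate <- 1 / stats::median(diff(
    kinematics$t[kinematics$agent == kinematics$agent[1]]))
  split_df <- dplyr::group_split(dplyr::group_by(kinematics, .data$pair_id))
  out <- purrr::map(split_df, function(df) {
    pid <- df$pair_id[1]
    d1 <- df[df$agent == 1L, ]; d2 <- df[df$agent == 2L, ]
    t_start <- max(min(d1$t), min(d2$t))
    t_end <- min(max(d1$t), max(d2$t))
    if (t_end < t_start - 1e-9) {
      warn(paste0("pair ", pid, " excluded: no co-presence window"))
      return(NULL)
    }
    k1 <- round((d1$t - t_start) * rate)
    k2 <- round((d2$t - t_start) * rate)
    keep <- intersect(k1[k1 >= 0 & d1$t <= t_end + 1e-9],
                      k2[k2 >= 0 & d2$t <= t_end + 1e-9])
    if (length(keep) == 0) {
      warn(paste0("pair ", pid, " excluded: no aligned overlap samples"))
      return(NULL)
    }
    dplyr::bind_rows(d1[match(keep, k1), ], d2[match(keep, k2), ])
  })
  res <- dplyr::bind_rows(purrr::compact(out))
  if (nrow(res) == 0) abort("no pair retains a co-presence window")
  attr(res, "resample_rate") <- rate
  res
}

#' Build a concatenated, normalized ensemble from overlap-trimmed pairs
#'
#' Concatenates the chosen variable across pairs (ascending `pair_id`),
#' independently for agent 1 and agent 2, recording where each pair's
#' segment starts so that estimators can refuse to treat the joint between
#' two unrelated flights as a dynamical transition. Samples flagged invalid
#' (sub-floor speed) in either agent are dropped from both, preserving the
#' within-pair alignment. The ensemble is then normalized to zero mean and
#' unit (sample) variance per agent series -- per dimension for the 3D
#' velocity variable -- either globally over the whole ensemble (default) or
#' per segment.
#'
#' @param kinematics Overlap-trimmed kinematics (see [extract_overlap()]).
#' @param variable `"curvature"` (1D) or `"velocity"` (3D).
#' @param normalize `"global"`, `"per_segment"`, or `"none"`.
#' @return A tibble of class `flight_ensemble` with columns `pair_id,
#'   agent, segment, idx` and value column(s) (`value`, or `vx, vy, vz`),
#'   and attributes `segment_bounds` (0-based start index of each pair's
#'   contribution), `variable`, `normalized`, `segment_lengths`.
#' @export
build_ensemble <- function(kinematics,
                           variable = c("curvature", "velocity"),
                           normalize = c("global", "per_segment", "none")) {
  variable <- match.arg(variable)
  normalize <- match.arg(normalize)
  pids <- sort(unique(kinematics$pair_id))
  cols <- if (variable == "curvature") "curvature" else c("vx", "vy", "vz")
  # index rows once per (pair, agent); the loop below only shuffles indices
  row_idx <- split(seq_len(nrow(kinematics)),
                   list(kinematics$agent, kinematics$pair_id), drop = TRUE)
  keep1 <- list(); keep2 <- list(); lens <- integer(0); used <- character(0)
  for (pid in pids) {
    i1 <- row_idx[[paste(1, pid, sep = ".")]]
    i2 <- row_idx[[paste(2, pid, sep = ".")]]
    if (length(i1) != length(i2))
      abort(paste0("pair ", pid, " has unequal agent lengths; run ",
                   "extract_overlap() first"))
    keep <- kinematics$curvature_valid[i1] & kinematics$curvature_valid[i2]
    if (!all(keep))
      inform(paste0("pair ", pid, ": dropped ", sum(!keep),
                    " sub-floor-speed samples"))
    if (!any(keep)) next
    keep1[[pid]] <- i1[keep]; keep2[[pid]] <- i2[keep]
    lens <- c(lens, sum(keep)); used <- c(used, pid)
  }
  if (length(used) == 0) abort("no usable samples in any pair")
  bounds <- cumsum(c(0L, head(lens, -1)))
  ord <- c(unlist(keep1, use.names = FALSE), unlist(keep2, use.names = FALSE))
  half <- tibble(pair_id = rep(used, lens),
                 segment = rep(seq_along(used), lens),
                 idx = unlist(lapply(lens, seq_len), use.names = FALSE))
  ens <- dplyr::bind_rows(half, half)
  ens$agent <- rep(1:2, each = nrow(half))
  for (j in seq_along(cols))
    ens[[if (variable == "curvature") "value" else cols[j]]] <-
      kinematics[[cols[j]]][ord]
  ens <- ens[, c("pair_id", "agent", "segment", "idx",
                 if (variable == "curvature") "value" else cols)]
  attr(ens, "segment_bounds") <- bounds
  attr(ens, "segment_lengths") <- lens
  attr(ens, "variable") <- variable
  attr(ens, "normalized") <- FALSE
  class(ens) <- c("flight_ensemble", class(ens))
  if (normalize != "none") ens <- normalize_ensemble(ens, scope = normalize)
  ens
}

#' Standardize an ensemble to zero mean and unit variance
#'
#' Centers and scales each agent's concatenated series (per dimension for
#' 3D variables), either over the whole ensemble (`"global"`) or within
#' each pair's segment (`"per_segment"`). Uses the sample (n-1) variance.
#'
#' @param ensemble A `flight_ensemble` from [build_ensemble()].
#' @param scope `"global"` or `"per_segment"`.
#' @return The normalized ensemble (attribute `normalized = TRUE`).
#' @export
normalize_ensemble <- function(ensemble, scope = c("global", "per_segment")) {
  scope <- match.arg(scope)
  cols <- intersect(c("value", "vx", "vy", "vz"), names(ensemble))
  zstd <- function(x, where) {
    if (length(x) < 2) abort(paste0("cannot normalize ", where,
                                    ": fewer than 2 samples"))
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      abort(paste0("zero variance in normalization scope: ", where))
    (x - mean(x)) / s
  }
  grp <- if (scope == "global") list(ensemble$agent)
         else list(ensemble$agent, ensemble$segment)
  for (cl in cols) {
    ensemble[[cl]] <- unsplit(lapply(
      split(seq_len(nrow(ensemble)), grp), function(ii) {
        where <- paste0("agent ", ensemble$agent[ii[1]],
                        if (scope == "per_segment")
                          paste0(", segment ", ensemble$segment[ii[1]]),
                        ", ", cl)
        zstd(ensemble[[cl]][ii], where)
      }), grp)
  }
  attr(ensemble, "normalized") <- TRUE
  attr(ensemble, "normalize_scope") <- scope
  ensemble
}

#' Extract one agent's series and boundary bookkeeping from an ensemble
#'
#' @param ensemble A `flight_ensemble`.
#' @param agent 1 or 2.
#' @return A numeric vector (curvature) or n-by-3 matrix (velocity); the
#'   ensemble's 0-based `segment_bounds` are attached as attribute
#'   `segment_bounds`.
#' @export
ensemble_series <- function(ensemble, agent) {
  stopifnot(agent %in% 1:2)
  d <- ensemble[ensemble$agent == agent, ]
  out <- if (attr(ensemble, "variable") == "curvature") d$value
         else as.matrix(d[, c("vx", "vy", "vz")])
  attr(out, "segment_bounds") <- attr(ensemble, "segment_bounds")
  out
}
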