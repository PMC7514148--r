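#' Configuration for the coupled flight-pair simulator
#'
#' Bundles the parameters of the self-propelled-particle test bed. Each
#' agent flies at constant speed. Its own steering is an
#' Ornstein--Uhlenbeck angular-velocity process (diffusion intensity
#' `noise`, correlation time `turning_persistence`) modulated by a
#' two-state burst envelope (maneuver bouts versus cruising), so turning
#' happens in smooth, episodic arcs. The heading additionally relaxes
#' toward a shared straight corridor axis with gain `corridor_gain`
#' (environmental forcing common to both agents, with no information
#' exchange), and the position integrates the heading at constant speed.
#' Integration uses internal substeps so that the sampled positions lie on
#' a genuinely smooth path and spline differentiation recovers the true
#' curvature.
#'
#' Directed coupling is turn matching: a listening agent's applied angular
#' velocity is the convex combination `(own + c * partner) / (1 + c)` of
#' its own steering and the partner's applied steering observed `delay`
#' seconds earlier, with dimensionless mixing weight
#' `c = gain * turning_persistence` (relaxation at rate `gain` over one
#' turning correlation time). A strongly coupled agent therefore turns
#' like a delayed copy of its partner -- the partner's turning signal is
#' written directly into the listener's curvature, the variable the
#' coupling analyses read -- without exceeding realistic turn rates.
#'
#' Agent 1 is the front agent (it enters the observation volume first);
#' agent 2 enters `entry_delay` seconds later. `front_to_rear` therefore
#' means the front agent's turning drives the rear agent's;
#' `rear_to_front` the reverse. Both agents of a pair enter near the same
#' point (a pair-common lateral offset from the corridor axis plus an
#' individual offset of scale `separation`), so the corridor restoring
#' force gives the two flight paths a shared, interaction-free similarity
#' -- the environmental channel the shuffled-partner control is designed
#' to absorb.
#'
#' @param duration Flight duration per agent in seconds. Default 1.3 s,
#'   matching the typical flight duration of the field recordings the
#'   simulator emulates (median about 1.26 s).
#' @param sample_rate Native sampling rate in Hz (time step
#'   `1/sample_rate`).
#' @param speed Flight speed in m/s (constant per agent).
#' @param noise Heading diffusion intensity in rad/sqrt(s); over times
#'   long compared with `turning_persistence` the heading diffuses with
#'   this intensity.
#' @param turning_persistence Correlation time (s) of the angular-velocity
#'   process: turning happens in smooth arcs, not white jitter.
#' @param coupling_mode One of `"none"`, `"front_to_rear"`,
#'   `"rear_to_front"`, `"bidirectional"`.
#' @param gain Coupling gain in 1/s; the dimensionless mixing weight of
#'   the partner's steering in the listener's applied turning is
#'   `gain * turning_persistence` (default gain 35, persistence 0.35 s,
#'   weight about 12 -- a strongly following regime).
#' @param delay Sensorimotor coupling delay in seconds (default 0.05 s).
#' @param corridor_gain Strength of the shared environment: the gain
#'   (1/s) of the relaxation toward the corridor axis, and the scale of a
#'   slow pair-common steering disturbance (the two agents fly through the
#'   same air column and respond to the same transient features at the
#'   same moment). The disturbance is what makes the two curvature series
#'   of an uncoupled pair positively correlated; it carries no
#'   agent-to-agent information.
#' @param entry_delay Seconds by which agent 2 enters after agent 1.
#'   Default 0.55 s, chosen so a 1.3 s flight leaves a co-presence window
#'   of about 0.75 s -- about 130 samples at 180 Hz per pair, the
#'   per-pair overlap scale of the field data's no-obstacle group.
#' @param separation Scale (m) of the individual lateral offset of each
#'   agent's entry point.
#' @param behavior Behavior label attached to the pair: `"NM"`, `"MC"` or
#'   `"MT"` (metadata only; the simulator has no obstacle geometry).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_pair()], [simulate_group()]
#' @export
sim_config <- function(duration = 1.3,
                       sample_rate = 180,
                       speed = 3,
                       noise = 1.5,
                       turning_persistence = 0.35,
                       coupling_mode = c("none", "front_to_rear",
                                         "rear_to_front", "bidirectional"),
                       gain = 35,
                       delay = 0.05,
                       corridor_gain = 0.3,
                       entry_delay = 0.55,
                       separation = 0.5,
                       behavior = c("NM", "MC", "MT"),
                       seed = NULL) {
  coupling_mode <- match.arg(coupling_mode)
  behavior <- match.arg(behavior)
  stopifnot(duration > 0, sample_rate > 0, speed > 0, noise >= 0,
            turning_persistence > 0, gain >= 0, delay >= 0,
            corridor_gain >= 0, entry_delay >= 0, separation >= 0)
  if (delay >= duration)
    abort("coupling `delay` must be shorter than `duration`")
  if (duration * sample_rate < 50)
    abort("`duration * sample_rate` must give at least 50 samples")
  structure(list(duration = duration, sample_rate = sample_rate,
                 speed = speed, noise = noise,
                 turning_persistence = turning_persistence,
                 coupling_mode = coupling_mode, gain = gain, delay = delay,
                 corridor_gain = corridor_gain, entry_delay = entry_delay,
                 separation = separation, behavior = behavior, seed = seed),
            class = "sim_config")
}

# project vector u onto the tangent plane of unit vector h
.tangent <- function(u, h) u - sum(u * h) * h

# turning-skeleton constants
.substeps <- 6      # integration substeps per native sample (smooth path)
.burst_rate <- 2    # 1/s: switching rate of the maneuver/cruise envelope
.burst_lo <- 0.3    # envelope multiplier while cruising
.burst_hi <- 2.2    # envelope multiplier during a maneuver bout
.env_tau <- 0.5     # s: correlation time of the shared-environment steering
.env_sd <- 0.6      # rad/s stationary sd of that steering per unit gain
.env_gate_tau <- 0.5   # s: correlation time of the shared maneuver gate
.env_gate_sd <- 0.45   # log-scale sd of that gate per unit gain

# OU angular-velocity series (2 tangent components, unit = rad/s), with
# stationary sd sigma / sqrt(2 tau) so the heading diffuses with
# intensity sigma over long times
.steer_series <- function(n, tau, sigma, dt) {
  a <- exp(-dt / tau)
  s_st <- sigma / sqrt(2 * tau)
  b <- s_st * sqrt(1 - a^2)
  u <- matrix(0, n, 2)
  u[1, ] <- rnorm(2, 0, s_st)
  for (t in 2:n) u[t, ] <- a * u[t - 1, ] + b * rnorm(2)
  u
}

# two-state telegraph burst envelope (maneuver bouts vs cruising)
.burst_series <- function(n, dt) {
  e <- numeric(n)
  st <- sample(c(.burst_lo, .burst_hi), 1)
  flips <- runif(n) < .burst_rate * dt
  for (t in seq_len(n)) {
    if (flips[t]) st <- ifelse(st == .burst_lo, .burst_hi, .burst_lo)
    e[t] <- st
  }
  e
}

#' Simulate one coupled (or uncoupled) flight pair
#'
#' Generates the 3D trajectories of a front agent (agent 1) and a rear
#' agent (agent 2) under the dynamics described in [sim_config()]. Both
#' agents are integrated jointly on one absolute-time grid; a listening
#' agent reads its partner's recorded steering (applied turn amplitude) at
#' the configured delay, so the information-flow direction is known by
#' construction and exact on the grid for any coupling mode.
#'
#' @param config A [sim_config()] object.
#' @param pair_id Identifier for the pair (default `"P01"`).
#'
#' @return A tibble in the package's trajectory dialect with columns
#'   `pair_id, agent, t, x, y, z, behavior`, one row per native sample,
#'   and attribute `ground_truth` (a one-row tibble with the coupling
#'   mode, gains and seed).
#' @examples
#' cfg <- sim_config(coupling_mode = "rear_to_front", seed = 1)
#' traj <- simulate_pair(cfg)
#' head(traj)
#' @export
simulate_pair <- function(config, pair_id = "P01") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dt <- 1 / config$sample_rate
  sub <- .substeps
  dts <- dt / sub
  n1 <- round(config$duration / dt) + 1
  off <- round(config$entry_delay / dt)
  n2 <- round(config$duration / dt) + 1
  n_steps <- max(off + n2, n1)
  n_sub <- (n_steps - 1L) * sub + 1L
  sub1 <- (n1 - 1L) * sub + 1L          # last active substep, agent 1
  sub2_from <- off * sub + 1L           # first active substep, agent 2
  active1 <- seq_len(n_sub) <= sub1
  active2 <- seq_len(n_sub) >= sub2_from
  delay_steps <- max(1L, round(config$delay / dts))

  # both agents enter near the same spot: a pair-common lateral offset
  # (entry geometry of the shared corridor) plus individual scatter
  common_off <- rnorm(2, 0, 0.5)
  common_tilt <- rnorm(2, 0, 0.1)
  pos0 <- function() c(0, common_off + rnorm(2, 0, config$separation / 2))
  head0 <- function() {
    h <- c(1, common_tilt + rnorm(2, 0, 0.05))
    h / sqrt(sum(h^2))
  }
  mode <- config$coupling_mode
  listens <- c(mode %in% c("rear_to_front", "bidirectional"),   # 1 <- 2
               mode %in% c("front_to_rear", "bidirectional"))   # 2 <- 1
  mix <- config$gain * config$turning_persistence

  # per-agent turning programs on the substep grid (drawn up front; the
  # integration loop is deterministic given these)
  steer <- list(.steer_series(n_sub, config$turning_persistence,
                              config$noise, dts),
                .steer_series(n_sub, config$turning_persistence,
                              config$noise, dts))
  env <- list(.burst_series(n_sub, dts), .burst_series(n_sub, dts))
  # pair-common slow steering disturbance on absolute time (world y/z)
  shared <- .steer_series(n_sub, .env_tau,
                          .env_sd * config$corridor_gain * sqrt(2 * .env_tau),
                          dts)
  # pair-common slow maneuver gate: both agents turn harder in the same
  # moments (same obstacles and traffic at the same absolute time);
  # smooth and slow, so it comodulates the two curvature magnitudes
  # without creating step-scale conditional information
  lg <- .steer_series(n_sub, .env_gate_tau,
                      .env_gate_sd * config$corridor_gain *
                        sqrt(2 * .env_gate_tau), dts)[, 1]
  gate <- exp(lg - 0.5 * stats::var(lg))

  pos <- list(matrix(NA_real_, n_sub, 3), matrix(NA_real_, n_sub, 3))
  app <- list(matrix(NA_real_, n_sub, 3), matrix(NA_real_, n_sub, 3))
  p <- list(pos0(), pos0())
  h <- list(head0(), head0())
  active <- list(active1, active2)
  for (i in seq_len(n_sub)) {
    for (ag in 1:2) {
      if (!active[[ag]][i]) next
      pos[[ag]][i, ] <- p[[ag]]
      hh <- h[[ag]]
      # tangent frame at the current heading
      ref <- if (abs(hh[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- .tangent(ref, hh); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(hh[2] * e1[3] - hh[3] * e1[2],
              hh[3] * e1[1] - hh[1] * e1[3],
              hh[1] * e1[2] - hh[2] * e1[1])
      own <- gate[i] * env[[ag]][i] *
        (steer[[ag]][i, 1] * e1 + steer[[ag]][i, 2] * e2)
      turn <- own
      if (listens[ag] && i > delay_steps) {
        m2 <- app[[3 - ag]][i - delay_steps, ]  # partner's steering, rad/s
        if (!anyNA(m2))
          turn <- (own + mix * .tangent(m2, hh)) / (1 + mix)
      }
      app[[ag]][i, ] <- turn
      # physical forcing on top of the steering choice: shared disturbance
      dh <- (turn + .tangent(c(0, shared[i, 1], shared[i, 2]), hh)) * dts
      if (config$corridor_gain > 0) {
        lambda <- 1  # 1/m, lateral scale of the corridor restoring force
        axis_dir <- c(1, -lambda * p[[ag]][2], -lambda * p[[ag]][3])
        axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
        dh <- dh + config$corridor_gain * .tangent(axis_dir, hh) * dts
      }
      hh <- hh + dh
      nrm <- sqrt(sum(hh^2))
      if (abs(nrm - 1) > 0.5) abort("unstable heading step (internal bug)")
      h[[ag]] <- hh / nrm
      p[[ag]] <- p[[ag]] + config$speed * h[[ag]] * dts
    }
  }
  # keep native-rate samples only
  keep <- seq(1L, n_sub, by = sub)
  active1 <- active1[keep]; active2 <- active2[keep]
  pos <- list(pos[[1]][keep, , drop = FALSE], pos[[2]][keep, , drop = FALSE])

  tgrid <- (seq_len(n_steps) - 1) * dt
  out1 <- tibble(pair_id = pair_id, agent = 1L, t = tgrid[active1],
                 x = pos[[1]][active1, 1], y = pos[[1]][active1, 2],
                 z = pos[[1]][active1, 3], behavior = config$behavior)
  out2 <- tibble(pair_id = pair_id, agent = 2L, t = tgrid[active2],
                 x = pos[[2]][active2, 1], y = pos[[2]][active2, 2],
                 z = pos[[2]][active2, 3], behavior = config$behavior)
  out <- dplyr::bind_rows(out1, out2)
  attr(out, "ground_truth") <- tibble(
    pair_id = pair_id, coupling_mode = mode, gain = config$gain,
    delay = config$delay, corridor_gain = config$corridor_gain,
    noise = config$noise, seed = if (is.null(config$seed)) NA_integer_
    else as.integer(config$seed))
  out
}

#' Simulate a group of independent flight pairs
#'
#' Draws `n_pairs` pairs from [simulate_pair()], each with its own seed
#' derived from `seed`, and with per-pair flight durations jittered
#' uniformly by up to 20% to emulate the unequal trajectory lengths of
#' field data.
#'
#' @param config A [sim_config()] template (its `seed` field is ignored).
#' @param n_pairs Number of pairs (at least 2, so a shuffled-partner
#'   control is possible downstream).
#' @param seed Master seed from which per-pair seeds are derived.
#' @param duration_jitter Relative half-width of the uniform duration
#'   jitter.
#' @return A tibble of all pairs' samples (trajectory dialect), with
#'   attribute `ground_truth` (one row per pair).
#' @export
simulate_group <- function(config, n_pairs = 10, seed = 1,
                           duration_jitter = 0.2) {
  stopifnot(inherits(config, "sim_config"), n_pairs >= 1)
  if (n_pairs < 2)
    warn("groups need >= 2 pairs for the shuffled-partner control")
  set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n_pairs)
  jit <- runif(n_pairs, 1 - duration_jitter, 1 + duration_jitter)
  ids <- sprintf("P%02d", seq_len(n_pairs))
  sims <- purrr::map(seq_len(n_pairs), function(i) {
    args <- unclass(config)
    args$duration <- config$duration * jit[i]
    args$seed <- pair_seeds[i]
    simulate_pair(do.call(sim_config, args), pair_id = ids[i])
  })
  out <- dplyr::bind_rows(sims)
  attr(out, "ground_truth") <- dplyr::bind_rows(
    purrr::map(sims, attr, "ground_truth"))
  out
}

#' Read and write trajectory files
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `pair_id,agent,t,x,y,z,behavior`, one row per sample, time in seconds
#' and coordinates in meters. Writing then re-reading is lossless to full
#' double precision (values are serialised with 17 significant digits).
#'
#' @param trajectories A trajectory tibble (columns as above).
#' @param path File path.
#' @return `read_trajectories()` returns the trajectory tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  req <- c("pair_id", "agent", "t", "x", "y", "z", "behavior")
  if (!all(req %in% names(trajectories)))
    abort(paste("trajectory table must have columns",
                paste(req, collapse = ", ")))
  df <- dplyr::mutate(
    trajectories[req],
    dplyr::across(c("t", "x", "y", "z"),
                  ~ sprintf("%.17g", .x)))
  tryCatch(
    readr::write_csv(df, path, progress = FALSE),
    error = function(e) abort(paste0("failed to write '", path, "': ",
                                     conditionMessage(e))))
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) abort(paste0("no such trajectory file: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  req <- c("pair_id", "agent", "t", "x", "y", "z", "behavior")
  if (!all(req %in% names(df)))
    abort(paste0("'", path, "' lacks the required trajectory header"))
  # numeric columns parsed with base R's correctly-rounded reader, so a
  # write/read cycle reproduces doubles bit-for-bit
  dplyr::mutate(df, agent = as.integer(.data$agent),
                dplyr::across(c("t", "x", "y", "z"), as.numeric))
}
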