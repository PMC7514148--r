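# run `fun` (scrambled kinematics -> named numeric vector) over n_shuffles
# independent partner scramblings; failed shuffles are resampled.
.null_matrix <- function(kinematics, fun, n_shuffles, max_retries = 10) {
  rows <- purrr::map(seq_len(n_shuffles), function(s) {
    for (r in seq_len(max_retries + 1L)) {
      v <- tryCatch(fun(scramble_partners(kinematics)),
                    error = function(e) {
                      warn(paste0("control shuffle failed (",
                                  conditionMessage(e), "); resampling"))
                      NULL
                    })
      if (!is.null(v)) return(v)
    }
    abort("control shuffle failed repeatedly")
  })
  do.call(rbind, rows)
}

#' Full directed-coupling analysis of one group of pairs
#'
#' Orchestrates the whole pipeline on a group of trajectories: spline
#' resampling, co-presence trimming, ensemble concatenation and
#' normalization, transfer entropy in both directions (with an optional
#' neighbour-count sweep), convergent cross mapping with a library-size
#' sweep, the shuffled-partner control condition for every reported value,
#' and the leadership decision. All randomness (tie noise, shuffles,
#' window subsampling) is drawn from one stream seeded by `seed`, so
#' identical inputs and configuration reproduce identical results.
#'
#' Directions are labelled from the front/rear convention: agent 1 entered
#' the observation volume first (front), agent 2 second (rear). `T_{2->1}`
#' is information flow from the rear to the front agent; `C_{2->1}` is the
#' skill of recovering agent 2's series from agent 1's shadow manifold
#' (high when agent 2 drives agent 1).
#'
#' @param trajectories Trajectory tibble (`pair_id, agent, t, x, y, z,
#'   behavior`) of the group's pairs.
#' @param label Group label carried into the results (e.g. `"all"`,
#'   `"NM"`).
#' @param variable `"curvature"` (1D) or `"velocity"` (3D; TE only -- CCM
#'   always runs on curvature since it accepts univariate series only).
#' @param resample_rate Uniform rate in Hz for the spline resampling.
#' @param k Reference neighbour count for the KSG estimator.
#' @param k_sweep Optional grid of neighbour counts (e.g. `2:15`); controls
#'   are computed per grid point.
#' @param n_shuffles Shuffled-partner datasets per control (default 100).
#' @param level Confidence level of the control interval.
#' @param E_grid Candidate embedding dimensions for simplex projection.
#' @param tau Embedding delay in samples.
#' @param lib_sizes Optional CCM library grid; default log-spaced.
#' @param window_cap Maximum CCM windows averaged per library size.
#' @param delta Dominance margin on the cross-map skills required to call
#'   leadership (see [infer_leadership()]).
#' @param velocity_te Also run multivariate TE on the 3D velocity
#'   ensembles.
#' @param run_ccm Set `FALSE` to skip the CCM stage.
#' @param seed Integer seed.
#' @return An object of class `coupling_analysis`; see [tidy()] /
#'   [glance()] methods and [infer_leadership()].
#' @export
analyze_group <- function(trajectories, label = "all",
                          variable = c("curvature", "velocity"),
                          resample_rate = 180, k = 8, k_sweep = NULL,
                          n_shuffles = 100, level = 0.95, E_grid = 1:10,
                          tau = 1, lib_sizes = NULL, window_cap = 200,
                          delta = 0.2, velocity_te = FALSE, run_ccm = TRUE,
                          seed = 1) {
  variable <- match.arg(variable)
  set.seed(seed)
  kin <- extract_overlap(compute_kinematics(trajectories, resample_rate))
  ks <- sort(unique(c(k, k_sweep)))

  te_observed <- function(var) {
    ens <- build_ensemble(kin, variable = var, normalize = "global")
    b <- attr(ens, "segment_bounds")
    s1 <- ensemble_series(ens, 1); s2 <- ensemble_series(ens, 2)
    obs <- dplyr::bind_rows(
      dplyr::mutate(knn_sweep(s1, s2, ks, bounds = b), direction = "1->2"),
      dplyr::mutate(knn_sweep(s2, s1, ks, bounds = b), direction = "2->1"))
    tibble(direction = obs$direction, k = obs$k, te = obs$te,
           n_effective = obs$n_effective)
  }
  te_nulls_of <- function(sk, var) {
    e <- build_ensemble(sk, variable = var, normalize = "global")
    bb <- attr(e, "segment_bounds")
    x1 <- ensemble_series(e, 1); x2 <- ensemble_series(e, 2)
    c(knn_sweep(x1, x2, ks, bounds = bb)$te,
      knn_sweep(x2, x1, ks, bounds = bb)$te)
  }
  te_verdicts <- function(obs_tbl, nulls, offset = 0) {
    sig <- purrr::map(seq_len(nrow(obs_tbl)), function(i) {
      col <- offset + (if (obs_tbl$direction[i] == "1->2") 0
                       else length(ks)) + match(obs_tbl$k[i], ks)
      significance(obs_tbl$te[i], nulls[, col], level = level,
                   metric = paste0("T_{", obs_tbl$direction[i], "}"))
    })
    dplyr::mutate(obs_tbl,
                  ci_low = purrr::map_dbl(sig, "ci_low"),
                  ci_high = purrr::map_dbl(sig, "ci_high"),
                  verdict = purrr::map_chr(sig, "verdict"))
  }

  te_obs <- te_observed(variable)

  ccm_obj <- NULL; E1 <- E2 <- NULL
  if (run_ccm) {
    ens <- build_ensemble(kin, variable = "curvature", normalize = "global")
    b <- attr(ens, "segment_bounds")
    s1 <- ensemble_series(ens, 1); s2 <- ensemble_series(ens, 2)
    E1 <- select_embedding_dim(s1, E_grid, tau, b)$E
    E2 <- select_embedding_dim(s2, E_grid, tau, b)$E
    ccm_obj <- ccm_sweep(s1, s2, E_a = E1, E_b = E2, tau = tau,
                         lib_sizes = lib_sizes, bounds = b,
                         window_cap = window_cap)
  }

  # one scramble loop feeds every control: TE (all k, both directions)
  # and, when enabled, the cross-map skills at maximum library size
  nulls <- .null_matrix(kin, function(sk) {
    out <- te_nulls_of(sk, variable)
    if (run_ccm) {
      e <- build_ensemble(sk, variable = "curvature", normalize = "global")
      bb <- attr(e, "segment_bounds")
      x1 <- ensemble_series(e, 1); x2 <- ensemble_series(e, 2)
      out <- c(out,
               as.numeric(cross_map_skill(
                 build_shadow_manifold(x2, E2, tau, bb), x1)),
               as.numeric(cross_map_skill(
                 build_shadow_manifold(x1, E1, tau, bb), x2)))
    }
    out
  }, n_shuffles)

  te_tbl <- te_verdicts(te_obs, nulls)

  ccm_tbl <- NULL
  if (run_ccm) {
    dirs <- list(list(d = "1->2", r = ccm_obj$a_to_b, col = 2 * length(ks) + 1),
                 list(d = "2->1", r = ccm_obj$b_to_a, col = 2 * length(ks) + 2))
    ccm_tbl <- dplyr::bind_rows(purrr::map(dirs, function(dd) {
      sig <- significance(dd$r$skill_at_lmax, nulls[, dd$col],
                          level = level,
                          metric = paste0("C_{", dd$d, "}"))
      tibble(direction = dd$d, E = dd$r$E,
             skill_at_lmax = dd$r$skill_at_lmax,
             l_max = max(dd$r$lib_sizes), convergence = dd$r$convergence,
             ci_low = sig$ci_low, ci_high = sig$ci_high,
             verdict = sig$verdict)
    }))
  }

  vel_tbl <- NULL
  if (velocity_te && variable != "velocity") {
    vel_obs <- te_observed("velocity")
    vel_nulls <- .null_matrix(kin, function(sk) te_nulls_of(sk, "velocity"),
                              n_shuffles)
    vel_tbl <- te_verdicts(vel_obs, vel_nulls)
  }

  lead <- infer_leadership(te_tbl, ccm_tbl, delta = delta, reference_k = k)
  structure(list(label = label, variable = variable, te = te_tbl,
                 ccm = ccm_tbl, ccm_sweeps = ccm_obj,
                 velocity_te = vel_tbl, leadership = lead,
                 n_pairs = length(unique(kin$pair_id)),
                 ensemble_length = sum(kin$agent == 1L),
                 config = list(resample_rate = resample_rate, k = k,
                               k_sweep = k_sweep, n_shuffles = n_shuffles,
                               level = level, tau = tau, delta = delta,
                               seed = seed)),
            class = "coupling_analysis")
}

#' Leadership decision from transfer-entropy and cross-map verdicts
#'
#' Declares leadership by agent `i` over agent `j` only when both methods
#' agree on a unidirectional picture: transfer entropy `i -> j` significant
#' with `j -> i` insignificant (at the reference neighbour count), and the
#' cross-map skill `C_{i->j}` both significant against its control and
#' larger than `C_{j->i}` by at least the dominance margin `delta`.
#' Bidirectional TE significance always yields `"none"` (two-way
#' information flow is the counterpart of no directed causal relationship),
#' as does a missing CCM control (the verdict is downgraded and the
#' rationale says so).
#'
#' @param te Tibble with columns `direction` (`"1->2"`/`"2->1"`), `k`,
#'   `verdict`.
#' @param ccm Tibble with columns `direction`, `skill_at_lmax`, `verdict`,
#'   or `NULL` if CCM was not run.
#' @param delta Dominance margin on the skill difference (default 0.2).
#' @param reference_k Neighbour count at which the TE verdicts are read.
#' @return A list of class `leadership_verdict`: `leadership` (`"none"`,
#'   `"agent_1"` or `"agent_2"`), `rationale`, `delta`, and the inputs'
#'   verdict summary.
#' @export
infer_leadership <- function(te, ccm, delta = 0.2, reference_k = 8) {
  tk <- te[te$k == reference_k, ]
  if (nrow(tk) != 2)
    abort("need TE verdicts for both directions at the reference k")
  sig12 <- tk$verdict[tk$direction == "1->2"] == "significant"
  sig21 <- tk$verdict[tk$direction == "2->1"] == "significant"
  details <- list(te_sig_1to2 = sig12, te_sig_2to1 = sig21)
  mk <- function(lead, why) {
    structure(c(details, list(leadership = lead, rationale = why,
                              delta = delta, reference_k = reference_k)),
              class = "leadership_verdict")
  }
  if (sig12 && sig21)
    return(mk("none", "bidirectional TE significance: mutual coupling, no directed leadership"))
  if (!sig12 && !sig21)
    return(mk("none", "no significant TE in either direction"))
  if (is.null(ccm))
    return(mk("none", "unidirectional TE but no CCM control available; verdict downgraded"))
  lead_agent <- if (sig12) 1L else 2L
  fwd <- if (sig12) "1->2" else "2->1"
  rev <- if (sig12) "2->1" else "1->2"
  c_fwd <- ccm[ccm$direction == fwd, ]
  c_rev <- ccm[ccm$direction == rev, ]
  dom <- c_fwd$skill_at_lmax - c_rev$skill_at_lmax
  if (c_fwd$verdict == "significant" && dom >= delta)
    return(mk(paste0("agent_", lead_agent),
              sprintf("unidirectional TE %s and dominant significant C_{%s} (%.3f vs %.3f, margin %.3f >= %.2f)",
                      fwd, fwd, c_fwd$skill_at_lmax, c_rev$skill_at_lmax,
                      dom, delta)))
  mk("none",
     sprintf("unidirectional TE %s but C_{%s} %s with margin %.3f < %.2f",
             fwd, fwd, c_fwd$verdict, dom, delta))
}

#' @export
print.leadership_verdict <- function(x, ...) {
  cat("Leadership:", x$leadership, "\n  ", x$rationale, "\n")
  invisible(x)
}

#' @export
print.coupling_analysis <- function(x, ...) {
  cat(sprintf("Coupling analysis '%s' (%s, %d pairs, ensemble length %d)\n",
              x$label, x$variable, x$n_pairs, x$ensemble_length))
  tk <- x$te[x$te$k == x$config$k, ]
  for (i in seq_len(nrow(tk)))
    cat(sprintf("  T_{%s} = %.4f nats (k = %d): %s\n", tk$direction[i],
                tk$te[i], tk$k[i], tk$verdict[i]))
  if (!is.null(x$ccm))
    for (i in seq_len(nrow(x$ccm)))
      cat(sprintf("  C_{%s} = %.3f at L = %d (%s): %s\n",
                  x$ccm$direction[i], x$ccm$skill_at_lmax[i],
                  x$ccm$l_max[i], x$ccm$convergence[i], x$ccm$verdict[i]))
  cat("  Leadership:", x$leadership$leadership, "\n")
  invisible(x)
}

#' Analyze every behavior group in a trajectory table
#'
#' Splits the pairs by behavior label, runs [analyze_group()] on the whole
#' dataset (`"all"`) and on each behavior subgroup with at least two pairs
#' (smaller subgroups cannot form a shuffled-partner control and are
#' reported as skipped), and collects the results.
#'
#' @param trajectories Trajectory tibble with a `behavior` column.
#' @param ... Passed to [analyze_group()].
#' @return An object of class `coupling_analysis_set` (list of
#'   `coupling_analysis` plus a `skipped` character vector); [tidy()] gives
#'   the one-row-per-group summary table.
#' @export
analyze_groups <- function(trajectories, ...) {
  beh <- unique(trajectories$behavior)
  groups <- c(list(all = trajectories),
              purrr::map(rlang::set_names(beh),
                         ~ trajectories[trajectories$behavior == .x, ]))
  skipped <- character()
  res <- list()
  for (g in names(groups)) {
    npair <- length(unique(groups[[g]]$pair_id))
    if (npair < 2) {
      warn(paste0("group '", g, "' has ", npair,
                  " pair(s); skipped (control infeasible)"))
      skipped <- c(skipped, g)
      next
    }
    res[[g]] <- analyze_group(groups[[g]], label = g, ...)
  }
  structure(list(analyses = res, skipped = skipped),
            class = "coupling_analysis_set")
}

#' @export
print.coupling_analysis_set <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}
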