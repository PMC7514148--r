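#' Tidy a transfer-entropy result
#'
#' @param x A `te_result`.
#' @param ... Unused.
#' @return One-row tibble: `direction`, `value`, `estimator`,
#'   `n_effective` and the estimator settings.
#' @method tidy te_result
#' @export
tidy.te_result <- function(x, ...) {
  out <- tibble(direction = as.character(x$direction), value = x$value,
                estimator = x$estimator, n_effective = x$n_effective)
  for (nm in names(x$settings))
    if (is.atomic(x$settings[[nm]]) && length(x$settings[[nm]]) == 1)
      out[[nm]] <- x$settings[[nm]]
  out
}

#' @method glance te_result
#' @export
glance.te_result <- function(x, ...) tidy(x, ...)

#' Tidy a cross-mapping result into a long skill table
#'
#' @param x A `ccm_result` from [ccm_sweep()].
#' @param ... Unused.
#' @return Tibble with `direction`, `lib_size`, `skill`.
#' @method tidy ccm_result
#' @export
tidy.ccm_result <- function(x, ...) {
  dplyr::bind_rows(purrr::map(list(x$a_to_b, x$b_to_a), function(d)
    tibble(direction = d$direction, lib_size = d$lib_sizes,
           skill = d$skills)))
}

#' @method glance ccm_result
#' @export
glance.ccm_result <- function(x, ...) {
  dplyr::bind_rows(purrr::map(list(x$a_to_b, x$b_to_a), function(d)
    tibble(direction = d$direction, E = d$E, tau = d$tau,
           skill_at_lmax = d$skill_at_lmax, l_max = max(d$lib_sizes),
           convergence = d$convergence)))
}

#' Tidy a significance result
#'
#' @param x A `significance_result`.
#' @param ... Unused.
#' @return One-row tibble with the observed value, the control interval
#'   and the verdict.
#' @method tidy significance_result
#' @export
tidy.significance_result <- function(x, ...) {
  tibble(metric = x$metric, observed = x$observed, ci_low = x$ci_low,
         ci_high = x$ci_high, level = x$level,
         n_null = length(x$null_values), verdict = x$verdict)
}

#' @method glance significance_result
#' @export
glance.significance_result <- function(x, ...) tidy(x, ...)

#' Tidy a group coupling analysis into its per-direction results
#'
#' @param x A `coupling_analysis` from [analyze_group()].
#' @param ... Unused.
#' @return Long tibble with `group`, `method` (`te`, `ccm`,
#'   `te_velocity`), `direction`, `k` (TE rows), `value`, `ci_low`,
#'   `ci_high`, `verdict`.
#' @method tidy coupling_analysis
#' @export
tidy.coupling_analysis <- function(x, ...) {
  rows <- list(dplyr::mutate(
    dplyr::rename(x$te, value = "te"), method = "te", .before = 1))
  if (!is.null(x$ccm))
    rows <- c(rows, list(dplyr::mutate(
      tibble(direction = x$ccm$direction,
             value = x$ccm$skill_at_lmax, ci_low = x$ccm$ci_low,
             ci_high = x$ccm$ci_high, verdict = x$ccm$verdict),
      method = "ccm", .before = 1)))
  if (!is.null(x$velocity_te))
    rows <- c(rows, list(dplyr::mutate(
      dplyr::rename(x$velocity_te, value = "te"),
      method = "te_velocity", .before = 1)))
  dplyr::mutate(dplyr::bind_rows(rows), group = x$label, .before = 1)
}

#' One-row summary of a group coupling analysis
#'
#' @param x A `coupling_analysis`.
#' @param ... Unused.
#' @return One-row tibble mirroring a results-summary table row: TE and
#'   CCM verdicts per direction, cross-map skills, velocity-TE verdicts
#'   (or `"not run"`), and the leadership call.
#' @method glance coupling_analysis
#' @export
glance.coupling_analysis <- function(x, ...) {
  k0 <- x$config$k
  tk <- x$te[x$te$k == k0, ]
  pick <- function(tbl, d, col) {
    if (is.null(tbl)) return(NA)
    v <- tbl[[col]][tbl$direction == d]
    if (length(v) == 1) v else NA
  }
  vk <- if (is.null(x$velocity_te)) NULL
        else x$velocity_te[x$velocity_te$k == k0, ]
  tibble(group = x$label, n_pairs = x$n_pairs,
         ensemble_length = x$ensemble_length,
         te_1to2 = pick(tk, "1->2", "verdict"),
         te_2to1 = pick(tk, "2->1", "verdict"),
         ccm_1to2 = pick(x$ccm, "1->2", "skill_at_lmax"),
         ccm_2to1 = pick(x$ccm, "2->1", "skill_at_lmax"),
         ccm_1to2_verdict = pick(x$ccm, "1->2", "verdict"),
         ccm_2to1_verdict = pick(x$ccm, "2->1", "verdict"),
         te_velocity_1to2 = if (is.null(vk)) "not run"
                            else pick(vk, "1->2", "verdict"),
         te_velocity_2to1 = if (is.null(vk)) "not run"
                            else pick(vk, "2->1", "verdict"),
         leadership = x$leadership$leadership)
}

#' Summary table over analyzed groups
#'
#' @param x A `coupling_analysis_set` from [analyze_groups()].
#' @param ... Unused.
#' @return One row per analyzed group (see [glance.coupling_analysis()]);
#'   skipped groups are absent.
#' @method tidy coupling_analysis_set
#' @export
tidy.coupling_analysis_set <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$analyses, glance))
}

#' @method glance coupling_analysis_set
#' @export
glance.coupling_analysis_set <- function(x, ...) tidy(x, ...)

# ---- plotting -------------------------------------------------------------

#' Plot a neighbour-count sensitivity sweep of transfer entropy
#'
#' TE per direction against the KSG neighbour count, with the
#' shuffled-partner control interval as a ribbon when present.
#'
#' @param object A `coupling_analysis` (uses its TE table) or a plain
#'   tibble with columns `k`, `te`, `direction` and optionally
#'   `ci_low`/`ci_high`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coupling_analysis
#' @export
autoplot.coupling_analysis <- function(object, ...) {
  df <- object$te
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$te,
                                        colour = .data$direction))
  if (all(c("ci_low", "ci_high") %in% names(df)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                   fill = .data$direction),
      alpha = 0.2, colour = NA)
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "K (nearest neighbours)",
                  y = "Transfer entropy (nats)",
                  title = paste0("Group '", object$label,
                                 "': TE vs control"),
                  colour = "direction", fill = "direction") +
    ggplot2::theme_minimal()
}

#' Plot cross-map skill against library size
#'
#' @param object A `ccm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccm_result
#' @export
autoplot.ccm_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$lib_size, y = .data$skill,
                               colour = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "library size L", y = "cross-map skill",
                  title = "CCM convergence") +
    ggplot2::theme_minimal()
}

#' Plot an observed value against its shuffle null
#'
#' @param object A `significance_result`.
#' @param ... Unused.
#' @return A ggplot object (null histogram, control interval, observed
#'   value).
#' @method autoplot significance_result
#' @export
autoplot.significance_result <- function(object, ...) {
  df <- tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$metric %||% "metric",
                  title = paste0("Observed vs shuffled-partner null (",
                                 object$verdict, ")")) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
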