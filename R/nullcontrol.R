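#' Sample a derangement (partner scrambling) of a group of pairs
#'
#' Re-pairs each agent-1 series with the agent-2 series of a *different*
#' pair, via a uniformly sampled derangement of the pair ids (rejection
#' sampling from uniform permutations; the expected number of retries is
#' below e). After re-pairing, the two series of a pseudo-pair generally
#' differ in length, so the longer one's tail is truncated to match
#' ([truncate_to_match()]). The scrambled group then reruns the identical
#' downstream pipeline (concatenate, normalize, estimate), which is what
#' makes it a like-for-like null: any trajectory similarity induced by the
#' shared environment survives scrambling, while genuinely contemporaneous
#' interaction cannot.
#'
#' @param kinematics Overlap-trimmed kinematics tibble of at least 2 pairs.
#' @return A kinematics-like tibble of pseudo-pairs; each keeps the agent-1
#'   pair's id and behavior label, with attribute `partner_map` (tibble of
#'   `pair_id`, `partner_from`).
#' @export
scramble_partners <- function(kinematics) {
  pids <- sort(unique(kinematics$pair_id))
  npair <- length(pids)
  if (npair < 2)
    abort("no derangement exists for a single pair; need a group of >= 2")
  repeat {
    perm <- sample.int(npair)
    if (!any(perm == seq_len(npair))) break
  }
  rate <- attr(kinematics, "resample_rate")
  out <- purrr::map(seq_len(npair), function(i) {
    d1 <- kinematics[kinematics$pair_id == pids[i] &
                       kinematics$agent == 1L, ]
    d2 <- kinematics[kinematics$pair_id == pids[perm[i]] &
                       kinematics$agent == 2L, ]
    tr <- truncate_to_match(d1, d2)
    d2 <- tr[[2]]
    d2$pair_id <- pids[i]
    d2$behavior <- tr[[1]]$behavior[1]
    dplyr::bind_rows(tr[[1]], d2)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "resample_rate") <- rate
  attr(res, "partner_map") <- tibble(pair_id = pids,
                                     partner_from = pids[perm])
  res
}

#' Truncate the longer of two series to the shorter's length
#'
#' Keeps the leading samples of both inputs (vectors or data frames), so
#' both come out with the length of the shorter.
#'
#' @param a,b Vectors or data frames (rows = samples), both nonempty.
#' @return A list of the two truncated inputs.
#' @export
truncate_to_match <- function(a, b) {
  len <- function(v) if (is.data.frame(v)) nrow(v) else length(v)
  cut <- function(v, n) if (is.data.frame(v)) v[seq_len(n), , drop = FALSE]
                        else v[seq_len(n)]
  na <- len(a); nb <- len(b)
  stopifnot(na >= 1, nb >= 1)
  n <- min(na, nb)
  list(cut(a, n), cut(b, n))
}

#' Null distribution of a coupling metric under partner scrambling
#'
#' Applies `metric` to `n_shuffles` independently scrambled versions of the
#' group. The metric receives a scrambled, truncated kinematics table and
#' must itself re-run the full preprocessing (ensemble concatenation and
#' normalization) before estimating, so the null experiences identical
#' processing to the observed data. A shuffle on which the metric fails is
#' logged and resampled, up to `max_retries` times.
#'
#' @param kinematics Overlap-trimmed kinematics of the analyzed group.
#' @param metric Function: scrambled kinematics tibble -> numeric scalar.
#' @param n_shuffles Number of scrambled datasets (default 100).
#' @param seed Optional seed for the shuffle stream.
#' @param max_retries Resampling budget per failed shuffle.
#' @return Numeric vector of length `n_shuffles` (the null values), with
#'   attribute `n_retried`.
#' @export
null_distribution <- function(kinematics, metric, n_shuffles = 100,
                              seed = NULL, max_retries = 10) {
  stopifnot(n_shuffles >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_retried <- 0L
  vals <- purrr::map_dbl(seq_len(n_shuffles), function(s) {
    for (r in seq_len(max_retries + 1L)) {
      v <- tryCatch(metric(scramble_partners(kinematics)),
                    error = function(e) {
                      warn(paste0("shuffle failed (", conditionMessage(e),
                                  "); resampling"))
                      NULL
                    })
      if (!is.null(v)) {
        if (r > 1) n_retried <<- n_retried + 1L
        return(as.numeric(v))
      }
    }
    abort(paste0("metric failed on ", max_retries + 1,
                 " consecutive shuffles"))
  })
  attr(vals, "n_retried") <- n_retried
  vals
}

#' Significance of an observed metric against a shuffle null
#'
#' Computes the 95% (by default) confidence interval of the null values --
#' the empirical 2.5/97.5 percentile interval, or a normal approximation --
#' and calls the observed value significant if and only if it exceeds the
#' interval's upper limit strictly. Values inside the interval are
#' insignificant (conservative tie-break).
#'
#' @param observed Observed metric value.
#' @param null_values Numeric vector from [null_distribution()].
#' @param level Confidence level (default 0.95).
#' @param method `"percentile"` (empirical quantiles) or `"normal"`
#'   (mean +/- z sd).
#' @param metric Optional metric/direction label carried in the result.
#' @return An object of class `significance_result`: list with `metric`,
#'   `observed`, `null_values`, `ci_low`, `ci_high`, `level`, `verdict`
#'   (`"significant"` or `"insignificant"`).
#' @export
significance <- function(observed, null_values, level = 0.95,
                         method = c("percentile", "normal"),
                         metric = NA_character_) {
  method <- match.arg(method)
  stopifnot(length(null_values) >= 1, is.finite(observed))
  alpha <- (1 - level) / 2
  if (method == "percentile") {
    ci <- unname(quantile(null_values, c(alpha, 1 - alpha)))
  } else {
    z <- qnorm(1 - alpha)
    ci <- mean(null_values) + c(-z, z) * sd(null_values)
  }
  structure(list(metric = metric, observed = observed,
                 null_values = null_values, ci_low = ci[1], ci_high = ci[2],
                 level = level, method = method,
                 verdict = if (observed > ci[2]) "significant"
                           else "insignificant"),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4g vs null CI [%.4g, %.4g] (n = %d) -> %s\n",
              if (is.na(x$metric)) "metric" else x$metric, x$observed,
              x$ci_low, x$ci_high, length(x$null_values), x$verdict))
  invisible(x)
}
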