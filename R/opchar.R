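#' Proportion of successful trials with Monte Carlo standard error
#'
#' The simulation estimate of power (effect scenario) or the type 1 error
#' rate (null scenario) is the fraction of repetitions flagged successful;
#' its Monte Carlo standard error is `sqrt(p (1 - p) / n_sim)`, which is at
#' most 0.01 for 2,500 repetitions.
#'
#' @param successes Logical (or 0/1) vector, one flag per simulated trial.
#' @return List with `rate`, `mcse` and `n_sim`.
#' @examples
#' estimate_rate(c(TRUE, TRUE, TRUE, FALSE))
#' @export
estimate_rate <- function(successes) {
  if (length(successes) < 1L) stop("at least one trial is required")
  s <- as.logical(successes)
  p <- mean(s)
  list(rate = p, mcse = sqrt(p * (1 - p) / length(s)), n_sim = length(s))
}

#' Scaled power: power at a null-calibrated success threshold
#'
#' Replaces the nominal success threshold with the threshold `t*` that gives
#' a type 1 error rate of `alpha` in the matched null simulation, then
#' recomputes power.  The per-trial calibration statistic is the smallest
#' threshold at which that trial would be declared successful: the target
#' arm's final success probability in the effect scenario, the maximum over
#' treatment arms in the null scenario, and 0 for futility-stopped trials
#' (they cannot succeed at any threshold).  `t*` is the smallest observed
#' null statistic whose exceedance fraction is at most `alpha` (so the type
#' 1 error is maximal while still controlled; ties resolve to the
#' conservative side).
#'
#' @param effect_stats Per-trial statistics from the effect scenario.
#' @param null_stats Per-trial statistics from the matched null scenario.
#' @param alpha Target type 1 error rate (default 0.05).
#' @return List with `scaled_power`, `calibrated_threshold` and the achieved
#'   `null_rate` at that threshold.
#' @export
scaled_power <- function(effect_stats, null_stats, alpha = 0.05) {
  if (!length(effect_stats) || !length(null_stats))
    stop("both statistic vectors must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  cand <- sort(unique(c(null_stats, 1)))
  frac <- vapply(cand, function(t) mean(null_stats >= t), numeric(1))
  ok <- frac <= alpha
  tstar <- cand[which(ok)[1L]]  # smallest threshold controlling the rate
  list(scaled_power = mean(effect_stats >= tstar),
       calibrated_threshold = tstar,
       null_rate = mean(null_stats >= tstar))
}

#' Futility-stop and arm-drop frequencies across repetitions
#'
#' @param records List of `trial_record`s from one configuration.
#' @return List with `futility_by_interim` (incremental stop rate at each
#'   interim), `futility_total`, `drop_by_arm_interim` (matrix of
#'   incremental per-arm drop rates, interims in rows) and
#'   `drop_cumulative` (same, cumulated over interims).
#' @export
decision_frequencies <- function(records) {
  stopifnot(length(records) >= 1L)
  n_int <- max(vapply(records, function(r) r$n_interims, integer(1)))
  n_arms_max <- max(vapply(records, function(r)
    length(r$final_probs) + 1L, integer(1)))
  trt <- seq.int(2L, n_arms_max)
  n <- length(records)
  fut <- numeric(max(n_int, 1L))
  drop <- matrix(0, nrow = max(n_int, 1L), ncol = length(trt),
                 dimnames = list(interim = NULL, arm = paste0("arm", trt)))
  for (r in records) {
    if (!is.na(r$stopped_at)) fut[r$stopped_at] <- fut[r$stopped_at] + 1
    for (m in seq_along(r$decisions)) {
      d <- r$decisions[[m]]
      if (d$kind == "drop_arm")
        drop[m, paste0("arm", d$dropped_arm)] <-
          drop[m, paste0("arm", d$dropped_arm)] + 1
    }
  }
  fut <- fut / n
  drop <- drop / n
  list(futility_by_interim = fut, futility_total = sum(fut),
       drop_by_arm_interim = drop,
       drop_cumulative = apply(drop, 2, cumsum))
}

#' Summarise repeated trial runs into operating characteristics
#'
#' @param records List of `trial_record`s for one configuration and one
#'   scenario.
#' @param label Optional label copied into the summary row.
#' @return An object of class `simulation_summary`: a one-row data frame
#'   with the success rate and its Monte Carlo SE, mean sample size,
#'   futility-stop rate, proportion of trials with failed convergence
#'   diagnostics, and repetition count.
#' @export
summarize_trials <- function(records, label = NULL) {
  rate <- estimate_rate(vapply(records, function(r) isTRUE(r$success),
                               logical(1)))
  out <- data.frame(
    label = if (is.null(label)) NA_character_ else label,
    n_sim = rate$n_sim,
    success_rate = rate$rate,
    mcse = rate$mcse,
    mean_sample_size = mean(vapply(records, function(r)
      as.numeric(r$sample_size), numeric(1))),
    futility_rate = mean(vapply(records, function(r) !is.na(r$stopped_at),
                                logical(1))),
    diag_failure_rate = mean(vapply(records, function(r) !r$converged_all,
                                    logical(1))))
  class(out) <- c("simulation_summary", class(out))
  out
}

#' Per-trial calibration statistics from a set of records
#'
#' Extracts the `success_stat` used by [scaled_power()].
#'
#' @param records List of `trial_record`s.
#' @return Numeric vector.
#' @export
success_stats <- function(records) {
  vapply(records, function(r) as.numeric(r$success_stat), numeric(1))
}
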