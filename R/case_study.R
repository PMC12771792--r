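#' Case-study configuration
#'
#' Published parameters for a school physical-activity implementation
#' setting: 31 clusters per arm, 6 participants per cluster, ICC 0.07.
#' Under the effect scenario the proportions of teachers delivering the
#' target amount of activity are 0.172 (usual care), 0.619 (original
#' strategy, first trial), 0.649 (original strategy, second trial) and
#' 0.692 (updated strategy); under the null scenario all arms sit at 0.172.
#'
#' @param reps Number of simulated repetitions when the config is used by
#'   [run_case_study()].
#' @param priors,settings Model priors and sampler settings.
#' @return An object of class `case_study_config`.
#' @export
case_study_config <- function(reps = 500L, priors = prior_spec(),
                              settings = sampler_settings()) {
  structure(list(
    props = trial_properties(icc = 0.07, clusters_per_arm = 31L,
                             participants_per_cluster = 6L),
    effect_probs = c(0.172, 0.619, 0.649, 0.692),
    null_probs = rep(0.172, 4),
    success_threshold = 0.85,
    reps = as.integer(reps), priors = priors, settings = settings),
    class = "case_study_config")
}

case_scenario <- function(config, scenario = c("effect", "null")) {
  scenario <- match.arg(scenario)
  if (scenario == "effect")
    scenario_spec(config$effect_probs, "effect")
  else scenario_spec(config$null_probs, "null")
}

#' Run one sequential series of up to three two-arm trials
#'
#' The series mirrors optimisation over consecutive two-arm cRCTs: usual
#' care vs the first original strategy, then that strategy vs the second
#' original strategy, then the second original strategy vs the updated
#' strategy.  Each trial is a fixed two-arm cRCT with the case-study cluster
#' structure; the newer arm wins when its posterior probability of being
#' best (its contrast against the comparator beating the comparator's zero
#' reference) reaches 0.85.  A subsequent trial runs only if the preceding
#' one concluded the newer strategy more effective; the series succeeds only
#' if all three do.
#'
#' @param config A [case_study_config()].
#' @param scenario `"effect"` (published proportions) or `"null"` (all arms
#'   at the usual-care proportion).
#' @return A `series_record`: list with `success`, `trial_successes`,
#'   `trials_run`, `sample_size` and per-trial win probabilities.
#' @export
run_sequential_series <- function(config, scenario = c("effect", "null")) {
  scenario <- match.arg(scenario)
  p <- if (scenario == "effect") config$effect_probs else config$null_probs
  comparisons <- list(p[c(1, 2)], p[c(2, 3)], p[c(3, 4)])
  props <- config$props
  n_per_trial <- 2L * props$clusters_per_arm * props$participants_per_cluster
  wins <- logical(0)
  win_probs <- numeric(0)
  for (cmp in comparisons) {
    sc <- scenario_spec(cmp, "custom")
    data <- simulate_trial_dataset(sc, props)
    fit <- fit_model(data, config$priors, config$settings)
    pr <- success_probabilities(fit, "control_effect_zero")
    win <- unname(pr["arm2"]) >= config$success_threshold
    wins <- c(wins, win)
    win_probs <- c(win_probs, unname(pr["arm2"]))
    if (!win) break
  }
  structure(list(success = length(wins) == 3L && all(wins),
                 trial_successes = wins, trials_run = length(wins),
                 win_probs = win_probs,
                 sample_size = n_per_trial * length(wins),
                 max_sample_size = 3L * n_per_trial),
            class = "series_record")
}

#' Four-arm fixed and adaptive case-study trials
#'
#' `run_case_fixed()` runs the four-arm trial with no interim analysis;
#' `run_case_adaptive()` uses two equally spread interim analyses (stage
#' sizes 10/10/11 clusters per arm for k = 31) with the arm-dropping and
#' futility rules.  Effect-scenario success requires identifying the updated
#' strategy (arm 4) as best.
#'
#' @inheritParams run_sequential_series
#' @return A `trial_record` (see [run_trial()]).
#' @export
run_case_fixed <- function(config, scenario = c("effect", "null")) {
  scenario <- match.arg(scenario)
  run_trial(case_scenario(config, scenario), config$props,
            design_config(n_interims = 0,
                          success_threshold = config$success_threshold),
            config$priors, config$settings)
}

#' @rdname run_case_fixed
#' @export
run_case_adaptive <- function(config, scenario = c("effect", "null")) {
  scenario <- match.arg(scenario)
  run_trial(case_scenario(config, scenario), config$props,
            design_config(n_interims = 2,
                          success_threshold = config$success_threshold),
            config$priors, config$settings)
}

#' Full case-study comparison of the three designs
#'
#' Repeats the sequential, fixed and adaptive designs under the effect and
#' null scenarios and tabulates power, type 1 error rate, scaled power (four
#' -arm designs only; calibrating the sequential series would require data
#' from trials that only exist after the success threshold has been
#' applied), and mean/maximum sample sizes.
#'
#' @param config A [case_study_config()].
#' @param designs Subset of `c("sequential", "fixed", "adaptive")`.
#' @param master_seed Integer seed; repetitions use independent substreams
#'   (see [spawn_trial_streams()]).
#' @param cores Number of worker processes for repetitions.
#' @return A data frame, one row per design, with class
#'   `case_study_summary`; the per-design record lists are attached as the
#'   `"records"` attribute.
#' @export
run_case_study <- function(config = case_study_config(),
                           designs = c("sequential", "fixed", "adaptive"),
                           master_seed = 1L, cores = 1L) {
  designs <- match.arg(designs, several.ok = TRUE)
  reps <- config$reps
  runners <- list(
    sequential = function(sc) run_sequential_series(config, sc),
    fixed = function(sc) run_case_fixed(config, sc),
    adaptive = function(sc) run_case_adaptive(config, sc))
  rows <- list()
  all_records <- list()
  for (d in designs) {
    recs <- list()
    for (sc in c("effect", "null")) {
      seed_offset <- match(d, c("sequential", "fixed", "adaptive")) * 1000L +
        match(sc, c("effect", "null")) * 100L
      recs[[sc]] <- run_reps(function() runners[[d]](sc), reps,
                             master_seed + seed_offset, cores)
    }
    all_records[[d]] <- recs
    power <- estimate_rate(vapply(recs$effect, `[[`, logical(1), "success"))
    t1 <- estimate_rate(vapply(recs$null, `[[`, logical(1), "success"))
    scp <- if (d == "sequential") NA_real_ else
      scaled_power(success_stats(recs$effect),
                   success_stats(recs$null))$scaled_power
    rows[[d]] <- data.frame(
      design = d, power = power$rate, type1_error = t1$rate,
      scaled_power = scp,
      mean_n_null = mean(vapply(recs$null, function(r)
        as.numeric(r$sample_size), numeric(1))),
      mean_n_effect = mean(vapply(recs$effect, function(r)
        as.numeric(r$sample_size), numeric(1))),
      max_n = if (d == "sequential") recs$effect[[1L]]$max_sample_size
              else 4L * config$props$clusters_per_arm *
                config$props$participants_per_cluster,
      n_sim = reps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "records") <- all_records
  class(out) <- c("case_study_summary", class(out))
  out
}
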