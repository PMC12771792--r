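# Two per-trial RNG substreams (L'Ecuyer-CMRG): one for recruitment, one for
# the sampler.  The trial's own stream is split with nextRNGSubStream, and
# the caller-visible state is advanced to a third substream so consecutive
# trials differ.  If the session RNG is not L'Ecuyer, a trial-local stream
# is first derived from one draw of the session RNG.
trial_substreams <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  s <- get(".Random.seed", envir = globalenv())
  if (s[1L] %% 100L != 7L) {
    seed <- sample.int(2147483646L, 1L)
    state <- preserve_rng_state()
    suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
    s <- get(".Random.seed", envir = globalenv())
    restore_rng_state(state)
  } else {
    assign(".Random.seed",
           parallel::nextRNGSubStream(parallel::nextRNGSubStream(
             parallel::nextRNGSubStream(s))),
           envir = globalenv())
  }
  env <- new.env(parent = emptyenv())
  env$data <- s
  env$fit <- parallel::nextRNGSubStream(s)
  list(run = function(which, expr) {
    state <- preserve_rng_state()
    on.exit(restore_rng_state(state))
    assign(".Random.seed", env[[which]], envir = globalenv())
    value <- force(expr)
    env[[which]] <- get(".Random.seed", envir = globalenv())
    value
  })
}

#' Apply the interim decision rules
#'
#' Rules, in order: (1) if every active treatment arm's posterior probability
#' of success is strictly below `futility_threshold`, stop the whole trial
#' for futility; (2) otherwise, if any active arm is strictly below
#' `drop_threshold`, drop the single arm with the lowest probability,
#' breaking exact ties towards the arm with the lowest treatment effect
#' point estimate; (3) otherwise continue unchanged.  The futility check is
#' evaluated first because it quantifies over all arms and subsumes
#' dropping.  The control arm is never eligible.
#'
#' @param probs Named numeric vector of success probabilities for the
#'   currently active treatment arms (names `"arm2"`, `"arm3"`, ...).
#' @param point_estimates Named numeric vector of effect point estimates for
#'   the same arms (used only to break ties).
#' @param config A [design_config()].
#' @return A list of class `interim_decision` with `kind` (`"continue"`,
#'   `"drop_arm"` or `"stop_futility"`), `dropped_arm` (or `NA`) and the
#'   probabilities examined.
#' @export
evaluate_interim <- function(probs, point_estimates, config) {
  stopifnot(inherits(config, "design_config"))
  if (length(probs) == 0L) stop("no active treatment arms")
  if (all(probs < config$futility_threshold)) {
    return(structure(list(kind = "stop_futility", dropped_arm = NA_integer_,
                          probs = probs), class = "interim_decision"))
  }
  dropped <- NA_integer_
  kind <- "continue"
  eligible <- probs < config$drop_threshold
  if (any(eligible)) {
    lowest <- probs == min(probs)
    pick <- names(probs)[lowest]
    if (sum(lowest) > 1L) {
      est <- point_estimates[pick]
      pick <- pick[which.min(est)]
    } else {
      pick <- pick[1L]
    }
    dropped <- as.integer(sub("^arm", "", pick))
    kind <- "drop_arm"
  }
  structure(list(kind = kind, dropped_arm = dropped, probs = probs),
            class = "interim_decision")
}

#' Final success determination
#'
#' Under the effect scenario a trial succeeds only if it identifies the true
#' optimal arm: the designated target arm's final success probability must
#' reach the threshold (`>=`).  Under the null scenario a trial is
#' (incorrectly) successful if any treatment arm reaches the threshold.
#'
#' @param probs Named success probabilities for all treatment arms from the
#'   final model (which includes dropped arms' data and parameters).
#' @param mode `"effect_targets_arm"` (success = target arm wins) or
#'   `"null_any_arm"` (success = any arm wins).
#' @param threshold Success threshold (default 0.85).
#' @param target_arm Arm id that must be identified under the effect mode
#'   (default 4).
#' @return Logical flag.
#' @export
final_success <- function(probs, mode = c("effect_targets_arm", "null_any_arm"),
                          threshold = 0.85, target_arm = 4L) {
  mode <- match.arg(mode)
  if (mode == "effect_targets_arm") {
    nm <- paste0("arm", target_arm)
    if (!nm %in% names(probs)) stop("target arm missing from probabilities")
    unname(probs[nm] >= threshold)
  } else {
    any(probs >= threshold)
  }
}

#' Run one simulated trial end-to-end
#'
#' Recruits stage by stage according to the allocation plan, fits the
#' hierarchical model on all accumulated data (including dropped arms) at
#' every interim, applies the drop/futility rules to the active arms,
#' reallocates a dropped arm's future clusters, and - unless stopped for
#' futility - fits the final model and determines success.  Dropped arms
#' remain in the candidate set of the final best-arm evaluation.
#'
#' @param scenario A [scenario_spec()].
#' @param props A [trial_properties()].
#' @param config A [design_config()].
#' @param priors A [prior_spec()].
#' @param settings A [sampler_settings()].
#' @param success_mode Passed to [final_success()]; defaults to
#'   `"null_any_arm"` when `scenario$label == "null"`, else
#'   `"effect_targets_arm"`.
#' @param target_arm Target arm for the effect-mode success rule (default:
#'   the last arm, the designated optimal arm of the effect scenario).
#' @return A `trial_record`: list with `success`, `final_probs`,
#'   `success_stat` (the per-trial statistic used for threshold
#'   calibration: target-arm probability in effect mode, maximum over arms
#'   in null mode; 0 for futility-stopped trials), `decisions` (list of
#'   interim decisions), `dropped_arms`, `stopped_at` (interim index or NA),
#'   `sample_size`, `n_fits`, `converged_all` plus the final `data`.
#' @export
run_trial <- function(scenario, props, config = design_config(),
                      priors = prior_spec(), settings = sampler_settings(),
                      success_mode = NULL, target_arm = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(props, "trial_properties"))
  n_arms <- scenario$n_arms
  if (is.null(target_arm)) target_arm <- n_arms
  if (is.null(success_mode))
    success_mode <- if (scenario$label == "null") "null_any_arm"
                    else "effect_targets_arm"
  plan <- build_allocation_plan(config, props$clusters_per_arm, n_arms)
  active <- setdiff(seq_len(n_arms), 1L)  # treatment arms still recruiting
  clusters <- NULL
  data <- NULL
  decisions <- list()
  dropped_arms <- integer(0)
  stopped_at <- NA_integer_
  converged <- logical(0)
  n <- props$participants_per_cluster
  # recruitment and model fitting draw from separate substreams, so the
  # generated data are unaffected by how many interim fits run before a
  # stage (a trial with decisions disabled recruits exactly the fixed
  # design's data under the same seed)
  rs <- trial_substreams()
  on_data <- function(expr) rs$run("data", expr)
  on_fit <- function(expr) rs$run("fit", expr)

  # Cluster effects and outcomes are intrinsic to the clusters, so the full
  # no-drop cohort is generated up front and revealed stage by stage; a
  # trial whose decisions never fire therefore recruits exactly the data of
  # the fixed design under the same seed.  Clusters recruited on top of an
  # arm's planned quota (reallocated from a dropped arm) are generated on
  # demand.
  base <- on_data(simulate_stage(scenario, props,
                                 rep(props$clusters_per_arm, n_arms)))
  clusters <- base$clusters
  queues <- split(clusters$cluster, clusters$arm)  # unrecruited base ids
  recruited <- integer(0)

  recruit_stage <- function(s) {
    alloc <- plan$stages[s, ]
    rows <- NULL
    extra <- integer(n_arms)
    for (arm in seq_len(n_arms)) {
      take <- min(alloc[arm], length(queues[[arm]]))
      ids <- queues[[arm]][seq_len(take)]
      queues[[arm]] <<- queues[[arm]][-seq_len(take)]
      extra[arm] <- alloc[arm] - take
      if (take > 0L)
        rows <- rbind(rows, base$data[base$data$cluster %in% ids, ])
    }
    if (any(extra > 0L)) {
      stg <- on_data(simulate_stage(scenario, props, extra, clusters,
                                    stage = s))
      clusters <<- stg$clusters
      rows <- rbind(rows, stg$data)
    }
    rows$stage <- as.integer(s)
    recruited <<- c(recruited, unique(rows$cluster))
    rows
  }

  for (s in seq_len(plan$n_stages)) {
    data <- rbind(data, recruit_stage(s))
    if (s == plan$n_stages) break
    # interim analysis on all accumulated data (dropped arms included)
    fit <- on_fit(fit_model(data, priors, settings))
    converged <- c(converged, fit$converged)
    probs <- success_probabilities(fit, config$argmax_convention)
    active_probs <- probs[paste0("arm", active)]
    est <- vapply(active, function(a) effect_point_estimate(fit, a),
                  numeric(1))
    names(est) <- paste0("arm", active)
    dec <- evaluate_interim(active_probs, est, config)
    decisions[[s]] <- dec
    if (dec$kind == "stop_futility") {
      stopped_at <- s
      break
    }
    if (dec$kind == "drop_arm") {
      active <- setdiff(active, dec$dropped_arm)
      dropped_arms <- c(dropped_arms, dec$dropped_arm)
      plan <- reallocate_after_drop(plan, dec$dropped_arm, active,
                                    from_stage = s + 1L)
    }
  }

  if (is.na(stopped_at)) {
    fit <- on_fit(fit_model(data, priors, settings))
    converged <- c(converged, fit$converged)
    final_probs <- success_probabilities(fit, config$argmax_convention)
    success <- final_success(final_probs, success_mode,
                             config$success_threshold, target_arm)
    stat <- if (success_mode == "effect_targets_arm")
      unname(final_probs[paste0("arm", target_arm)]) else max(final_probs)
  } else {
    # futility-stopped trials can never be declared successful at any
    # threshold; they enter calibration with statistic 0
    final_probs <- decisions[[stopped_at]]$probs
    success <- FALSE
    stat <- 0
  }

  structure(list(success = success, final_probs = final_probs,
                 success_stat = stat, decisions = decisions,
                 dropped_arms = dropped_arms, stopped_at = stopped_at,
                 sample_size = length(recruited) * n,
                 n_fits = length(converged),
                 converged_all = all(converged),
                 scenario_label = scenario$label,
                 n_interims = config$n_interims,
                 data = data),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial: %s scenario, %d interim(s); success = %s, N = %d\n",
              x$scenario_label, x$n_interims, x$success, x$sample_size))
  if (length(x$dropped_arms))
    cat("Dropped arms:", paste(x$dropped_arms, collapse = ", "), "\n")
  if (!is.na(x$stopped_at))
    cat("Stopped for futility at interim", x$stopped_at, "\n")
  invisible(x)
}
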