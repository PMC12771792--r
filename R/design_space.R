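#' Trial properties for one cell of the simulation grid
#'
#' A cell of the factorial design space: the intra-class correlation of the
#' binary outcome (on the latent logistic scale), the number of clusters
#' randomised per arm when no arm is dropped, and the (common) number of
#' participants per cluster.
#'
#' @param icc Intra-class correlation coefficient, in `[0, 1)`.
#' @param clusters_per_arm Clusters randomised per arm over the whole trial
#'   (`k`), a positive integer.
#' @param participants_per_cluster Participants per cluster (`n`), a positive
#'   integer.
#' @return An object of class `trial_properties`.
#' @examples
#' trial_properties(icc = 0.05, clusters_per_arm = 15, participants_per_cluster = 10)
#' @export
trial_properties <- function(icc, clusters_per_arm, participants_per_cluster) {
  stopifnot(is.numeric(icc), length(icc) == 1L, icc >= 0, icc < 1)
  k <- as.integer(clusters_per_arm)
  n <- as.integer(participants_per_cluster)
  stopifnot(k >= 1L, n >= 1L)
  structure(list(icc = icc, clusters_per_arm = k,
                 participants_per_cluster = n),
            class = "trial_properties")
}

#' True per-arm favourable-event probabilities for a scenario
#'
#' Arm 1 is always the control/comparator.  Probabilities are interpreted as
#' the probability of the favourable outcome for a median cluster (cluster
#' effect zero); see [true_log_odds()].
#'
#' @param arm_probabilities Numeric vector of probabilities strictly in
#'   (0, 1), first entry the control arm.  Length at least 2.
#' @param label Scenario label: `"effect"`, `"null"` or `"custom"`.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_effect()
#' scenario_spec(c(0.1, 0.1, 0.15, 0.2), label = "custom")
#' @export
scenario_spec <- function(arm_probabilities,
                          label = c("custom", "effect", "null")) {
  label <- match.arg(label)
  p <- as.numeric(arm_probabilities)
  stopifnot(length(p) >= 2L, all(p > 0), all(p < 1))
  structure(list(arm_probabilities = p, label = label,
                 n_arms = length(p)),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
scenario_effect <- function() scenario_spec(c(0.1, 0.2, 0.3, 0.4), "effect")

#' @rdname scenario_spec
#' @export
scenario_null <- function() scenario_spec(rep(0.1, 4), "null")

#' Design configuration: interim schedule and decision thresholds
#'
#' Defines the adaptive design: how many interim analyses are performed, when
#' they occur, and the decision thresholds applied to the posterior
#' probability of success (the posterior probability that an arm is best).
#' An arm is eligible to be dropped when its probability falls below
#' `drop_threshold` (strict `<`); the whole trial stops for futility when
#' every active treatment arm is below `futility_threshold` (strict `<`);
#' final success requires the target probability to reach `success_threshold`
#' (`>=`).  At most one arm is dropped per interim and the control arm is
#' never dropped.
#'
#' @param n_interims Number of interim analyses: 0 (fixed design), 1 or 2.
#' @param interim_timing `"equal"` (interims at equal fractions of cluster
#'   recruitment) or `"late"` (two interims at roughly 50% and 75%;
#'   only valid with `n_interims = 2`).
#' @param drop_threshold Arm-dropping threshold (default 0.05).
#' @param futility_threshold Whole-trial futility threshold (default 0.15).
#' @param success_threshold Final success threshold (default 0.85).
#' @param argmax_convention How the candidate set for "best arm" is formed;
#'   see [success_probabilities()].  Default `"control_effect_zero"`.
#' @return An object of class `design_config`.
#' @examples
#' design_config(n_interims = 2)
#' design_config(n_interims = 2, interim_timing = "late")
#' @export
design_config <- function(n_interims = 0,
                          interim_timing = c("equal", "late"),
                          drop_threshold = 0.05,
                          futility_threshold = 0.15,
                          success_threshold = 0.85,
                          argmax_convention = c("control_effect_zero",
                                                "include_intercept")) {
  interim_timing <- match.arg(interim_timing)
  argmax_convention <- match.arg(argmax_convention)
  n_interims <- as.integer(n_interims)
  stopifnot(n_interims %in% 0:2)
  if (interim_timing == "late" && n_interims != 2L)
    stop("late interim timing requires exactly 2 interim analyses")
  stopifnot(drop_threshold >= 0, drop_threshold <= futility_threshold,
            futility_threshold < success_threshold, success_threshold <= 1)
  structure(list(n_interims = n_interims, interim_timing = interim_timing,
                 drop_threshold = drop_threshold,
                 futility_threshold = futility_threshold,
                 success_threshold = success_threshold,
                 max_drops_per_interim = 1L, control_droppable = FALSE,
                 argmax_convention = argmax_convention),
            class = "design_config")
}

#' Staged cluster allocation plan
#'
#' Builds the per-stage, per-arm cluster counts for a design.  With equal
#' timing and `S = n_interims + 1` stages, each arm recruits
#' `floor(k / S)` clusters per stage with the remainder added to the last
#' stages, so interims fall at roughly 1/2 (one interim) or 1/3 and 2/3 (two
#' interims) of recruitment.  With late timing the two interims fall after
#' `floor(k / 2)` and `round(3 k / 4)` clusters per arm.
#'
#' @param design A [design_config()].
#' @param clusters_per_arm Clusters per arm `k` (at least one per stage).
#' @param n_arms Number of arms including control (default 4).
#' @return An `allocation_plan`: a list with a `stages` integer matrix
#'   (rows = stages, columns = arms) plus metadata.
#' @examples
#' build_allocation_plan(design_config(n_interims = 1), 15)
#' build_allocation_plan(design_config(2, "late"), 25)
#' @export
build_allocation_plan <- function(design, clusters_per_arm, n_arms = 4L) {
  stopifnot(inherits(design, "design_config"))
  k <- as.integer(clusters_per_arm)
  n_arms <- as.integer(n_arms)
  n_stages <- design$n_interims + 1L
  if (k < n_stages)
    stop("clusters_per_arm must be at least the number of stages")
  if (design$interim_timing == "late") {
    cum <- c(k %/% 2L, as.integer(floor(3 * k / 4 + 0.5)), k)
    per_stage <- diff(c(0L, cum))
  } else {
    base <- k %/% n_stages
    rem <- k - base * n_stages
    per_stage <- rep(base, n_stages)
    if (rem > 0L)
      per_stage[seq.int(n_stages - rem + 1L, n_stages)] <- base + 1L
  }
  stages <- matrix(rep(as.integer(per_stage), n_arms), nrow = n_stages,
                   dimnames = list(stage = NULL, arm = paste0("arm", seq_len(n_arms))))
  structure(list(stages = stages, clusters_per_arm = k, n_arms = n_arms,
                 n_stages = n_stages, dropped = integer(0)),
            class = "allocation_plan")
}

#' Reallocate a dropped arm's future clusters to the remaining treatment arms
#'
#' Clusters that the dropped arm would have recruited in not-yet-recruited
#' stages are split equally among the remaining active treatment arms; any
#' leftover clusters (the remainder of the integer division) are assigned
#' uniformly at random among those arms.  The control arm's allocation and
#' already-recruited stages are never modified, and the total number of
#' clusters per stage is conserved.
#'
#' @param plan An [build_allocation_plan()] result.
#' @param dropped_arm Treatment arm id (2-based; arm 1 is control).
#' @param active_arms Integer ids of the treatment arms that remain active
#'   (excluding `dropped_arm`, excluding control).
#' @param from_stage First not-yet-recruited stage index.
#' @return The modified `allocation_plan`.
#' @export
reallocate_after_drop <- function(plan, dropped_arm, active_arms, from_stage) {
  stopifnot(inherits(plan, "allocation_plan"))
  dropped_arm <- as.integer(dropped_arm)
  active_arms <- as.integer(active_arms)
  if (dropped_arm == 1L) stop("the control arm cannot be dropped")
  if (dropped_arm %in% active_arms)
    stop("dropped_arm must not be listed among active_arms")
  if (any(active_arms <= 1L) || any(active_arms > plan$n_arms))
    stop("active_arms must be treatment arm ids")
  if (length(active_arms) < 1L)
    stop("at least one treatment arm must remain active")
  if (dropped_arm %in% plan$dropped)
    stop("arm has already been dropped")
  plan$dropped <- c(plan$dropped, dropped_arm)
  if (from_stage > plan$n_stages) return(plan)
  for (s in seq.int(from_stage, plan$n_stages)) {
    freed <- plan$stages[s, dropped_arm]
    if (freed == 0L) next
    each <- freed %/% length(active_arms)
    left <- freed %% length(active_arms)
    plan$stages[s, active_arms] <- plan$stages[s, active_arms] + each
    if (left > 0L) {
      lucky <- if (length(active_arms) == 1L) rep(active_arms, left)
               else sample(active_arms, left)
      for (a in lucky) plan$stages[s, a] <- plan$stages[s, a] + 1L
    }
    plan$stages[s, dropped_arm] <- 0L
  }
  plan
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat(sprintf("Allocation plan: %d arms, %d stage(s), k = %d per arm\n",
              x$n_arms, x$n_stages, x$clusters_per_arm))
  print(x$stages)
  invisible(x)
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf(
    "Design: %d interim(s), %s timing; drop < %.2f, futility < %.2f, success >= %.2f (%s)\n",
    x$n_interims, x$interim_timing, x$drop_threshold, x$futility_threshold,
    x$success_threshold, x$argmax_convention))
  invisible(x)
}
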