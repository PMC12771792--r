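#' Cluster random-effect standard deviation implied by an ICC
#'
#' On the latent logistic scale the residual variance is `pi^2 / 3`, so a
#' target intra-class correlation `icc` corresponds to a cluster
#' random-intercept standard deviation of
#' `sqrt(icc * (pi^2 / 3) / (1 - icc))`.
#'
#' @param icc Intra-class correlation, in `[0, 1)`.
#' @return The cluster-effect standard deviation (0 when `icc = 0`).
#' @examples
#' icc_to_cluster_sd(0.05)
#' @export
icc_to_cluster_sd <- function(icc) {
  if (!is.numeric(icc) || any(icc < 0) || any(icc >= 1))
    stop("icc must be in [0, 1)")
  sqrt(icc * (pi^2 / 3) / (1 - icc))
}

#' True parameters of the outcome model under a scenario
#'
#' The estimand is the log-odds ratio of the favourable outcome versus
#' control.  Scenario probabilities are probabilities for a median cluster
#' (cluster effect equal to zero), so the intercept is `qlogis(p_control)`
#' and each treatment contrast is `qlogis(p_j) - qlogis(p_control)`.
#'
#' @param scenario A [scenario_spec()].
#' @return A list with `intercept` (control log-odds) and `contrasts`
#'   (named log-odds ratios for arms 2..A).
#' @examples
#' true_log_odds(scenario_effect())
#' @export
true_log_odds <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- scenario$arm_probabilities
  lo <- qlogis(p)
  contrasts <- lo[-1L] - lo[1L]
  names(contrasts) <- paste0("theta", seq.int(2L, length(p)))
  list(intercept = lo[1L], contrasts = contrasts)
}

new_cluster_effects <- function(sd) {
  structure(list(cluster = integer(0), arm = integer(0),
                 alpha = numeric(0), sd = sd),
            class = "cluster_effects")
}

#' Simulate one recruitment stage of clustered binary outcomes
#'
#' Entire clusters are randomised at once.  For each newly recruited cluster
#' a random intercept `alpha ~ N(0, sd)` is drawn with
#' `sd = icc_to_cluster_sd(icc)`; each of the `n` participants in a cluster
#' of arm `j` then has favourable-outcome probability
#' `plogis(intercept + contrast_j + alpha)` and a Bernoulli outcome.  All
#' outcomes for recruited clusters are observed before the next interim.
#'
#' @param scenario A [scenario_spec()].
#' @param props A [trial_properties()].
#' @param stage_allocation Integer vector of new clusters per arm (length =
#'   number of arms; dropped arms have 0).
#' @param clusters Accumulated `cluster_effects` from earlier stages, or
#'   `NULL` at stage 1 (cluster ids are globally unique across arms).
#' @param stage Stage index (1-based), recorded with each row.
#' @return A list with `data` (a data frame with columns `participant`,
#'   `cluster`, `arm`, `stage`, `y`, and `p_true`, the conditional
#'   probability used to generate the row, retained only for testing) and
#'   `clusters` (updated `cluster_effects`).
#' @export
simulate_stage <- function(scenario, props, stage_allocation, clusters = NULL,
                           stage = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(props, "trial_properties"))
  alloc <- as.integer(stage_allocation)
  if (length(alloc) != scenario$n_arms)
    stop("stage_allocation must give one count per arm")
  if (any(alloc < 0L)) stop("negative cluster counts are not allowed")
  sd <- icc_to_cluster_sd(props$icc)
  if (is.null(clusters)) clusters <- new_cluster_effects(sd)
  truth <- true_log_odds(scenario)
  lin_arm <- c(truth$intercept, truth$intercept + truth$contrasts)

  n <- props$participants_per_cluster
  next_id <- if (length(clusters$cluster)) max(clusters$cluster) + 1L else 1L
  out <- vector("list", sum(alloc > 0L))
  ii <- 0L
  for (arm in seq_along(alloc)) {
    kj <- alloc[arm]
    if (kj == 0L) next
    ids <- seq.int(next_id, next_id + kj - 1L)
    next_id <- next_id + kj
    alpha <- if (sd > 0) rnorm(kj, 0, sd) else rep(0, kj)
    clusters$cluster <- c(clusters$cluster, ids)
    clusters$arm <- c(clusters$arm, rep(arm, kj))
    clusters$alpha <- c(clusters$alpha, alpha)
    p <- plogis(lin_arm[arm] + rep(alpha, each = n))
    ii <- ii + 1L
    out[[ii]] <- data.frame(
      participant = seq_len(kj * n),
      cluster = rep(ids, each = n),
      arm = arm,
      stage = as.integer(stage),
      y = rbinom(kj * n, 1L, p),
      p_true = p)
  }
  data <- do.call(rbind, out[seq_len(ii)])
  rownames(data) <- NULL
  list(data = data, clusters = clusters)
}

#' Simulate a complete dataset for a fixed (single-stage) trial
#'
#' Convenience wrapper around [simulate_stage()] recruiting all
#' `clusters_per_arm` clusters of every arm at once.
#'
#' @inheritParams simulate_stage
#' @return A data frame as in [simulate_stage()].
#' @export
simulate_trial_dataset <- function(scenario, props) {
  simulate_stage(scenario, props,
                 rep(props$clusters_per_arm, scenario$n_arms))$data
}

#' Read or write an outcome dataset as CSV
#'
#' The on-disk format has columns `participant,cluster,arm,stage,y` (the
#' generating probability `p_true` is a simulation-internal column and is not
#' serialised).
#'
#' @param data An outcome data frame.
#' @param path File path.
#' @return `read_outcomes()` returns the data frame; `write_outcomes()`
#'   returns `path` invisibly.
#' @export
write_outcomes <- function(data, path) {
  write.csv(data[, c("participant", "cluster", "arm", "stage", "y")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  d <- read.csv(path)
  need <- c("participant", "cluster", "arm", "stage", "y")
  if (!all(need %in% names(d)))
    stop("outcome CSV must have columns ", paste(need, collapse = ","))
  d[need]
}
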