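#' Prior specification for the hierarchical logistic model
#'
#' The intercept and every treatment contrast receive independent
#' `N(0, theta_prior_sd)` priors (default sd 2; sd 100 gives the vague-prior
#' sensitivity variant).  Cluster random intercepts are
#' `N(0, sigma_alpha)` with a `half-Normal(0, sigma_alpha_hyper_sd)`
#' hyperprior on `sigma_alpha` (default 0.4).
#'
#' @param theta_prior_sd Prior standard deviation for arm parameters.
#' @param sigma_alpha_hyper_sd Half-normal scale of the cluster-sd hyperprior.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(theta_prior_sd = 2, sigma_alpha_hyper_sd = 0.4) {
  stopifnot(theta_prior_sd > 0, sigma_alpha_hyper_sd > 0)
  structure(list(theta_prior_sd = theta_prior_sd,
                 sigma_alpha_hyper_sd = sigma_alpha_hyper_sd),
            class = "prior_spec")
}

#' MCMC sampler settings
#'
#' Defaults follow common practice for this model class: 4 chains with 750
#' warmup and 750 retained draws each (3,000 post-warmup draws in total).
#'
#' @param chains Number of chains (at least 2, for R-hat).
#' @param warmup_per_chain Warmup iterations per chain.
#' @param draws_per_chain Retained draws per chain.
#' @return An object of class `sampler_settings`.
#' @export
sampler_settings <- function(chains = 4L, warmup_per_chain = 750L,
                             draws_per_chain = 750L) {
  chains <- as.integer(chains)
  stopifnot(chains >= 2L, warmup_per_chain >= 0L, draws_per_chain >= 1L)
  structure(list(chains = chains,
                 warmup_per_chain = as.integer(warmup_per_chain),
                 draws_per_chain = as.integer(draws_per_chain)),
            class = "sampler_settings")
}

# collapse participant rows to one binomial record per cluster
collapse_clusters <- function(data) {
  stopifnot(all(data$y %in% 0:1))
  cl <- sort(unique(data$cluster))
  idx <- match(data$cluster, cl)
  y <- as.integer(rowsum(data$y, idx))
  n <- as.integer(tabulate(idx, nbins = length(cl)))
  arm <- integer(length(cl))
  arm[idx] <- data$arm
  if (anyDuplicated(unique(data[c("cluster", "arm")])$cluster))
    stop("a cluster appears in more than one arm")
  data.frame(cluster = cl, arm = arm, n = n, y = y)
}

#' Fit the Bayesian hierarchical logistic model
#'
#' Fits, by Polya-Gamma data-augmentation Gibbs sampling (exact MCMC), the
#' model `y ~ Bernoulli(p)` with
#' `logit(p) = theta1 + alpha_cluster + theta_j` for treatment arm `j`,
#' where `theta1` is the control log-odds (intercept), `theta_j` are
#' log-odds-ratio contrasts, and `alpha` are cluster random intercepts.
#' Data from dropped arms are always included.  Convergence diagnostics
#' (split rank-normalised R-hat, bulk and tail effective sample size) are
#' computed for every arm parameter and the cluster sd; a non-convergent fit
#' is returned with `converged = FALSE` rather than raising an error, so that
#' trial-level convergence can be tallied across repetitions.
#'
#' @param data Outcome data frame with columns `cluster`, `arm`, `y` (see
#'   [simulate_stage()]).
#' @param priors A [prior_spec()].
#' @param settings A [sampler_settings()].
#' @param store_alpha Keep the per-cluster random-intercept draws (needed
#'   only for checks of cluster-sd recovery).
#' @return An object of class `crt_fit` with elements `draws` (matrix of
#'   post-warmup draws: `theta1`, one `theta<j>` per non-control arm,
#'   `sigma_alpha`), `chain` (chain label per draw), `arms`, `diagnostics`
#'   (per-parameter R-hat / ESS table) and `converged`.
#' @export
fit_model <- function(data, priors = prior_spec(),
                      settings = sampler_settings(), store_alpha = FALSE) {
  stopifnot(inherits(priors, "prior_spec"),
            inherits(settings, "sampler_settings"))
  if (is.null(data) || nrow(data) == 0L) stop("data must be non-empty")
  cc <- collapse_clusters(data)
  arms <- sort(unique(cc$arm))
  if (length(arms) < 2L) stop("data must contain at least 2 arms")
  ref <- arms[1L]
  xidx <- match(cc$arm, arms) - 1L  # 0 = reference, 1.. = contrast index
  res <- .pg_gibbs_cpp(cc$y, cc$n, xidx, length(arms),
                       priors$theta_prior_sd, priors$sigma_alpha_hyper_sd,
                       settings$chains, settings$warmup_per_chain,
                       settings$draws_per_chain, store_alpha)
  cn <- c("theta1", paste0("theta", arms[-1L]), "sigma_alpha")
  per_chain <- lapply(seq_len(settings$chains), function(ch) {
    m <- cbind(res$theta[[ch]], res$sigma[[ch]])
    colnames(m) <- cn
    m
  })
  draws <- do.call(rbind, per_chain)
  chain <- rep(seq_len(settings$chains), each = settings$draws_per_chain)
  diag <- mcmc_diagnostics(per_chain)
  min_ess <- 100 * settings$chains
  converged <- all(diag$rhat < 1.05) && all(diag$ess_bulk > min_ess) &&
    all(diag$ess_tail > min_ess)
  structure(list(draws = draws, chain = chain, arms = arms, ref_arm = ref,
                 cluster_table = cc,
                 alpha = if (store_alpha) res$alpha else NULL,
                 priors = priors, settings = settings,
                 diagnostics = diag, converged = converged),
            class = "crt_fit")
}

#' @export
print.crt_fit <- function(x, ...) {
  cat(sprintf("Hierarchical logistic fit: %d arms, %d clusters, %d draws (%d chains)\n",
              length(x$arms), nrow(x$cluster_table), nrow(x$draws),
              x$settings$chains))
  est <- colMeans(x$draws)
  print(round(est, 3))
  cat(if (x$converged) "Diagnostics: converged\n" else
    "Diagnostics: NOT converged\n")
  invisible(x)
}

#' Posterior probability that each treatment arm is best
#'
#' For each treatment arm the proportion of posterior draws in which its
#' parameter is the largest of the candidate set.  Under the default
#' `control_effect_zero` convention the candidates are the treatment
#' log-odds-ratio contrasts together with 0, the control arm's own contrast,
#' so an arm is "best" in a draw when it beats every other treatment arm and
#' the control.  Under `include_intercept` the candidate set is taken
#' literally as the model parameters `{theta1, theta2, ...}` (intercept
#' included); because the intercept is on the log-odds rather than the
#' log-odds-ratio scale, this reduces to an argmax over the treatment
#' contrasts whenever the control event probability is below 0.5.
#' Exact ties within a draw are broken towards the lowest arm index
#' (a measure-zero event).
#'
#' @param fit A [fit_model()] result.
#' @param convention `"control_effect_zero"` or `"include_intercept"`.
#' @return Named vector of probabilities, one per treatment arm in the fit.
#'   With the control candidate included, the probabilities over the full
#'   candidate set sum to 1 (the control's share is the complement).
#' @export
success_probabilities <- function(fit,
                                  convention = c("control_effect_zero",
                                                 "include_intercept")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fit, "crt_fit"))
  trt <- fit$arms[-1L]
  th <- fit$draws[, paste0("theta", trt), drop = FALSE]
  cand <- if (convention == "control_effect_zero")
    cbind(0, th) else cbind(fit$draws[, "theta1"], th)
  best <- max.col(cand, ties.method = "first")  # lowest index wins ties
  out <- vapply(seq_along(trt) + 1L, function(j) mean(best == j), numeric(1))
  names(out) <- paste0("arm", trt)
  out
}

#' Posterior mean treatment effect (log-odds ratio) of one arm
#'
#' Used as the "treatment effect estimate" when breaking ties between arms
#' that are equally eligible for dropping.
#'
#' @param fit A [fit_model()] result.
#' @param arm Treatment arm id.
#' @return Posterior mean of the arm's log-odds-ratio contrast.
#' @export
effect_point_estimate <- function(fit, arm) {
  stopifnot(inherits(fit, "crt_fit"))
  col <- paste0("theta", arm)
  if (!col %in% colnames(fit$draws) || arm == fit$ref_arm)
    stop("arm must be a treatment arm present in the fit")
  mean(fit$draws[, col])
}

#' Export posterior draws as CSV
#'
#' Columns `chain,draw` followed by the arm parameters and `sigma_alpha`.
#'
#' @param fit A [fit_model()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- data.frame(chain = fit$chain,
                  draw = ave(fit$chain, fit$chain, FUN = seq_along),
                  fit$draws, check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
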