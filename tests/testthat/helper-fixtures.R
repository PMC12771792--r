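# Shared fixtures: quick sampler settings for unit tests, a hand-buildable
# fit object for decision-rule tests, and memoised heavy simulation runs
# shared between acceptance checks.

quick_settings <- function() sampler_settings(chains = 2L, warmup_per_chain = 200L,
                                              draws_per_chain = 300L)

# a minimal crt_fit whose theta draws are given explicitly (one row per draw)
fake_fit <- function(theta_draws, theta1 = NULL, sigma = 0.3) {
  arms <- as.integer(sub("^theta", "", colnames(theta_draws)))
  n <- nrow(theta_draws)
  draws <- cbind(theta1 = if (is.null(theta1)) rep(-2, n) else theta1,
                 theta_draws, sigma_alpha = rep(sigma, n))
  structure(list(draws = draws, chain = rep(1L, n),
                 arms = c(1L, arms), ref_arm = 1L,
                 cluster_table = NULL, priors = prior_spec(),
                 settings = sampler_settings(), diagnostics = NULL,
                 converged = TRUE),
            class = "crt_fit")
}

# memoised store for expensive simulation runs reused across test blocks
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# case-study repetitions shared by several acceptance criteria
case_reps <- 100L

case_records <- function(design, scenario) {
  cached(paste("case", design, scenario, sep = "_"), {
    config <- case_study_config(reps = case_reps)
    runner <- switch(design,
                     fixed = function() run_case_fixed(config, scenario),
                     adaptive = function() run_case_adaptive(config, scenario))
    seed <- 20260000L + match(design, c("fixed", "adaptive")) * 10L +
      match(scenario, c("effect", "null"))
    adaptcrt:::run_reps(runner, case_reps, seed)
  })
}
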