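test_that("best-arm probabilities match brute-force counting on listed draws", {
  th <- cbind(theta2 = c(0.9, -0.2, 0.3, 0.1),
              theta3 = c(0.5, 0.4, 0.6, -0.3),
              theta4 = c(0.1, 0.3, 0.7, -0.1))
  fit <- fake_fit(th, theta1 = c(-2, -2, -2, -2))
  # independent oracle: per-draw argmax over the candidate set by direct loop
  brute <- function(cand_builder) {
    counts <- c(arm2 = 0, arm3 = 0, arm4 = 0)
    for (i in 1:4) {
      cand <- cand_builder(i)
      best <- names(cand)[which.max(cand)]
      if (best %in% names(counts)) counts[best] <- counts[best] + 1
    }
    counts / 4
  }
  expected_zero <- brute(function(i) c(control = 0, arm2 = unname(th[i, 1]),
                                       arm3 = unname(th[i, 2]),
                                       arm4 = unname(th[i, 3])))
  expect_equal(success_probabilities(fit, "control_effect_zero"),
               expected_zero)
  expect_equal(unname(expected_zero), c(0.5, 0.25, 0.25))
  expected_incl <- brute(function(i) c(control = -2, arm2 = unname(th[i, 1]),
                                       arm3 = unname(th[i, 2]),
                                       arm4 = unname(th[i, 3])))
  expect_equal(success_probabilities(fit, "include_intercept"), expected_incl)
})

test_that("an arm that dominates every draw gets probability one", {
  th <- cbind(theta2 = rep(0.1, 5), theta3 = rep(0.2, 5), theta4 = rep(3, 5))
  fit <- fake_fit(th)
  expect_equal(success_probabilities(fit),
               c(arm2 = 0, arm3 = 0, arm4 = 1))
})

test_that("probabilities over the full candidate set partition the draws", {
  set.seed(8)
  th <- cbind(theta2 = rnorm(500, 0, 1), theta3 = rnorm(500, 0, 1),
              theta4 = rnorm(500, 0, 1))
  fit <- fake_fit(th)
  pr <- success_probabilities(fit, "control_effect_zero")
  control_share <- mean(apply(th, 1, max) < 0)
  expect_equal(sum(pr) + control_share, 1)
  # invariant to permuting draw order
  perm <- sample(500)
  fit2 <- fake_fit(th[perm, , drop = FALSE])
  expect_equal(success_probabilities(fit2, "control_effect_zero"), pr)
})

test_that("exact ties within a draw go to the lowest arm index", {
  th <- cbind(theta2 = c(1, 1), theta3 = c(1, 0), theta4 = c(0.5, 1))
  fit <- fake_fit(th)
  expect_equal(success_probabilities(fit), c(arm2 = 1, arm3 = 0, arm4 = 0))
})

test_that("the effect point estimate is the posterior mean of the contrast", {
  th <- cbind(theta2 = c(-1, 1, 0, 0), theta3 = c(2, 2, 2, 2),
              theta4 = c(0.1, 0.2, 0.3, 0.4))
  fit <- fake_fit(th)
  expect_equal(effect_point_estimate(fit, 2), 0)
  expect_equal(effect_point_estimate(fit, 3), 2)
  expect_equal(effect_point_estimate(fit, 4), 0.25)
  expect_error(effect_point_estimate(fit, 1), "treatment")
})

test_that("diagnostics flag agreement for iid chains and disagreement for shifted chains", {
  set.seed(21)
  good <- lapply(1:4, function(i)
    matrix(rnorm(600 * 2), 600, 2, dimnames = list(NULL, c("a", "b"))))
  dg <- mcmc_diagnostics(good)
  expect_true(all(dg$rhat < 1.05))
  expect_true(all(dg$ess_bulk > 400))
  expect_true(all(dg$ess_tail > 400))
  bad <- lapply(1:4, function(i)
    matrix(rnorm(600 * 2, mean = i), 600, 2,
           dimnames = list(NULL, c("a", "b"))))
  db <- mcmc_diagnostics(bad)
  expect_true(all(db$rhat > 1.05))
})

test_that("the model recovers generating parameters on a large trial", {
  set.seed(14)
  props <- trial_properties(0.05, 50, 50)
  d <- simulate_trial_dataset(scenario_effect(), props)
  fit <- fit_model(d, store_alpha = TRUE)
  truth <- true_log_odds(scenario_effect())
  est <- colMeans(fit$draws)
  expect_lt(abs(est["theta4"] - truth$contrasts["theta4"]), 0.2)
  expect_lt(abs(est["theta3"] - truth$contrasts["theta3"]), 0.2)
  expect_lt(abs(est["theta2"] - truth$contrasts["theta2"]), 0.2)
  expect_lt(abs(est["theta1"] - truth$intercept), 0.3)
  # cluster-sd posterior concentrates near the ICC-implied value
  expect_lt(abs(est["sigma_alpha"] - icc_to_cluster_sd(0.05)), 0.15)
  expect_true(fit$converged)
})

test_that("null-scenario contrasts are estimated near zero on large data", {
  # average the posterior means over independent datasets so the check
  # reflects the generating truth rather than one sample's noise
  props <- trial_properties(0.05, 50, 50)
  est <- rowMeans(vapply(15:17, function(seed) {
    set.seed(seed)
    d <- simulate_trial_dataset(scenario_null(), props)
    colMeans(fit_model(d)$draws)[c("theta2", "theta3", "theta4")]
  }, numeric(3)))
  expect_true(all(abs(est) < 0.2))
})

test_that("posterior matches an independent MCMC implementation (rjags)", {
  set.seed(7)
  d <- simulate_trial_dataset(scenario_effect(), trial_properties(0.1, 15, 10))
  fit <- fit_model(d, settings = sampler_settings(4, 1000, 2500))
  cc <- adaptcrt:::collapse_clusters(d)
  model <- "model {
    for (c in 1:K) {
      y[c] ~ dbin(p[c], n[c])
      logit(p[c]) <- theta1 + th[arm[c]] + alpha[c]
      alpha[c] ~ dnorm(0, 1 / pow(sigma, 2))
    }
    th[1] <- 0
    for (j in 2:4) { th[j] ~ dnorm(0, 1/4) }
    theta1 ~ dnorm(0, 1/4)
    sigma ~ dnorm(0, 1/0.16) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = cc$y, n = cc$n, arm = cc$arm,
                                      K = nrow(cc)),
                          n.chains = 2, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("theta1", "th", "sigma"), 5000,
                           progress.bar = "none")
  m <- summary(s)$statistics
  expect_equal(unname(colMeans(fit$draws)[c("theta2", "theta3", "theta4")]),
               unname(m[c("th[2]", "th[3]", "th[4]"), "Mean"]),
               tolerance = 0.05)
  expect_equal(unname(colMeans(fit$draws)["theta1"]),
               unname(m["theta1", "Mean"]), tolerance = 0.05)
  expect_equal(unname(apply(fit$draws, 2, sd)[c("theta2", "theta3", "theta4")]),
               unname(m[c("th[2]", "th[3]", "th[4]"), "SD"]),
               tolerance = 0.05)
})

test_that("vague and default priors give close success probabilities on large data", {
  set.seed(16)
  props <- trial_properties(0.05, 25, 25)
  d <- simulate_trial_dataset(scenario_effect(), props)
  f2 <- fit_model(d, prior_spec(theta_prior_sd = 2))
  f100 <- fit_model(d, prior_spec(theta_prior_sd = 100))
  p2 <- success_probabilities(f2)
  p100 <- success_probabilities(f100)
  expect_true(all(abs(p2 - p100) < 0.05))
})

test_that("draws export to CSV with chain and draw labels", {
  th <- cbind(theta2 = 1:4 / 10, theta3 = rep(0, 4), theta4 = rep(1, 4))
  fit <- fake_fit(th)
  path <- tempfile(fileext = ".csv")
  write_draws(fit, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 4)
  expect_true(all(c("chain", "draw", "theta1", "theta2", "sigma_alpha")
                  %in% names(d)))
  unlink(path)
})
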