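test_that("interim rules: futility precedes dropping, strict thresholds", {
  cfg <- design_config(n_interims = 1)
  est <- c(arm2 = 0.1, arm3 = 0.2, arm4 = 0.3)
  # all below futility threshold -> stop
  d <- evaluate_interim(c(arm2 = 0.10, arm3 = 0.12, arm4 = 0.14), est, cfg)
  expect_equal(d$kind, "stop_futility")
  # one arm below drop threshold -> drop the lowest
  d <- evaluate_interim(c(arm2 = 0.02, arm3 = 0.40, arm4 = 0.50), est, cfg)
  expect_equal(d$kind, "drop_arm")
  expect_equal(d$dropped_arm, 2L)
  # tie on probability -> lowest effect estimate dropped
  d <- evaluate_interim(c(arm2 = 0.04, arm3 = 0.04, arm4 = 0.90),
                        c(arm2 = 0.1, arm3 = 0.2, arm4 = 2), cfg)
  expect_equal(d$dropped_arm, 2L)
  d <- evaluate_interim(c(arm2 = 0.04, arm3 = 0.04, arm4 = 0.90),
                        c(arm2 = 0.3, arm3 = 0.2, arm4 = 2), cfg)
  expect_equal(d$dropped_arm, 3L)
  # nothing below any threshold -> continue
  d <- evaluate_interim(c(arm2 = 0.20, arm3 = 0.30, arm4 = 0.50), est, cfg)
  expect_equal(d$kind, "continue")
  expect_true(is.na(d$dropped_arm))
  # boundary: exactly at the futility threshold is not futile
  d <- evaluate_interim(c(arm2 = 0.15, arm3 = 0.10, arm4 = 0.10), est, cfg)
  expect_false(d$kind == "stop_futility")
  expect_error(evaluate_interim(numeric(0), numeric(0), cfg), "active")
})

test_that("final success: target arm in effect mode, any arm in null mode", {
  pr <- c(arm2 = 0.01, arm3 = 0.05, arm4 = 0.90)
  expect_true(final_success(pr, "effect_targets_arm", 0.85, 4))
  pr2 <- c(arm2 = 0.01, arm3 = 0.95, arm4 = 0.60)
  expect_false(final_success(pr2, "effect_targets_arm", 0.85, 4))
  expect_true(final_success(pr2, "null_any_arm", 0.85))
  # strict boundary: 0.8499 fails, 0.85 succeeds
  expect_false(final_success(c(arm2 = 0.8499, arm3 = 0, arm4 = 0),
                             "null_any_arm", 0.85))
  expect_true(final_success(c(arm2 = 0.85, arm3 = 0, arm4 = 0),
                            "null_any_arm", 0.85))
})

test_that("a fixed design runs one fit and recruits every cluster", {
  set.seed(31)
  rec <- run_trial(scenario_effect(), trial_properties(0.05, 4, 5),
                   design_config(0), settings = quick_settings())
  expect_equal(rec$n_fits, 1L)
  expect_length(rec$decisions, 0L)
  expect_equal(rec$sample_size, 4L * 4L * 5L)
})

test_that("with decision thresholds disabled the adaptive trial recruits the fixed design's data", {
  props <- trial_properties(0.1, 6, 4)
  off <- design_config(2, drop_threshold = 0, futility_threshold = 0,
                       success_threshold = 0.85)
  stream <- spawn_trial_streams(77, 1)[[1]]
  a <- with_stream(stream, function()
    run_trial(scenario_effect(), props, off, settings = quick_settings()))
  b <- with_stream(stream, function()
    run_trial(scenario_effect(), props, design_config(0),
              settings = quick_settings()))
  expect_length(a$decisions, 2L)
  expect_true(all(vapply(a$decisions, function(d) d$kind == "continue",
                         logical(1))))
  # identical outcomes cluster by cluster (stage labels differ by design)
  ord <- function(d) {
    d <- d[order(d$cluster, d$participant),
           c("participant", "cluster", "arm", "y", "p_true")]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(a$data), ord(b$data))
  expect_equal(a$sample_size, b$sample_size)
})

test_that("sample size accounting reflects early stopping", {
  # futility-stopped trials keep only the clusters recruited so far:
  # 2 interims, k = 15, n = 10, 4 arms stopped at interim 1 -> 4 * 5 * 10
  props <- trial_properties(0.2, 15, 10)
  cfg <- design_config(2, futility_threshold = 0.99,
                       success_threshold = 0.995)
  set.seed(44)
  rec <- run_trial(scenario_null(), props, cfg, settings = quick_settings())
  expect_equal(rec$stopped_at, 1L)
  expect_equal(rec$sample_size, 4L * 5L * 10L)
  expect_false(rec$success)
  expect_equal(rec$success_stat, 0)
})

test_that("a dropped arm stays in the final candidate set and data", {
  props <- trial_properties(0.05, 6, 8)
  # generous drop threshold so the worst arm is dropped without triggering
  # futility (the best arm under the effect scenario sits well above 0.36)
  cfg <- design_config(1, drop_threshold = 0.35, futility_threshold = 0.36,
                       success_threshold = 0.85)
  set.seed(55)
  rec <- run_trial(scenario_effect(), props, cfg, settings = quick_settings())
  expect_length(rec$dropped_arms, 1L)
  expect_true(is.na(rec$stopped_at))
  # final probabilities cover all three treatment arms
  expect_setequal(names(rec$final_probs), c("arm2", "arm3", "arm4"))
  # dropped arm's stage-1 clusters are still in the final data
  expect_true(rec$dropped_arms %in% rec$data$arm)
  # total clusters conserved: dropped arm's future clusters reallocated
  expect_equal(rec$sample_size, 4L * 6L * 8L)
})

test_that("the last active treatment arm is never dropped", {
  # dropping requires prob < drop_threshold <= futility_threshold; a single
  # remaining arm below the drop threshold is then also below futility, so
  # the trial stops instead
  cfg <- design_config(2)
  d <- evaluate_interim(c(arm4 = 0.03), c(arm4 = -1), cfg)
  expect_equal(d$kind, "stop_futility")
})
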