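scr <- screening_config()
dcfg <- dsc_config()

.bias_records <- function(chosen_fun) {
  grid <- worker_grid(dcfg)
  start <- rep(grid, length.out = 95)
  data.frame(participant_id = "p1", block = rep(1:5, each = 19),
             trial = rep(1:19, 5), start_workforce = start,
             chosen_workforce = chosen_fun(start))
}

test_that("the response-bias screen uses least circular distance with a strict boundary", {
  grid <- worker_grid(dcfg)
  never <- .bias_records(identity)
  r <- dsc_response_bias_screen(never, dcfg, scr)
  expect_equal(r$mean_change, 0)
  expect_true(r$excluded)

  two_steps <- .bias_records(function(s) {
    grid[(match(s, grid) - 1 + 2) %% 12 + 1]
  })
  r2 <- dsc_response_bias_screen(two_steps, dcfg, scr)
  expect_equal(r2$mean_change, 2)
  expect_false(r2$excluded)   # strictly below 2 excludes; exactly 2 retained

  set.seed(21)
  prof <- archetype_profile("null", "p1", "single")
  rand <- simulate_dsc_agent(prof, dcfg)
  r3 <- dsc_response_bias_screen(rand, dcfg, scr)
  expect_lt(abs(r3$mean_change - 3), 0.6)
  expect_false(r3$excluded)
})

test_that("zero-on-target blocks exclude a participant from the confidence analyses", {
  sc <- data.frame(participant_id = "p1", block = 1:5,
                   trials_on_target = c(0, 3, 4, 5, 6))
  expect_true(zero_target_block_screen(sc))
  sc$trials_on_target <- rep(1, 5)
  expect_false(zero_target_block_screen(sc))
})

test_that("chance-level zero-block rate matches the exact Markov computation", {
  # analytic P(no on-target trial in a 19-trial block) under random input
  ex <- dsc_chance_exact(19, dcfg)
  states <- as.numeric(names(ex$per_state_prob))
  band <- abs(states - dcfg$target_production) <= dcfg$on_target_halfwidth
  Tm <- ex$transition
  d <- numeric(length(states))
  d[states == dcfg$initial_production] <- 1
  for (t in 1:19) {
    d <- as.vector(d %*% Tm)
    d[band] <- 0            # kill paths that landed on target
  }
  p0 <- sum(d)
  set.seed(31)
  zero <- vapply(1:500, function(i) {
    blk <- run_dsc_block(dsc_policy_random(dcfg), dcfg)
    sum(blk$on_target[1:19]) == 0
  }, logical(1))
  se <- sqrt(p0 * (1 - p0) / 500)
  expect_lt(abs(mean(zero) - p0), 3 * se)
  expect_gt(p0, 0)  # a 53-strong random cohort has a nonzero expected exclusion count
})

test_that("the accuracy screen is strict at the 75 percent boundary", {
  sc <- data.frame(participant_id = "p1", block = 1:10,
                   pct_correct_all = rep(75, 10))
  expect_false(asrt_accuracy_screen(sc, scr))
  sc$pct_correct_all[4] <- 60
  expect_true(asrt_accuracy_screen(sc, scr))
  sc$pct_correct_all <- rep(25, 10)  # chance-level responder
  expect_true(asrt_accuracy_screen(sc, scr))
})

test_that("the Welch awareness test handles clear, null and degenerate inputs", {
  w <- welch_awareness_test(c(6, 6, 5, 6, 5), c(2, 1, 2, 2, 1), scr)
  expect_true(w$aware)
  expect_lt(w$p, 0.001)

  same <- c(3, 4, 5, 4)
  w2 <- welch_awareness_test(same, same, scr)
  expect_equal(w2$t, 0)
  expect_equal(w2$p, 0.5)
  expect_false(w2$aware)

  expect_true(is.na(welch_awareness_test(5, c(1, 2, 3), scr)$aware))
  expect_true(is.na(welch_awareness_test(c(4, 4, 4), c(4, 4), scr)$aware))
})

test_that("Welch directional p agrees with the exhaustive permutation test on small samples", {
  set.seed(77)
  for (i in 1:6) {
    on <- round(rnorm(5, 4.2, 1), 2)
    off <- round(rnorm(6, 3.5, 1.3), 2)
    w <- welch_awareness_test(on, off, scr)
    expect_lt(abs(w$p - perm_welch_p(on, off)), 0.02)
  }
})

test_that("the questionnaire criterion is inclusive at five points", {
  expect_true(questionnaire_awareness(c(5, 3, 2, 2), scr))
  expect_false(questionnaire_awareness(c(4, 4, 2, 2), scr))
  expect_true(questionnaire_awareness(c(12, 0, 0, 0), scr))
  expect_error(questionnaire_awareness(c(5, 3, 2, 1), scr), "12")
})

test_that("exclusion is monotone in the screening thresholds", {
  set.seed(55)
  spec <- data.frame(condition = "single",
                     archetype = c("learner", "anchored", "negligent"),
                     n = c(4L, 3L, 3L))
  coh <- generate_cohort(spec, seed = 55)
  strict <- screen_cohort(coh, scr = screening_config())
  lax <- screen_cohort(coh, scr = screening_config(dsc_mean_change_min = 1.2,
                                                   asrt_block_accuracy_min = 60))
  expect_true(all(strict$excluded_dsc_bias | !lax$excluded_dsc_bias))
  expect_true(all(strict$excluded_asrt_accuracy | !lax$excluded_asrt_accuracy))
})
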