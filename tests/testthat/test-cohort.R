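test_that("profile validation rejects out-of-range parameters", {
  expect_error(agent_profile("x", "single", dsc_knowledge = 1.2), "probability")
  expect_error(agent_profile("x", "single", asrt_baseline_rt = -5), "positive")
  expect_error(agent_profile("x", "weekly"), "arg")
  expect_error(archetype_profile("cyborg", "x", "single"), "archetype")
})

test_that("anchored agents track the start value as programmed", {
  prof0 <- agent_profile("a0", "single", dsc_policy = "anchored",
                         anchor_strength = 0)
  d0 <- simulate_dsc_agent(prof0, seed = 5)
  expect_equal(d0$chosen_workforce, d0$start_workforce)  # mean change 0
  prof <- archetype_profile("anchored", "a1", "single")
  d1 <- simulate_dsc_agent(prof, seed = 6)
  r <- dsc_response_bias_screen(d1)
  expect_true(r$excluded)
})

test_that("aware agents couple confidence to outcome; unaware agents do not", {
  set.seed(8)
  prof_aw <- archetype_profile("aware_dsc", "aw", "single")
  conf_gap <- function(prof) {
    d <- simulate_dsc_agent(prof)
    mean(d$confidence[d$on_target]) - mean(d$confidence[!d$on_target])
  }
  gaps_aw <- replicate(10, conf_gap(prof_aw))
  prof_un <- agent_profile("un", "single")
  gaps_un <- replicate(10, conf_gap(prof_un))
  expect_gt(mean(gaps_aw), 1)
  expect_lt(abs(mean(gaps_un)), 0.5)
})

test_that("ASRT agents express the programmed pattern advantage", {
  set.seed(12)
  # zero advantage, no errors: per-block median difference near zero
  diffs0 <- replicate(10, {
    p <- agent_profile("z", "single", asrt_pattern_advantage = 0,
                       asrt_error_rate = 0, asrt_error_rate_random = 0)
    sc <- score_asrt(simulate_asrt_agent(p))
    mean(sc$median_rt_random - sc$median_rt_pattern)
  })
  expect_lt(abs(mean(diffs0)), 4)
  # 20 ms advantage at block 10 recovered by scoring
  diffs20 <- replicate(30, {
    p <- agent_profile("v", "single", asrt_pattern_advantage = 20)
    sc <- score_asrt(simulate_asrt_agent(p))
    sc$median_rt_random[sc$block == 10] - sc$median_rt_pattern[sc$block == 10]
  })
  expect_lt(abs(mean(diffs20) - 20), 6)
  p <- agent_profile("v", "single", asrt_pattern_advantage = 20)
  sc <- score_asrt(simulate_asrt_agent(p, seed = 3))
  expect_gt(sc$median_rt_random[sc$block == 10] /
              sc$median_rt_pattern[sc$block == 10], 1)
})

test_that("negligent agents fail the accuracy screen by construction", {
  prof <- archetype_profile("negligent", "n1", "single")
  sc <- score_asrt(simulate_asrt_agent(prof, seed = 10))
  expect_true(asrt_accuracy_screen(sc))
  expect_true(any(sc$pct_correct_all < 75))
})

test_that("generation sequences respect the constraint and the programmed knowledge", {
  prof0 <- agent_profile("g0", "single", generation_knowledge = 0,
                         exclusion_control = 0)
  set.seed(13)
  props0 <- replicate(300, {
    g <- simulate_generation(prof0, "inclusion")
    expect_length(g$positions, 80)
    runs <- rle(g$positions)$lengths
    expect_lte(max(runs), 3)
    unname(code_triplets(g$positions)$proportions["pattern_consistent"])
  })
  expect_lt(abs(mean(props0) - 0.25), 0.012)

  # full knowledge with full exclusion control: exclusion < inclusion
  prof1 <- agent_profile("g1", "single", generation_knowledge = 1,
                         exclusion_control = 1)
  set.seed(14)
  inc <- mean(replicate(60, unname(
    code_triplets(simulate_generation(prof1, "inclusion")$positions)$
      proportions["pattern_consistent"])))
  exc <- mean(replicate(60, unname(
    code_triplets(simulate_generation(prof1, "exclusion")$positions)$
      proportions["pattern_consistent"])))
  expect_gt(inc, exc)

  # no exclusion control: automatic application makes the modes equivalent
  prof2 <- agent_profile("g2", "single", generation_knowledge = 0.3,
                         exclusion_control = 0)
  set.seed(15)
  inc2 <- mean(replicate(250, unname(
    code_triplets(simulate_generation(prof2, "inclusion")$positions)$
      proportions["pattern_consistent"])))
  exc2 <- mean(replicate(250, unname(
    code_triplets(simulate_generation(prof2, "exclusion")$positions)$
      proportions["pattern_consistent"])))
  expect_lt(abs(inc2 - exc2), 0.02)
})

test_that("questionnaires always sum to 12 and encode awareness", {
  prof_aw <- archetype_profile("aware_asrt", "q1", "single")
  prof_un <- agent_profile("q2", "single")
  for (s in 1:10) {
    qa <- simulate_questionnaire(prof_aw, seed = s)
    qu <- simulate_questionnaire(prof_un, seed = s + 100)
    expect_equal(sum(qa$points), 12)
    expect_equal(sum(qu$points), 12)
    expect_true(questionnaire_awareness(qa$points))
    expect_false(questionnaire_awareness(qu$points))
  }
})

test_that("cohorts are reproducible, sized by spec, and session-tagged", {
  expect_length(generate_cohort(data.frame(condition = "single",
                                           archetype = "learner", n = 0L),
                                seed = 1), 0)
  spec <- data.frame(condition = c("single", "multiple"),
                     archetype = "learner", n = c(2L, 2L))
  c1 <- generate_cohort(spec, seed = 99)
  c2 <- generate_cohort(spec, seed = 99)
  expect_identical(as_session_logs(c1)$dsc, as_session_logs(c2)$dsc)
  expect_identical(as_session_logs(c1)$asrt, as_session_logs(c2)$asrt)
  multi <- c1[[3]]
  expect_equal(unique(multi$dsc[, c("block", "session")])$session, 1:5)
  expect_equal(unique(multi$asrt[, c("block", "session")])$session,
               rep(1:5, each = 2))
  single <- c1[[1]]
  expect_equal(unique(single$asrt$session), 1L)
})

test_that("planted response-biased agents are recovered exactly per condition", {
  spec <- rbind(
    data.frame(condition = "single", archetype = c("anchored", "learner"),
               n = c(8L, 2L)),
    data.frame(condition = "multiple", archetype = c("anchored", "learner"),
               n = c(5L, 2L))
  )
  coh <- generate_cohort(spec, seed = 123)
  scr_tab <- screen_cohort(coh)
  counts <- tapply(scr_tab$excluded_dsc_bias, scr_tab$condition, sum)
  expect_equal(unname(counts["single"]), 8L)
  expect_equal(unname(counts["multiple"]), 5L)
})
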