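test_that("triplet classification agrees with the explicit-form oracle on all 64 triples", {
  g <- expand.grid(p1 = 1:4, p2 = 1:4, p3 = 1:4)
  mine <- classify_triplet(g$p1, g$p2, g$p3)
  ref <- mapply(brute_triplet, g$p1, g$p2, g$p3)
  expect_equal(mine, unname(ref))
  # the four categories partition the 64 triples
  expect_equal(as.vector(table(factor(mine, triplet_categories()))),
               c(16L, 12L, 4L, 32L))
  expect_equal(classify_triplet(4, 1, 3), "pattern_consistent")
  expect_equal(classify_triplet(1, 1, 1), "repetition")
  expect_equal(classify_triplet(2, 3, 2), "span")
  expect_equal(classify_triplet(4, 2, 2), "inconsistent")
  expect_error(classify_triplet(0, 1, 2), "positions")
})

test_that("overlapping windowing yields length minus two triplets", {
  prof <- agent_profile("g1", "single")
  gen <- simulate_generation(prof, "inclusion", seed = 5)
  tc <- code_triplets(gen$positions)
  expect_equal(tc$n_triplets, 78L)
  expect_equal(sum(tc$proportions), 1)
  # hand-coded example: (4,1,3) and (3,2,2) instantiate the 4-r-3 and 3-r-2
  # pattern-consistent forms; (1,3,2) matches no positive rule
  tc2 <- code_triplets(c(4, 1, 3, 2, 2))
  expect_equal(unname(tc2$proportions["pattern_consistent"]), 2 / 3)
  expect_equal(unname(tc2$proportions["inconsistent"]), 1 / 3)
  expect_equal(code_triplets(c(1, 2, 3))$n_triplets, 1L)
  expect_error(code_triplets(c(1, 2)), "at least 3")
})

test_that("DSC scoring truncates to recorded trials and splits confidence by outcome", {
  cfg <- dsc_config()
  rec <- data.frame(
    participant_id = "p1", block = 1L, trial = 1:20,
    start_workforce = 100, chosen_workforce = 600,
    error = 0,
    production = c(rep(9000, 19), 7000),  # trial 20 off target but unrecorded
    on_target = c(rep(TRUE, 19), FALSE),
    confidence = 4
  )
  sc <- score_dsc(rec, cfg)
  expect_equal(sc$trials_on_target, 19L)
  expect_equal(sc$mean_confidence_on, 4)
  expect_true(is.na(sc$mean_confidence_off))

  rec2 <- rec
  rec2$production <- rep(c(9000, 6000), 10)
  rec2$on_target <- rep(c(TRUE, FALSE), 10)
  sc2 <- score_dsc(rec2, cfg)
  expect_equal(sc2$trials_on_target, 10L)  # 19 recorded: 10 on, 9 off
  expect_equal(sc2$mean_confidence_on, 4)
  expect_equal(sc2$mean_confidence_off, 4)
  expect_error(score_dsc(rec[, setdiff(names(rec), "on_target")]),
               "on_target")
})

test_that("ASRT scoring uses correct non-warm-up trials for medians", {
  rec <- data.frame(
    participant_id = "p1", block = 1L,
    trial_type = c(rep("warmup_random", 8), rep(c("pattern", "random"), 100)),
    correct = TRUE,
    rt_ms = c(rep(999, 8), rep(c(480, 500), 100))
  )
  sc <- score_asrt(rec)
  expect_equal(sc$median_rt_pattern, 480)
  expect_equal(sc$median_rt_random, 500)   # warm-up 999s excluded
  expect_equal(sc$pct_correct_all, 100)
  # errors on random trials are excluded from the random median only
  rec2 <- rec
  slow_err <- rec2$trial_type == "random" & rec2$rt_ms == 500
  rec2$rt_ms[slow_err][1:50] <- 2000
  rec2$correct[slow_err][1:50] <- FALSE
  sc2 <- score_asrt(rec2)
  expect_equal(sc2$median_rt_random, 500)
  expect_equal(sc2$pct_correct_random, 50)
  expect_equal(sc2$pct_correct_pattern, 100)
})

test_that("learning indices reproduce arithmetic cases and telescope exactly", {
  asrt <- data.frame(
    participant_id = "p1", block = 1:10,
    median_rt_pattern = 100,
    median_rt_random = 100 * (1 + 0.01 * (0:9)),
    pct_correct_pattern = 95, pct_correct_random = 94,
    pct_correct_all = 94.5
  )
  dsc <- data.frame(participant_id = "p1", block = 1:5,
                    trials_on_target = c(2, 3, 4, 5, 6),
                    mean_confidence_on = 4, mean_confidence_off = 3)
  li <- learning_indices(dsc, asrt)
  expect_equal(li$asrt_ratio_last_block, 1.09)
  expect_equal(li$asrt_cum_ratio_delta, 0.09)
  expect_equal(li$dsc_mean_on_target, 4)
  expect_equal(li$dsc_cum_block_delta, 4)

  # equal medians everywhere: ratio 1, cumulative difference 0
  asrt$median_rt_random <- 100
  li2 <- learning_indices(dsc, asrt)
  expect_equal(li2$asrt_ratio_last_block, 1)
  expect_equal(li2$asrt_cum_rt_diff, 0)

  # telescoping identity on arbitrary positive medians
  set.seed(9)
  asrt$median_rt_random <- runif(10, 400, 600)
  asrt$median_rt_pattern <- runif(10, 400, 600)
  li3 <- learning_indices(dsc, asrt)
  ratio <- asrt$median_rt_random / asrt$median_rt_pattern
  expect_equal(li3$asrt_cum_ratio_delta, ratio[10] - ratio[1])
  expect_equal(li3$dsc_cum_block_delta,
               dsc$trials_on_target[5] - dsc$trials_on_target[1])
})
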