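#' Behavioural profile of a synthetic participant
#'
#' Collects every parameter governing one simulated participant's behaviour
#' on both tasks, the generation task and the questionnaire. The cohort
#' generator instantiates profiles from archetypes ([default_cohort_spec()]),
#' but profiles can be built directly for targeted simulations.
#'
#' @param participant_id Identifier string.
#' @param condition `"single"` (everything in one sitting) or `"multiple"`
#'   (the same exposure spread over five daily sessions).
#' @param dsc_policy Worker-input policy: `"random"`, `"anchored"` (stays
#'   near the randomized start value; the response-bias case) or
#'   `"inversion_learner"` (applies the inversion of the production law with
#'   some probability).
#' @param dsc_knowledge Probability of applying the inversion rule in block
#'   1 (inversion learner only).
#' @param dsc_knowledge_gain Per-block increment of that probability
#'   (learning with practice); capped at 1.
#' @param anchor_strength Mean circular adjustment in grid steps for the
#'   anchored policy; below 2 the bias screen is designed to exclude the
#'   agent.
#' @param asrt_baseline_rt Mean reaction time in block 1, ms.
#' @param asrt_block_gain General speed-up per block, ms (practice effect
#'   common to both trial types).
#' @param asrt_pattern_advantage Pattern-trial RT advantage reached in the
#'   final block, ms; the advantage grows linearly from 0 in block 1
#'   (sequence learning expresses itself with practice).
#' @param asrt_rt_noise Scale (ms) of the exponential component of the
#'   positively skewed ex-Gaussian trial noise; a Gaussian component with
#'   20 ms SD is always added, and RTs are floored at 150 ms.
#' @param asrt_error_rate Error probability on pattern trials.
#' @param asrt_error_rate_random Error probability on random (and warm-up)
#'   trials.
#' @param negligent If `TRUE`, one block is answered nearly at random
#'   (error probability 0.6), which the 75 percent accuracy screen must
#'   detect.
#' @param aware_dsc If `TRUE`, confidence ratings track trial outcome
#'   (higher when on target); otherwise confidence is independent of
#'   outcome.
#' @param aware_asrt If `TRUE`, the questionnaire allocates five or more
#'   points to the sequence aspect.
#' @param generation_knowledge Probability of emitting the pattern successor
#'   of the position two back at alternate slots of a generated sequence.
#' @param exclusion_control Probability of successfully suppressing that
#'   successor under exclusion instructions; the remainder of the time the
#'   learned regularity is applied automatically, as under inclusion.
#' @param confidence_base Centre of the ordinal confidence scale used by the
#'   agent.
#' @param confidence_shift Added to the confidence centre on on-target
#'   trials when `aware_dsc`.
#' @param confidence_noise SD of the Gaussian confidence noise before
#'   rounding and clipping to the 1-6 scale.
#' @return An object of class `"agent_profile"`.
#' @export
agent_profile <- function(participant_id,
                          condition = c("single", "multiple"),
                          dsc_policy = c("inversion_learner", "random",
                                         "anchored"),
                          dsc_knowledge = 0.08,
                          dsc_knowledge_gain = 0.04,
                          anchor_strength = 0.8,
                          asrt_baseline_rt = 530,
                          asrt_block_gain = 7,
                          asrt_pattern_advantage = 10,
                          asrt_rt_noise = 60,
                          asrt_error_rate = 0.04,
                          asrt_error_rate_random = 0.055,
                          negligent = FALSE,
                          aware_dsc = FALSE,
                          aware_asrt = FALSE,
                          generation_knowledge = 0.16,
                          exclusion_control = 0.1,
                          confidence_base = 3,
                          confidence_shift = 1.5,
                          confidence_noise = 0.8) {
  condition <- match.arg(condition)
  dsc_policy <- match.arg(dsc_policy)
  probs <- c(dsc_knowledge, dsc_knowledge_gain, asrt_error_rate,
             asrt_error_rate_random, generation_knowledge, exclusion_control)
  if (any(probs < 0) || any(c(dsc_knowledge, asrt_error_rate,
                              asrt_error_rate_random, generation_knowledge,
                              exclusion_control) > 1)) {
    stop("probability parameters must lie in [0, 1]")
  }
  if (asrt_baseline_rt <= 0 || asrt_rt_noise <= 0) {
    stop("reaction-time parameters must be positive")
  }
  if (anchor_strength < 0) stop("anchor_strength must be non-negative")
  structure(
    list(participant_id = participant_id, condition = condition,
         dsc_policy = dsc_policy, dsc_knowledge = dsc_knowledge,
         dsc_knowledge_gain = dsc_knowledge_gain,
         anchor_strength = anchor_strength,
         asrt_baseline_rt = asrt_baseline_rt,
         asrt_block_gain = asrt_block_gain,
         asrt_pattern_advantage = asrt_pattern_advantage,
         asrt_rt_noise = asrt_rt_noise,
         asrt_error_rate = asrt_error_rate,
         asrt_error_rate_random = asrt_error_rate_random,
         negligent = negligent, aware_dsc = aware_dsc,
         aware_asrt = aware_asrt,
         generation_knowledge = generation_knowledge,
         exclusion_control = exclusion_control,
         confidence_base = confidence_base,
         confidence_shift = confidence_shift,
         confidence_noise = confidence_noise),
    class = "agent_profile"
  )
}

.dsc_policy_for_block <- function(profile, block, cfg) {
  switch(profile$dsc_policy,
    random = dsc_policy_random(cfg),
    anchored = dsc_policy_anchored(profile$anchor_strength, cfg),
    inversion_learner = dsc_policy_inversion(
      min(1, profile$dsc_knowledge +
            profile$dsc_knowledge_gain * (block - 1)), cfg)
  )
}

.ordinal_confidence <- function(raw, levels) {
  pmin(levels, pmax(1, round(raw)))
}

#' Simulate a participant's sugar-factory session
#'
#' Runs the participant's worker-input policy for every block (inversion
#' knowledge may grow per block) and attaches confidence ratings: aware
#' agents centre their rating higher on on-target trials, unaware agents
#' rate independently of outcome; Gaussian noise is rounded and clipped to
#' the ordinal 1-6 scale. In the multiple condition DSC block b belongs to
#' session b.
#'
#' @param profile An [agent_profile()].
#' @param cfg A [dsc_config()].
#' @param seed Optional integer seed.
#' @return DSC trial data frame with `participant_id`, `condition`,
#'   `session`, and the [run_dsc_block()] columns plus `confidence`.
#' @export
simulate_dsc_agent <- function(profile, cfg = dsc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(cfg$n_blocks), function(b) {
    run_dsc_block(.dsc_policy_for_block(profile, b, cfg), cfg, block = b)
  }))
  n <- nrow(recs)
  raw <- profile$confidence_base + stats::rnorm(n, 0, profile$confidence_noise)
  if (profile$aware_dsc) {
    raw <- raw + profile$confidence_shift * recs$on_target
  }
  recs$confidence <- .ordinal_confidence(raw, cfg$confidence_levels)
  data.frame(
    participant_id = profile$participant_id,
    condition = profile$condition,
    session = if (profile$condition == "multiple") recs$block else 1L,
    recs
  )
}

#' Simulate a participant's ASRT session
#'
#' Generates the stimulus stream with [make_asrt_session()] and layers the
#' agent's response model on top: mean RT falls linearly with block
#' (general practice), pattern trials gain an advantage that grows linearly
#' to `asrt_pattern_advantage` ms in the final block, and ex-Gaussian noise
#' (Gaussian SD 20 ms plus exponential with scale `asrt_rt_noise`) is added,
#' floored at 150 ms. Correctness is Bernoulli per trial type; a negligent
#' agent answers one randomly chosen block with error probability 0.6, which
#' forces that block under the 75 percent accuracy screen. In the multiple
#' condition ASRT blocks 2b-1 and 2b belong to session b.
#'
#' @param profile An [agent_profile()].
#' @param cfg An [asrt_config()].
#' @param seed Optional integer seed.
#' @return ASRT trial data frame with `participant_id`, `condition`,
#'   `session`, `block`, `index`, `trial_type`, `target`, `response`,
#'   `correct`, `rt_ms`.
#' @export
simulate_asrt_agent <- function(profile, cfg = asrt_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stream <- make_asrt_session(cfg)
  n <- nrow(stream)
  is_pat <- stream$trial_type == "pattern"
  adv_frac <- if (cfg$n_blocks > 1) {
    (stream$block - 1) / (cfg$n_blocks - 1)
  } else 1
  mu <- profile$asrt_baseline_rt -
    profile$asrt_block_gain * (stream$block - 1) -
    profile$asrt_pattern_advantage * adv_frac * is_pat
  rt <- pmax(150, mu + stats::rnorm(n, 0, 20) +
               stats::rexp(n, 1 / profile$asrt_rt_noise))
  err_p <- ifelse(is_pat, profile$asrt_error_rate,
                  profile$asrt_error_rate_random)
  if (profile$negligent) {
    bad_block <- sample(cfg$n_blocks, 1L)
    err_p[stream$block == bad_block] <- 0.6
  }
  correct <- stats::runif(n) >= err_p
  wrong <- (stream$target - 1L +
              sample(cfg$n_positions - 1L, n, replace = TRUE)) %%
    cfg$n_positions + 1L
  data.frame(
    participant_id = profile$participant_id,
    condition = profile$condition,
    session = if (profile$condition == "multiple") {
      ceiling(stream$block / 2)
    } else 1L,
    block = stream$block,
    index = stream$index,
    trial_type = stream$trial_type,
    target = stream$target,
    response = ifelse(correct, stream$target, wrong),
    correct = correct,
    rt_ms = rt
  )
}

#' Simulate one generation-task sequence
#'
#' Produces an 80-position sequence under inclusion or exclusion
#' instructions. At every second slot (from slot 3 on) the agent considers
#' the pattern successor of the position two back: under inclusion it emits
#' it with probability `generation_knowledge`, otherwise responds uniformly;
#' under exclusion it first suppresses the successor with probability
#' `exclusion_control` (choosing uniformly among the other positions), and
#' with the remaining probability applies the learned regularity
#' automatically, exactly as under inclusion. Every emission passes through
#' the run-length constraint ([constrain_generation_input()]); a rejected
#' emission is replaced by a uniform draw among admissible positions.
#'
#' @param profile An [agent_profile()].
#' @param mode `"inclusion"` or `"exclusion"`.
#' @param cfg An [asrt_config()].
#' @param seed Optional integer seed.
#' @return An object of class `"generation_record"`: list with `mode` and
#'   `positions` (integer vector of length `generation_length`).
#' @export
simulate_generation <- function(profile, mode = c("inclusion", "exclusion"),
                                cfg = asrt_config(), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  np <- cfg$n_positions
  L <- cfg$generation_length
  pos <- integer(L)
  know_parity <- sample(0:1, 1L)
  for (s in seq_len(L)) {
    cand <- NA_integer_
    if (s >= 3L && s %% 2L == know_parity) {
      succ <- pattern_successor(pos[s - 2L], cfg)
      if (mode == "exclusion" && stats::runif(1L) < profile$exclusion_control) {
        cand <- sample(setdiff(seq_len(np), succ), 1L)
      } else if (stats::runif(1L) < profile$generation_knowledge) {
        cand <- succ
      }
    }
    if (is.na(cand)) cand <- sample(np, 1L)
    if (!constrain_generation_input(cand, pos[seq_len(s - 1L)],
                                    cfg$max_run_length)) {
      allowed <- seq_len(np)[vapply(seq_len(np), function(p) {
        constrain_generation_input(p, pos[seq_len(s - 1L)],
                                   cfg$max_run_length)
      }, logical(1))]
      cand <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }
    pos[s] <- cand
  }
  structure(list(mode = mode, positions = pos), class = "generation_record")
}

#' Simulate the weighted-choice questionnaire
#'
#' Twelve points are allocated across the four aspects. An aware agent puts
#' five to nine points on the sequence aspect (aspect 1), an unaware agent
#' zero to four; the remainder is spread multinomially over the other three
#' aspects. The total is always 12.
#'
#' @param profile An [agent_profile()].
#' @param seed Optional integer seed.
#' @return Data frame with `aspect_id` (1-4) and `points`.
#' @export
simulate_questionnaire <- function(profile, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a1 <- if (profile$aware_asrt) sample(5:9, 1L) else sample(0:4, 1L)
  rest <- stats::rmultinom(1, 12 - a1, rep(1 / 3, 3))[, 1]
  data.frame(aspect_id = 1:4, points = c(a1, rest))
}

#' Default cohort composition
#'
#' One row per condition and archetype with the number of agents to
#' simulate. The default demo cohort has 33 participants per condition and
#' plants, by construction, 8 single / 5 multiple response-biased
#' (anchored) agents, 7 / 2 negligent agents, 3 / 6 agents whose confidence
#' tracks outcome, and 2 / 4 agents with reportable sequence knowledge; the
#' remainder are ordinary implicit learners.
#'
#' @return Data frame with columns `condition`, `archetype`, `n`.
#' @export
default_cohort_spec <- function() {
  rbind(
    data.frame(condition = "single",
               archetype = c("learner", "anchored", "negligent",
                             "aware_dsc", "aware_asrt"),
               n = c(13L, 8L, 7L, 3L, 2L)),
    data.frame(condition = "multiple",
               archetype = c("learner", "anchored", "negligent",
                             "aware_dsc", "aware_asrt"),
               n = c(16L, 5L, 2L, 6L, 4L))
  )
}

#' Build a profile from an archetype name
#'
#' Archetypes: `"learner"` (ordinary implicit learner), `"anchored"`
#' (response-biased on the DSC task), `"negligent"` (fails the ASRT accuracy
#' screen), `"aware_dsc"` (confidence tracks outcome), `"aware_asrt"`
#' (reportable sequence knowledge, stronger generation knowledge and
#' exclusion control), `"null"` (no learning anywhere: random DSC policy, no
#' pattern advantage, no generation knowledge; the false-positive-rate
#' reference).
#'
#' @param archetype Archetype name.
#' @param participant_id,condition Passed to [agent_profile()].
#' @param ... Overrides passed on to [agent_profile()].
#' @return An [agent_profile()].
#' @export
archetype_profile <- function(archetype, participant_id, condition, ...) {
  base <- list(participant_id = participant_id, condition = condition, ...)
  extra <- switch(archetype,
    learner = list(),
    anchored = list(dsc_policy = "anchored"),
    negligent = list(negligent = TRUE),
    aware_dsc = list(aware_dsc = TRUE),
    aware_asrt = list(aware_asrt = TRUE, generation_knowledge = 0.35,
                      exclusion_control = 0.5),
    null = list(dsc_policy = "random", asrt_pattern_advantage = 0,
                generation_knowledge = 0, exclusion_control = 0),
    stop(sprintf("unknown archetype '%s'", archetype))
  )
  do.call(agent_profile, utils::modifyList(base, extra))
}

.simulate_participant <- function(profile, dsc_cfg, asrt_cfg, seed) {
  set.seed(seed)
  dsc <- simulate_dsc_agent(profile, dsc_cfg)
  asrt <- simulate_asrt_agent(profile, asrt_cfg)
  gen <- lapply(c("inclusion", "exclusion"), function(m) {
    simulate_generation(profile, m, asrt_cfg)
  })
  qn <- simulate_questionnaire(profile)
  qn <- data.frame(participant_id = profile$participant_id, qn)
  gen_df <- do.call(rbind, lapply(gen, function(g) {
    data.frame(participant_id = profile$participant_id, mode = g$mode,
               serial = seq_along(g$positions), position = g$positions)
  }))
  structure(
    list(profile = profile, dsc = dsc, asrt = asrt, generation = gen_df,
         questionnaire = qn, seed = seed),
    class = "participant_dataset"
  )
}

#' Generate a synthetic cohort
#'
#' Simulates every agent listed in the cohort spec, with a per-participant
#' seed drawn once from the master seed so the whole cohort is reproducible.
#' In the multiple condition DSC block b and ASRT blocks 2b-1, 2b carry
#' session tag b (one DSC block plus two ASRT blocks per day over five
#' days); single-condition data carry session 1 throughout.
#'
#' @param spec Cohort composition as in [default_cohort_spec()].
#' @param dsc_cfg,asrt_cfg Task configurations.
#' @param seed Optional master seed.
#' @return An object of class `"implearn_cohort"`: a list of
#'   `participant_dataset` objects.
#' @export
generate_cohort <- function(spec = default_cohort_spec(),
                            dsc_cfg = dsc_config(),
                            asrt_cfg = asrt_config(),
                            seed = NULL) {
  stopifnot(all(spec$n >= 0))
  if (!is.null(seed)) set.seed(seed)
  spec <- spec[spec$n > 0, , drop = FALSE]
  rows <- spec[rep(seq_len(nrow(spec)), spec$n), c("condition", "archetype")]
  n_total <- nrow(rows)
  if (n_total == 0) return(structure(list(), class = "implearn_cohort"))
  seeds <- sample.int(.Machine$integer.max, n_total)
  out <- lapply(seq_len(n_total), function(i) {
    id <- sprintf("%s_%03d", substr(rows$condition[i], 1, 1), i)
    prof <- archetype_profile(rows$archetype[i], id, rows$condition[i])
    .simulate_participant(prof, dsc_cfg, asrt_cfg, seeds[i])
  })
  structure(out, class = "implearn_cohort")
}

#' Simulate a cohort with a shared latent ability
#'
#' Draws a bivariate-normal latent ability per agent with correlation `rho`
#' between the DSC component and the ASRT component, maps the components to
#' inversion knowledge (0 to 0.4, flat across blocks) and final-block
#' pattern advantage (0 to 25 ms), and simulates both tasks (generation and
#' questionnaire are skipped; this cohort exists to study cross-task
#' correlation of learning indices).
#'
#' @param n Number of agents.
#' @param rho Latent correlation between the two task abilities.
#' @param seed Optional seed.
#' @param dsc_cfg,asrt_cfg Task configurations.
#' @return List with `dsc` and `asrt` trial data frames (all agents) and
#'   `abilities` (data frame of the latent values and mapped parameters).
#' @export
simulate_ability_cohort <- function(n, rho, seed = NULL,
                                    dsc_cfg = dsc_config(),
                                    asrt_cfg = asrt_config()) {
  stopifnot(n >= 3, abs(rho) <= 1)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  know <- 0.4 * stats::pnorm(z1)
  adv <- 25 * stats::pnorm(z2)
  seeds <- sample.int(.Machine$integer.max, n)
  dsc <- vector("list", n)
  asrt <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- agent_profile(sprintf("a_%03d", i), "single",
                          dsc_knowledge = know[i], dsc_knowledge_gain = 0,
                          asrt_pattern_advantage = adv[i])
    set.seed(seeds[i])
    dsc[[i]] <- simulate_dsc_agent(prof, dsc_cfg)
    asrt[[i]] <- simulate_asrt_agent(prof, asrt_cfg)
  }
  list(dsc = do.call(rbind, dsc), asrt = do.call(rbind, asrt),
       abilities = data.frame(participant_id = sprintf("a_%03d", seq_len(n)),
                              z_dsc = z1, z_asrt = z2,
                              dsc_knowledge = know, pattern_advantage = adv))
}
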