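.log_schemas <- list(
  dsc = c("participant_id", "condition", "session", "block", "trial",
          "start_workforce", "chosen_workforce", "error", "production",
          "on_target", "confidence"),
  asrt = c("participant_id", "condition", "session", "block", "index",
           "trial_type", "target", "response", "correct", "rt_ms"),
  generation = c("participant_id", "mode", "serial", "position"),
  questionnaire = c("participant_id", "aspect_id", "points"),
  participants = c("participant_id", "condition")
)

#' Flatten a cohort into the canonical session-log tables
#'
#' @param cohort An `implearn_cohort` or an existing `session_logs` object
#'   (returned unchanged).
#' @return An object of class `"session_logs"`: a list of data frames
#'   `dsc`, `asrt`, `generation`, `questionnaire`, `participants` (blinded:
#'   id and condition only) and, when built from a cohort, `profiles`
#'   (ground truth: archetype-level flags per participant).
#' @export
as_session_logs <- function(cohort) {
  if (inherits(cohort, "session_logs")) return(cohort)
  if (!inherits(cohort, "implearn_cohort")) {
    stop("expected an implearn_cohort or session_logs object")
  }
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  if (length(cohort) == 0) {
    logs <- lapply(.log_schemas, empty)
    logs$profiles <- empty(c("participant_id", "condition"))
    return(structure(logs, class = "session_logs"))
  }
  bind <- function(field) {
    do.call(rbind, lapply(cohort, function(p) p[[field]]))
  }
  dsc <- bind("dsc")
  asrt <- bind("asrt")
  gen <- bind("generation")
  qn <- bind("questionnaire")
  profiles <- do.call(rbind, lapply(cohort, function(p) {
    pr <- p$profile
    data.frame(participant_id = pr$participant_id, condition = pr$condition,
               dsc_policy = pr$dsc_policy, anchor_strength = pr$anchor_strength,
               negligent = pr$negligent, aware_dsc = pr$aware_dsc,
               aware_asrt = pr$aware_asrt,
               generation_knowledge = pr$generation_knowledge,
               seed = p$seed)
  }))
  rownames(profiles) <- NULL
  structure(
    list(dsc = dsc, asrt = asrt, generation = gen, questionnaire = qn,
         participants = profiles[, c("participant_id", "condition")],
         profiles = profiles),
    class = "session_logs"
  )
}

#' Write session logs as CSV files
#'
#' Writes the canonical UTF-8, header-row CSV files: `dsc.csv`, `asrt.csv`,
#' `generation.csv`, `questionnaire.csv`, the blinded `participants.csv`,
#' and (when available) the ground-truth `profiles_ground_truth.csv`.
#'
#' @param cohort An `implearn_cohort` or `session_logs` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_session_logs <- function(cohort, dir) {
  logs <- as_session_logs(cohort)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(dsc = "dsc.csv", asrt = "asrt.csv", generation = "generation.csv",
             questionnaire = "questionnaire.csv",
             participants = "participants.csv")
  paths <- character(0)
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    utils::write.csv(logs[[nm]], path, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  if (!is.null(logs$profiles)) {
    path <- file.path(dir, "profiles_ground_truth.csv")
    utils::write.csv(logs$profiles, path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read session logs from CSV files
#'
#' Reads the tables written by [write_session_logs()], validating that every
#' required column is present (a missing column is reported by name) and
#' that trial indices are monotone within participant and block. Writing and
#' re-reading a cohort reproduces the same tables.
#'
#' @param dir Directory containing the CSV files.
#' @return A `"session_logs"` object.
#' @export
read_session_logs <- function(dir) {
  read_one <- function(nm, file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop(sprintf("missing session log '%s'", file))
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    miss <- setdiff(.log_schemas[[nm]], names(df))
    if (length(miss)) {
      stop(sprintf("schema error in %s: missing column '%s'", file, miss[1]))
    }
    if (nrow(df) == 0) warning(sprintf("empty session log '%s'", file))
    df
  }
  logs <- list(
    dsc = read_one("dsc", "dsc.csv"),
    asrt = read_one("asrt", "asrt.csv"),
    generation = read_one("generation", "generation.csv"),
    questionnaire = read_one("questionnaire", "questionnaire.csv"),
    participants = read_one("participants", "participants.csv")
  )
  check_monotone <- function(df, idx_col, what) {
    if (nrow(df) == 0) return(invisible())
    sp <- split(df[[idx_col]], list(df$participant_id, df$block), drop = TRUE)
    bad <- vapply(sp, function(x) any(diff(x) <= 0), logical(1))
    if (any(bad)) {
      stop(sprintf("schema error in %s: non-monotone trial indices (%s)",
                   what, names(sp)[bad][1]))
    }
  }
  check_monotone(logs$dsc, "trial", "dsc.csv")
  check_monotone(logs$asrt, "index", "asrt.csv")
  if (nrow(logs$asrt) &&
      !all(logs$asrt$trial_type %in%
             c("warmup_random", "random", "pattern"))) {
    stop("schema error in asrt.csv: bad trial_type value")
  }
  structure(logs, class = "session_logs")
}

.config_hash <- function(...) {
  txt <- paste(vapply(list(...), function(x) paste(deparse(x), collapse = ""),
                      character(1)), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

.gen_scores <- function(gen, cfg) {
  if (nrow(gen) == 0) return(NULL)
  parts <- split(gen, list(gen$participant_id, gen$mode), drop = TRUE)
  out <- lapply(parts, function(d) {
    d <- d[order(d$serial), ]
    tc <- code_triplets(d$position, cfg)
    data.frame(participant_id = d$participant_id[1], mode = d$mode[1],
               prop_pattern_consistent =
                 unname(tc$proportions["pattern_consistent"]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.anova_or_null <- function(expr, label) {
  tryCatch(expr, error = function(e) {
    message(sprintf("stage '%s' skipped: %s", label, conditionMessage(e)))
    NULL
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: scoring of both tasks, the data-reduction screens and
#' awareness criteria, the chance baselines, the mixed-design ANOVAs
#' (trials on target by session and block; confidence by session, block and
#' outcome; ASRT median RT and percent correct by session, block and trial
#' type; generation proportion pattern-consistent by session and task), the
#' cross-task learning-index correlations, and a robustness re-analysis with
#' aware participants excluded. Participants are excluded independently per
#' task, and the intersection of retained participants feeds the
#' correlations.
#'
#' @param cohort An `implearn_cohort` or `session_logs` object.
#' @param dsc_cfg,asrt_cfg,scr Task and screening configurations.
#' @param chance_replicates Monte-Carlo replicates for the DSC chance level.
#' @param stream_blocks Simulated blocks for the ASRT stream triplet
#'   expectation.
#' @param run_chance Include the chance stage?
#' @param seed Seed for the stochastic chance computations.
#' @param out_dir If non-`NULL`, every artifact is also written there as CSV
#'   together with run metadata (seed and configuration hash).
#' @return A report bundle: list with `scores`, `screening`,
#'   `exclusion_counts`, `chance`, `anova`, `correlations`,
#'   `anova_aware_excluded`, `meta`.
#' @export
run_pipeline <- function(cohort, dsc_cfg = dsc_config(),
                         asrt_cfg = asrt_config(),
                         scr = screening_config(),
                         chance_replicates = 10000,
                         stream_blocks = 200,
                         run_chance = TRUE,
                         seed = NULL,
                         out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  logs <- as_session_logs(cohort)

  dsc_scores <- if (nrow(logs$dsc)) score_dsc(logs$dsc, dsc_cfg) else NULL
  asrt_scores <- if (nrow(logs$asrt)) score_asrt(logs$asrt) else NULL
  gen_scores <- .gen_scores(logs$generation, asrt_cfg)

  screening <- if (nrow(logs$dsc)) {
    screen_cohort(logs, dsc_cfg, asrt_cfg, scr)
  } else NULL

  exclusion_counts <- if (!is.null(screening)) {
    agg <- function(flag) {
      tapply(screening[[flag]], screening$condition, sum, na.rm = TRUE)
    }
    list(dsc_bias = agg("excluded_dsc_bias"),
         dsc_zero_target_block = agg("excluded_dsc_zero_target_block"),
         asrt_accuracy = agg("excluded_asrt_accuracy"),
         aware_dsc = agg("aware_dsc"),
         aware_asrt = agg("aware_asrt"))
  } else NULL
  if (!is.null(exclusion_counts)) {
    message(sprintf(
      "screens: %d bias-excluded, %d zero-target-block, %d accuracy-excluded",
      sum(screening$excluded_dsc_bias),
      sum(screening$excluded_dsc_zero_target_block),
      sum(screening$excluded_asrt_accuracy)))
  }

  chance <- if (run_chance) {
    list(
      dsc_monte_carlo = dsc_chance_simulation(
        chance_replicates, dsc_cfg$recorded_trials_per_block, dsc_cfg),
      dsc_exact = dsc_chance_exact(dsc_cfg$recorded_trials_per_block, dsc_cfg),
      triplets = triplet_chance_enumeration(asrt_cfg),
      circular = expected_circular_change(dsc_cfg),
      asrt_stream = asrt_stream_triplet_expectation(asrt_cfg, stream_blocks)
    )
  } else NULL

  cond_of <- function(ids) {
    logs$participants$condition[match(ids, logs$participants$participant_id)]
  }
  retained_dsc <- if (!is.null(screening)) {
    screening$participant_id[!screening$excluded_dsc_bias]
  } else character(0)
  retained_conf <- if (!is.null(screening)) {
    screening$participant_id[!screening$excluded_dsc_bias &
                               !screening$excluded_dsc_zero_target_block]
  } else character(0)
  retained_asrt <- if (!is.null(screening)) {
    screening$participant_id[!screening$excluded_asrt_accuracy]
  } else character(0)

  build_anovas <- function(keep_dsc, keep_conf, keep_asrt) {
    res <- list()
    ds <- dsc_scores[dsc_scores$participant_id %in% keep_dsc, , drop = FALSE]
    if (length(unique(cond_of(unique(ds$participant_id)))) == 2) {
      d <- ds
      d$session_type <- cond_of(d$participant_id)
      res$dsc_on_target <- .anova_or_null(
        mixed_anova(d, dv = "trials_on_target", id = "participant_id",
                    within = "block", between = "session_type"),
        "ANOVA trials on target")
    }
    dc <- dsc_scores[dsc_scores$participant_id %in% keep_conf, , drop = FALSE]
    if (nrow(dc)) {
      long <- rbind(
        data.frame(participant_id = dc$participant_id, block = dc$block,
                   target = "on", confidence = dc$mean_confidence_on),
        data.frame(participant_id = dc$participant_id, block = dc$block,
                   target = "off", confidence = dc$mean_confidence_off))
      long$session_type <- cond_of(long$participant_id)
      res$dsc_confidence <- .anova_or_null(
        suppressWarnings(
          mixed_anova(long, dv = "confidence", id = "participant_id",
                      within = c("block", "target"),
                      between = "session_type")),
        "ANOVA confidence")
    }
    as <- asrt_scores[asrt_scores$participant_id %in% keep_asrt, , drop = FALSE]
    if (nrow(as)) {
      long_rt <- rbind(
        data.frame(participant_id = as$participant_id, block = as$block,
                   trial_type = "pattern", y = as$median_rt_pattern),
        data.frame(participant_id = as$participant_id, block = as$block,
                   trial_type = "random", y = as$median_rt_random))
      long_rt$session_type <- cond_of(long_rt$participant_id)
      res$asrt_rt <- .anova_or_null(
        suppressWarnings(
          mixed_anova(long_rt, dv = "y", id = "participant_id",
                      within = c("block", "trial_type"),
                      between = "session_type")),
        "ANOVA ASRT RT")
      long_acc <- rbind(
        data.frame(participant_id = as$participant_id, block = as$block,
                   trial_type = "pattern", y = as$pct_correct_pattern),
        data.frame(participant_id = as$participant_id, block = as$block,
                   trial_type = "random", y = as$pct_correct_random))
      long_acc$session_type <- cond_of(long_acc$participant_id)
      res$asrt_accuracy <- .anova_or_null(
        suppressWarnings(
          mixed_anova(long_acc, dv = "y", id = "participant_id",
                      within = c("block", "trial_type"),
                      between = "session_type")),
        "ANOVA ASRT accuracy")
    }
    gs <- gen_scores[gen_scores$participant_id %in% keep_asrt, , drop = FALSE]
    if (!is.null(gen_scores) && nrow(gs)) {
      gs$session_type <- cond_of(gs$participant_id)
      res$generation <- .anova_or_null(
        mixed_anova(gs, dv = "prop_pattern_consistent",
                    id = "participant_id", within = "mode",
                    between = "session_type"),
        "ANOVA generation")
    }
    res
  }

  anova_tables <- if (!is.null(dsc_scores) && !is.null(asrt_scores)) {
    build_anovas(retained_dsc, retained_conf, retained_asrt)
  } else list()

  correlations <- NULL
  both <- intersect(retained_dsc, retained_asrt)
  if (length(both) >= 3 && !is.null(dsc_scores) && !is.null(asrt_scores)) {
    idx <- learning_indices(
      dsc_scores[dsc_scores$participant_id %in% both, , drop = FALSE],
      asrt_scores[asrt_scores$participant_id %in% both, , drop = FALSE])
    idx <- idx[stats::complete.cases(idx), , drop = FALSE]
    if (nrow(idx) >= 3) {
      correlations <- list(
        indices = idx,
        on_target_vs_ratio = .anova_or_null(
          pearson_correlation(idx$dsc_mean_on_target,
                              idx$asrt_ratio_last_block), "correlation 1"),
        on_target_vs_cum_rt_diff = .anova_or_null(
          pearson_correlation(idx$dsc_mean_on_target,
                              idx$asrt_cum_rt_diff), "correlation 2"),
        cum_delta_vs_cum_ratio_delta = .anova_or_null(
          pearson_correlation(idx$dsc_cum_block_delta,
                              idx$asrt_cum_ratio_delta), "correlation 3"))
    }
  }

  aware_dsc_ids <- if (!is.null(screening)) {
    screening$participant_id[screening$aware_dsc %in% TRUE]
  } else character(0)
  aware_asrt_ids <- if (!is.null(screening)) {
    screening$participant_id[screening$aware_asrt %in% TRUE]
  } else character(0)
  anova_aware_excluded <- if (length(anova_tables)) {
    build_anovas(setdiff(retained_dsc, aware_dsc_ids),
                 setdiff(retained_conf, aware_dsc_ids),
                 setdiff(retained_asrt, aware_asrt_ids))
  } else list()

  bundle <- list(
    scores = list(dsc = dsc_scores, asrt = asrt_scores,
                  generation = gen_scores),
    screening = screening,
    exclusion_counts = exclusion_counts,
    chance = chance,
    anova = anova_tables,
    correlations = correlations,
    anova_aware_excluded = anova_aware_excluded,
    meta = list(seed = seed,
                config_hash = .config_hash(dsc_cfg, asrt_cfg, scr),
                n_participants = nrow(logs$participants))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) {
        utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
      }
    }
    wr(dsc_scores, "scores_dsc.csv")
    wr(asrt_scores, "scores_asrt.csv")
    wr(gen_scores, "scores_generation.csv")
    wr(screening, "screening.csv")
    for (nm in names(anova_tables)) {
      wr(anova_tables[[nm]], sprintf("anova_%s.csv", nm))
    }
    if (!is.null(correlations)) wr(correlations$indices, "learning_indices.csv")
    meta_df <- data.frame(key = c("seed", "config_hash", "n_participants"),
                          value = c(if (is.null(seed)) NA else seed,
                                    bundle$meta$config_hash,
                                    bundle$meta$n_participants))
    wr(meta_df, "run_metadata.csv")
  }
  bundle
}
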