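#' Configuration of the alternating serial reaction time task
#'
#' Fixed parameters of the ASRT protocol: the cyclic pattern over the four
#' screen positions, the warm-up and alternating trial counts per block, the
#' number of blocks, and the generation-task settings.
#'
#' @param n_positions Number of screen positions (numbered left to right).
#' @param pattern The repeating cycle of pattern-trial positions. Must visit
#'   every position exactly once.
#' @param warmup_trials Random trials at the start of every block.
#' @param sequence_trials Alternating pattern/random trials per block; must
#'   be even and divide evenly across positions together with the warm-up.
#' @param n_blocks Blocks per session.
#' @param break_seconds Between-block break (metadata only; not simulated).
#' @param generation_length Length of a generated sequence in the
#'   inclusion/exclusion task.
#' @param max_run_length Longest admissible run of one position in the
#'   generation task; a fourth consecutive repeat is silently rejected.
#'
#' @return An object of class `"asrt_config"`.
#' @export
asrt_config <- function(n_positions = 4,
                        pattern = c(4, 3, 2, 1),
                        warmup_trials = 8,
                        sequence_trials = 200,
                        n_blocks = 10,
                        break_seconds = 15,
                        generation_length = 80,
                        max_run_length = 3) {
  if (!setequal(pattern, seq_len(n_positions)) ||
      length(pattern) != n_positions) {
    stop("pattern must visit every position exactly once")
  }
  if (sequence_trials %% 2L != 0L) {
    stop("sequence_trials must be even (pattern/random alternation)")
  }
  n_trials <- warmup_trials + sequence_trials
  if (n_trials %% n_positions != 0L ||
      (sequence_trials / 2) %% n_positions != 0L) {
    stop("trial counts must divide evenly across positions")
  }
  structure(
    list(
      n_positions = as.integer(n_positions),
      pattern = as.integer(pattern),
      warmup_trials = as.integer(warmup_trials),
      sequence_trials = as.integer(sequence_trials),
      n_blocks = as.integer(n_blocks),
      break_seconds = break_seconds,
      generation_length = as.integer(generation_length),
      max_run_length = as.integer(max_run_length)
    ),
    class = "asrt_config"
  )
}

#' Cyclic successor of a position under the repeating pattern
#'
#' With the default pattern 4, 3, 2, 1 the successors are 4 -> 3 -> 2 ->
#' 1 -> 4. Pattern-trial targets step through this cycle; a triplet whose
#' third element is the successor of its first is pattern-consistent.
#'
#' @param position Position(s) in `1:n_positions`.
#' @param cfg An [asrt_config()].
#' @return The successor position(s).
#' @export
pattern_successor <- function(position, cfg = asrt_config()) {
  idx <- match(position, cfg$pattern)
  if (anyNA(idx)) stop("position outside 1..n_positions")
  cfg$pattern[idx %% length(cfg$pattern) + 1L]
}

#' Label every trial of a block as warm-up, pattern or random
#'
#' Trial types are fixed by construction metadata, never inferred from the
#' data: the first `warmup_trials` trials are warm-up random trials, after
#' which pattern and random trials strictly alternate, starting with a
#' pattern trial iff `pattern_first`.
#'
#' @param cfg An [asrt_config()].
#' @param pattern_first Logical: is the first post-warm-up trial a pattern
#'   trial?
#' @return Character vector of length `warmup_trials + sequence_trials` with
#'   values `"warmup_random"`, `"pattern"`, `"random"`.
#' @export
classify_trial_types <- function(cfg = asrt_config(), pattern_first) {
  if (length(pattern_first) != 1L || is.na(pattern_first)) {
    stop("construction metadata (pattern_first) is required")
  }
  pair <- if (pattern_first) c("pattern", "random") else c("random", "pattern")
  c(rep("warmup_random", cfg$warmup_trials),
    rep(pair, cfg$sequence_trials / 2L))
}

#' Generate the target stream of one ASRT block
#'
#' Emits `warmup_trials + sequence_trials` targets. Pattern trials walk the
#' repeating cycle from a uniformly drawn starting phase; whether the first
#' post-warm-up trial is pattern or random is drawn uniformly. All random
#' trials (warm-up included) are a random permutation of a multiset balanced
#' so that every position occurs equally often in the whole block.
#'
#' @param cfg An [asrt_config()].
#' @param block 1-based block index stamped into the records.
#' @param seed Optional integer seed.
#' @return A data frame with `block`, `index`, `trial_type`, `target`, and
#'   attribute `meta` (list with `pattern_first` and starting `phase`).
#' @export
make_asrt_block <- function(cfg = asrt_config(), block = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- cfg$n_positions
  pattern_first <- sample(c(TRUE, FALSE), 1L)
  phase <- sample(length(cfg$pattern), 1L)
  types <- classify_trial_types(cfg, pattern_first)
  n <- length(types)
  is_pat <- types == "pattern"
  n_pat <- sum(is_pat)
  pat_targets <- cfg$pattern[(phase - 1L + seq_len(n_pat) - 1L) %% np + 1L]
  per_pos_total <- n %/% np
  rand_count <- per_pos_total - tabulate(pat_targets, np)
  if (any(rand_count < 0)) stop("pattern trials overfill the position balance")
  rand_targets <- sample(rep(seq_len(np), rand_count))
  targets <- integer(n)
  targets[is_pat] <- pat_targets
  targets[!is_pat] <- rand_targets
  out <- data.frame(
    block = as.integer(block),
    index = seq_len(n),
    trial_type = types,
    target = targets
  )
  attr(out, "meta") <- list(pattern_first = pattern_first, phase = phase)
  out
}

#' Generate a full ASRT session
#'
#' @param cfg An [asrt_config()].
#' @param seed Optional integer seed for the whole session.
#' @return A data frame of `n_blocks` blocks of targets (no responses).
#' @export
make_asrt_session <- function(cfg = asrt_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_len(cfg$n_blocks), function(b) {
    make_asrt_block(cfg, block = b)
  }))
}

#' The generation-task input constraint
#'
#' In the inclusion/exclusion generation task a run of identical positions
#' longer than `max_run_length` is silently rejected: a candidate equal to
#' each of the last `max_run_length` accepted positions is refused.
#'
#' @param candidate Candidate position.
#' @param history Accepted prefix of the generated sequence.
#' @param max_run_length Longest admissible run.
#' @return Logical: is the candidate accepted?
#' @export
constrain_generation_input <- function(candidate, history, max_run_length = 3L) {
  h <- length(history)
  if (h < max_run_length) return(TRUE)
  !all(history[(h - max_run_length + 1L):h] == candidate)
}
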