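#' Triplet category names
#'
#' The four categories that partition all ordered position triples:
#' `pattern_consistent` (third element is the cyclic successor of the
#' first), `span` (x-y-x), `repetition` (x-x-x) and `inconsistent`
#' (everything else).
#'
#' @return Character vector of the category names, in reporting order.
#' @export
triplet_categories <- function() {
  c("pattern_consistent", "span", "repetition", "inconsistent")
}

#' Classify an ordered position triple
#'
#' Categories are assigned with precedence repetition, then span, then
#' pattern-consistent (under any pattern that visits each position once the
#' three positive categories cannot overlap, because a position is never its
#' own successor; the precedence is stated for clarity and for robustness to
#' hypothetical patterns where it could matter).
#'
#' @param p1,p2,p3 Positions in `1:n_positions`. Vectorised.
#' @param cfg An [asrt_config()].
#' @return Character vector of categories.
#' @examples
#' classify_triplet(4, 1, 3) # pattern consistent: 4 -> r -> 3
#' classify_triplet(2, 3, 2) # span
#' @export
classify_triplet <- function(p1, p2, p3, cfg = asrt_config()) {
  pos <- c(p1, p2, p3)
  if (!all(pos %in% seq_len(cfg$n_positions))) {
    stop("positions must lie in 1..n_positions")
  }
  succ <- pattern_successor(p1, cfg)
  ifelse(p1 == p2 & p2 == p3, "repetition",
    ifelse(p1 == p3, "span",
      ifelse(p3 == succ, "pattern_consistent", "inconsistent")))
}

#' Reduce a position sequence to overlapping triplets
#'
#' Every window of three consecutive positions is classified with
#' [classify_triplet()]; a sequence of length `L` yields `L - 2` triplets
#' (an 80-trial generated sequence yields 78).
#'
#' @param positions Integer sequence of positions, length `>= 3`.
#' @param cfg An [asrt_config()].
#' @return An object of class `"triplet_counts"`: a list with `n_triplets`,
#'   integer `counts` and numeric `proportions`, both named by category.
#' @export
code_triplets <- function(positions, cfg = asrt_config()) {
  L <- length(positions)
  if (L < 3L) stop("need at least 3 positions to form a triplet")
  cats <- classify_triplet(positions[1:(L - 2L)],
                           positions[2:(L - 1L)],
                           positions[3:L], cfg)
  counts <- table(factor(cats, levels = triplet_categories()))
  counts <- stats::setNames(as.integer(counts), triplet_categories())
  structure(
    list(n_triplets = L - 2L, counts = counts,
         proportions = counts / (L - 2L)),
    class = "triplet_counts"
  )
}

#' @export
print.triplet_counts <- function(x, ...) {
  cat(sprintf("Triplet counts over %d windows:\n", x$n_triplets))
  print(round(x$proportions, 4))
  invisible(x)
}

.one_per <- function(df, col, default) {
  if (!col %in% names(df)) df[[col]] <- default
  df
}

#' Score sugar-factory trial records per block
#'
#' Keeps only the first `recorded_trials_per_block` trials of every block
#' (the logged protocol), counts trials on target, and splits mean
#' confidence by trial outcome. A block with no on-target (or no off-target)
#' trials yields `NA` for the corresponding confidence mean; such
#' participants are later screened case-wise.
#'
#' @param records DSC trial data frame as produced by [simulate_dsc_agent()]
#'   (columns `block`, `trial`, `production`, `on_target`, `confidence`, and
#'   optionally `participant_id`).
#' @param cfg A [dsc_config()].
#' @return Data frame with one row per participant and block:
#'   `participant_id`, `block`, `trials_on_target`, `mean_confidence_on`,
#'   `mean_confidence_off`.
#' @export
score_dsc <- function(records, cfg = dsc_config()) {
  req <- c("block", "trial", "on_target")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop(sprintf("malformed DSC log: missing column '%s'", miss[1]))
  }
  records <- .one_per(records, "participant_id", "p1")
  records <- .one_per(records, "confidence", NA_real_)
  rec <- records[records$trial <= cfg$recorded_trials_per_block, , drop = FALSE]
  parts <- split(rec, list(rec$participant_id, rec$block), drop = TRUE)
  out <- lapply(parts, function(d) {
    on <- d$on_target
    data.frame(
      participant_id = d$participant_id[1],
      block = d$block[1],
      trials_on_target = sum(on),
      mean_confidence_on = if (any(on)) mean(d$confidence[on]) else NA_real_,
      mean_confidence_off = if (any(!on)) mean(d$confidence[!on]) else NA_real_
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$participant_id, out$block), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score ASRT trial records per block and trial type
#'
#' Warm-up trials are excluded throughout. Median reaction times are
#' computed over correct trials only, separately for pattern and random
#' trials; percentage correct is computed over all non-warm-up trials of
#' each type, plus pooled across types (the accuracy screen operates on the
#' pooled value). A block with no correct trials of a type yields `NA` for
#' that median.
#'
#' @param records ASRT trial data frame (columns `block`, `trial_type`,
#'   `correct`, `rt_ms`, and optionally `participant_id`).
#' @return Data frame with one row per participant and block:
#'   `median_rt_pattern`, `median_rt_random`, `pct_correct_pattern`,
#'   `pct_correct_random`, `pct_correct_all`.
#' @export
score_asrt <- function(records) {
  req <- c("block", "trial_type", "correct", "rt_ms")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop(sprintf("malformed ASRT log: missing column '%s'", miss[1]))
  }
  records <- .one_per(records, "participant_id", "p1")
  rec <- records[records$trial_type != "warmup_random", , drop = FALSE]
  parts <- split(rec, list(rec$participant_id, rec$block), drop = TRUE)
  med_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_
  out <- lapply(parts, function(d) {
    pat <- d$trial_type == "pattern"
    data.frame(
      participant_id = d$participant_id[1],
      block = d$block[1],
      median_rt_pattern = med_or_na(d$rt_ms[pat & d$correct]),
      median_rt_random = med_or_na(d$rt_ms[!pat & d$correct]),
      pct_correct_pattern = 100 * mean(d$correct[pat]),
      pct_correct_random = 100 * mean(d$correct[!pat]),
      pct_correct_all = 100 * mean(d$correct)
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$participant_id, out$block), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-task learning indices per participant
#'
#' Computes the five indices used to relate learning across the two tasks:
#'
#' * `asrt_ratio_last_block`: median RT of random trials divided by median
#'   RT of pattern trials in the final block (dimensionless; relative
#'   measure robust to individual differences in overall speed).
#' * `asrt_cum_rt_diff`: the cumulative (summed over blocks) difference
#'   in median RT, random minus pattern, in ms.
#' * `asrt_cum_ratio_delta`: the cumulative successive-block difference of
#'   the random/pattern RT ratio; by telescoping this equals the last-block
#'   ratio minus the first-block ratio.
#' * `dsc_mean_on_target`: mean trials on target per block.
#' * `dsc_cum_block_delta`: cumulative successive-block difference in
#'   trials on target; telescopes to last block minus first block.
#'
#' A participant with an undefined median in any referenced block gets `NA`
#' indices and is dropped from correlations downstream.
#'
#' @param dsc_scores Output of [score_dsc()].
#' @param asrt_scores Output of [score_asrt()].
#' @return Data frame with one row per participant present in both inputs.
#' @export
learning_indices <- function(dsc_scores, asrt_scores) {
  ids <- intersect(unique(dsc_scores$participant_id),
                   unique(asrt_scores$participant_id))
  out <- lapply(ids, function(id) {
    ds <- dsc_scores[dsc_scores$participant_id == id, , drop = FALSE]
    as <- asrt_scores[asrt_scores$participant_id == id, , drop = FALSE]
    ds <- ds[order(ds$block), ]
    as <- as[order(as$block), ]
    ratio <- as$median_rt_random / as$median_rt_pattern
    nb <- nrow(as)
    data.frame(
      participant_id = id,
      asrt_ratio_last_block = ratio[nb],
      asrt_cum_rt_diff = sum(as$median_rt_random - as$median_rt_pattern),
      asrt_cum_ratio_delta = if (nb > 1) sum(diff(ratio)) else NA_real_,
      dsc_mean_on_target = mean(ds$trials_on_target),
      dsc_cum_block_delta = if (nrow(ds) > 1) {
        sum(diff(ds$trials_on_target))
      } else NA_real_
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
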