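.chance_estimate <- function(value, se, n_replicates, method) {
  structure(
    list(value = value, standard_error = se,
         n_replicates = as.integer(n_replicates), method = method),
    class = "chance_estimate"
  )
}

#' @export
print.chance_estimate <- function(x, ...) {
  cat(sprintf("Chance estimate (%s): %.4f (SE %.4f, replicates %d)\n",
              x$method, x$value, x$standard_error, x$n_replicates))
  invisible(x)
}

#' Monte-Carlo chance level for trials on target
#'
#' Simulates blocks of the sugar-factory task under uniform-random worker
#' input on every trial (start state: the displayed initial production) and
#' returns the mean number of on-target trials per block with its standard
#' error. With the default configuration and 19 recorded trials the chance
#' level is about 2.38 trials per block.
#'
#' @param n_replicates Number of simulated blocks.
#' @param trials Trials per simulated block (19 under the logged protocol).
#' @param cfg A [dsc_config()].
#' @param seed Optional integer seed.
#' @return A `"chance_estimate"` (value in trials on target per block).
#' @export
dsc_chance_simulation <- function(n_replicates = 10000, trials = 19,
                                  cfg = dsc_config(), seed = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (trials == 0) return(.chance_estimate(0, 0, n_replicates, "monte_carlo"))
  grid <- worker_grid(cfg)
  P <- rep(cfg$initial_production, n_replicates)
  counts <- numeric(n_replicates)
  for (t in seq_len(trials)) {
    W <- sample(grid, n_replicates, replace = TRUE)
    E <- sample(cfg$error_values, n_replicates, replace = TRUE)
    P <- pmin(pmax(cfg$gain * W - P + E, cfg$production_min),
              cfg$production_max)
    counts <- counts + (abs(P - cfg$target_production) <=
                          cfg$on_target_halfwidth)
  }
  .chance_estimate(mean(counts), stats::sd(counts) / sqrt(n_replicates),
                   n_replicates, "monte_carlo")
}

#' Exact chance level for trials on target
#'
#' The production state only takes the thousand-ton grid values (the grid is
#' closed under the production law with clamping), so chance performance
#' under uniform-random worker input is a small Markov chain. This
#' enumerates the 36 (worker, error) outcomes from every state to build the
#' transition matrix and the per-state on-target probability (5/36 from
#' odd-thousand states, 4/36 from even), then propagates the state
#' distribution from the initial production to obtain the exact expected
#' on-target count over a block.
#'
#' @param trials Trials per block.
#' @param cfg A [dsc_config()].
#' @return A `"chance_estimate"` with `method = "enumeration"`,
#'   `standard_error` 0 and `n_replicates` 0; the extra element
#'   `per_state_prob` gives the one-trial on-target probability from each
#'   production state.
#' @export
dsc_chance_exact <- function(trials = 19, cfg = dsc_config()) {
  grid <- worker_grid(cfg)
  states <- seq(cfg$production_min, cfg$production_max, by = 1000)
  ns <- length(states)
  combos <- expand.grid(W = grid, E = cfg$error_values)
  Tm <- matrix(0, ns, ns, dimnames = list(states, states))
  v <- numeric(ns)
  for (i in seq_len(ns)) {
    newP <- step_production(combos$W, states[i], combos$E, cfg)
    j <- match(newP, states)
    if (anyNA(j)) stop("production left the thousand-ton state grid")
    tab <- tabulate(j, ns)
    Tm[i, ] <- tab / nrow(combos)
    v[i] <- mean(abs(newP - cfg$target_production) <= cfg$on_target_halfwidth)
  }
  d <- numeric(ns)
  d[match(cfg$initial_production, states)] <- 1
  total <- 0
  for (t in seq_len(trials)) {
    total <- total + sum(d * v)
    d <- as.vector(d %*% Tm)
  }
  out <- .chance_estimate(total, 0, 0, "enumeration")
  out$per_state_prob <- stats::setNames(v, states)
  out$transition <- Tm
  out
}

#' Chance proportions of the four triplet categories
#'
#' Exhaustive enumeration of all `n_positions^3` ordered triples under
#' [classify_triplet()]. With four positions: 16/64 pattern-consistent,
#' 12/64 span, 4/64 repetition, 32/64 inconsistent. Percentages are rounded
#' to one decimal with round-half-to-even, mapping the exact 6.25 to 6.2.
#'
#' @param cfg An [asrt_config()].
#' @return Data frame with `category`, `count`, `proportion`, `percent`.
#' @export
triplet_chance_enumeration <- function(cfg = asrt_config()) {
  np <- cfg$n_positions
  g <- expand.grid(p1 = seq_len(np), p2 = seq_len(np), p3 = seq_len(np))
  cats <- classify_triplet(g$p1, g$p2, g$p3, cfg)
  counts <- table(factor(cats, levels = triplet_categories()))
  data.frame(
    category = triplet_categories(),
    count = as.integer(counts),
    proportion = as.numeric(counts) / nrow(g),
    percent = round(100 * as.numeric(counts) / nrow(g), 1)
  )
}

#' Expected circular change under independent responding
#'
#' Exact mean of the least-path circular distance over all ordered pairs of
#' worker-grid values: if the chosen input is independent of the randomized
#' start value, a mean change of 3 grid steps is expected (the distance
#' distribution on the 12-cycle puts mass 1/12 on 0 and on the antipodal 6,
#' and 2/12 on each of 1 to 5).
#'
#' @param cfg A [dsc_config()].
#' @return List with `mean`, `max`, and the `distribution` of distances
#'   (named numeric vector of probabilities).
#' @export
expected_circular_change <- function(cfg = dsc_config()) {
  grid <- worker_grid(cfg)
  pairs <- expand.grid(a = grid, b = grid)
  d <- circular_distance(pairs$a, pairs$b, cfg)
  list(mean = mean(d), max = max(d),
       distribution = table(d) / length(d))
}

#' Triplet composition of simulated ASRT stimulus streams
#'
#' Generates blocks with [make_asrt_block()], codes every overlapping window
#' of three stimulus positions (warm-up included), and averages the category
#' proportions. The pattern-consistent total decomposes into structurally
#' forced windows (start and end on pattern trials, consistent by
#' construction) and chance-consistent windows starting on a random trial
#' (consistent with probability about 1/4); with the default protocol the
#' total is about 61 percent.
#'
#' @param cfg An [asrt_config()].
#' @param n_blocks_simulated Number of simulated blocks.
#' @param seed Optional integer seed.
#' @return List with `proportions` (named, over the four categories),
#'   `percent` (rounded to one decimal), `forced_pattern_share` (share of
#'   all windows that start and end on pattern trials),
#'   `random_start_consistent_share` (consistent share among the remaining
#'   windows), `n_triplets`, `n_blocks_simulated`.
#' @export
asrt_stream_triplet_expectation <- function(cfg = asrt_config(),
                                            n_blocks_simulated = 1000,
                                            seed = NULL) {
  stopifnot(n_blocks_simulated >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::setNames(numeric(4), triplet_categories())
  n_windows <- 0
  forced <- 0
  other_windows <- 0
  other_consistent <- 0
  for (b in seq_len(n_blocks_simulated)) {
    blk <- make_asrt_block(cfg)
    n <- nrow(blk)
    cats <- classify_triplet(blk$target[1:(n - 2L)], blk$target[2:(n - 1L)],
                             blk$target[3:n], cfg)
    tt <- blk$trial_type
    is_forced <- tt[1:(n - 2L)] == "pattern" & tt[3:n] == "pattern"
    tab <- table(factor(cats, levels = triplet_categories()))
    counts <- counts + as.numeric(tab)
    n_windows <- n_windows + (n - 2L)
    forced <- forced + sum(is_forced)
    other_windows <- other_windows + sum(!is_forced)
    other_consistent <- other_consistent +
      sum(cats == "pattern_consistent" & !is_forced)
  }
  props <- counts / n_windows
  list(
    proportions = props,
    percent = round(100 * props, 1),
    forced_pattern_share = forced / n_windows,
    random_start_consistent_share = other_consistent / other_windows,
    n_triplets = n_windows,
    n_blocks_simulated = n_blocks_simulated
  )
}
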