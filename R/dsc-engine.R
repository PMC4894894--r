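#' Configuration of the sugar-factory control task
#'
#' Bundles every fixed parameter of the dynamic system control (DSC) task:
#' the hidden production law `P_t = gain * W_t - P_{t-1} + error` with
#' clamping at the production limits, the circular worker-input grid, the
#' on-target band around the production goal, and the block/trial protocol.
#'
#' @param target_production Production goal in tons.
#' @param on_target_halfwidth Half-width of the on-target band in tons; a
#'   trial counts as on target when `|production - target| <=` this value.
#' @param gain Tons of production per worker in the hidden law.
#' @param error_values Equiprobable random error added to the raw production
#'   on every trial; must be symmetric about zero.
#' @param production_min,production_max Clamping limits for production, tons.
#' @param worker_min,worker_max,worker_step The circular worker-input grid:
#'   `worker_min` to `worker_max` in steps of `worker_step`, wrapping at the
#'   ends.
#' @param initial_production Displayed previous production at the start of
#'   every block, tons.
#' @param initial_workforce Displayed previous workforce at the start of
#'   every block, workers (display metadata only).
#' @param trials_per_block Trials simulated per block.
#' @param recorded_trials_per_block Trials per block that enter scoring (the
#'   study protocol logged one fewer trial than was run; set equal to
#'   `trials_per_block` for the un-truncated protocol).
#' @param n_blocks Number of blocks per session.
#' @param confidence_levels Number of points on the ordinal confidence scale.
#'
#' @return An object of class `"dsc_config"`.
#' @examples
#' cfg <- dsc_config()
#' worker_grid(cfg)
#' @export
dsc_config <- function(target_production = 9000,
                       on_target_halfwidth = 1000,
                       gain = 20,
                       error_values = c(-1000, 0, 1000),
                       production_min = 1000,
                       production_max = 12000,
                       worker_min = 100,
                       worker_max = 1200,
                       worker_step = 100,
                       initial_production = 6000,
                       initial_workforce = 600,
                       trials_per_block = 20,
                       recorded_trials_per_block = 19,
                       n_blocks = 5,
                       confidence_levels = 6) {
  grid <- seq(worker_min, worker_max, by = worker_step)
  if (length(grid) != (worker_max - worker_min) / worker_step + 1) {
    stop("worker grid is not an integer number of steps")
  }
  if (!setequal(error_values, -error_values)) {
    stop("error_values must be symmetric about zero")
  }
  if (production_min >= target_production - on_target_halfwidth) {
    stop("production_min must lie below the on-target band")
  }
  if (production_max <= target_production + on_target_halfwidth) {
    stop("production_max must lie above the on-target band")
  }
  if (recorded_trials_per_block > trials_per_block) {
    stop("recorded_trials_per_block cannot exceed trials_per_block")
  }
  if (initial_production < production_min || initial_production > production_max) {
    stop("initial_production outside production limits")
  }
  structure(
    list(
      target_production = target_production,
      on_target_halfwidth = on_target_halfwidth,
      gain = gain,
      error_values = sort(error_values),
      production_min = production_min,
      production_max = production_max,
      worker_min = worker_min,
      worker_max = worker_max,
      worker_step = worker_step,
      initial_production = initial_production,
      initial_workforce = initial_workforce,
      trials_per_block = as.integer(trials_per_block),
      recorded_trials_per_block = as.integer(recorded_trials_per_block),
      n_blocks = as.integer(n_blocks),
      confidence_levels = as.integer(confidence_levels)
    ),
    class = "dsc_config"
  )
}

#' The circular worker-input grid
#'
#' @param cfg A [dsc_config()].
#' @return Numeric vector of the admissible worker inputs.
#' @export
worker_grid <- function(cfg = dsc_config()) {
  seq(cfg$worker_min, cfg$worker_max, by = cfg$worker_step)
}

.check_on_grid <- function(x, cfg, what) {
  if (!all(x %in% worker_grid(cfg))) {
    stop(sprintf("%s must lie on the worker grid (%d-%d step %d)",
                 what, cfg$worker_min, cfg$worker_max, cfg$worker_step))
  }
  invisible(x)
}

#' One step of the hidden production law
#'
#' Applies `P_t = gain * W_t - P_{t-1} + error`, then clamps the result to
#' the production limits. Deterministic given its inputs; the random error
#' is passed in explicitly.
#'
#' @param chosen_workforce Worker input, on the grid. Vectorised.
#' @param previous_production Previous production in tons, within limits.
#' @param error_drawn One of the configured error values.
#' @param cfg A [dsc_config()].
#' @return Clamped production in tons.
#' @examples
#' step_production(600, 6000, 0)    # the displayed initial state is a fixed point
#' step_production(1200, 1000, 1000) # clamped at the upper limit
#' @export
step_production <- function(chosen_workforce, previous_production, error_drawn,
                            cfg = dsc_config()) {
  .check_on_grid(chosen_workforce, cfg, "chosen_workforce")
  if (any(previous_production < cfg$production_min |
          previous_production > cfg$production_max)) {
    stop("previous_production outside production limits")
  }
  if (!all(error_drawn %in% cfg$error_values)) {
    stop("error_drawn must be one of the configured error values")
  }
  raw <- cfg$gain * chosen_workforce - previous_production + error_drawn
  pmin(pmax(raw, cfg$production_min), cfg$production_max)
}

#' Is a production value on target?
#'
#' @param production Production in tons, within the production limits.
#' @param cfg A [dsc_config()].
#' @return Logical; `TRUE` iff production lies inside the on-target band,
#'   inclusive at both endpoints.
#' @export
is_on_target <- function(production, cfg = dsc_config()) {
  if (any(production < cfg$production_min | production > cfg$production_max)) {
    stop("production outside production limits")
  }
  abs(production - cfg$target_production) <= cfg$on_target_halfwidth
}

#' Least-path distance on the circular worker scale
#'
#' The worker input wraps around at the ends of the grid, so the distance
#' between two inputs is the least of the clockwise and counter-clockwise
#' step counts: `min(|i - j|, n - |i - j|)` for grid indices `i`, `j` on an
#' `n`-cycle. With the default 12-value grid the range is 0-6.
#'
#' @param a,b Worker inputs on the grid. Vectorised.
#' @param cfg A [dsc_config()].
#' @return Integer distances in grid steps.
#' @examples
#' circular_distance(1200, 100) # wrapping: one step, not eleven
#' circular_distance(100, 700)  # antipodal: the maximum of 6
#' @export
circular_distance <- function(a, b, cfg = dsc_config()) {
  grid <- worker_grid(cfg)
  .check_on_grid(a, cfg, "a")
  .check_on_grid(b, cfg, "b")
  n <- length(grid)
  d <- abs(match(a, grid) - match(b, grid))
  pmin(d, n - d)
}

#' Run one block of the sugar-factory task
#'
#' Simulates `trials_per_block` trials. On every trial the starting value of
#' the worker counter is drawn uniformly from the grid, the policy is asked
#' for a worker input, a random error is drawn equiprobably, and production
#' evolves by [step_production()]. Draw order within a trial is fixed
#' (start value, policy, error) so that a seeded run is reproducible.
#'
#' @param policy A function `(state, start_workforce) -> workforce` where
#'   `state` is a list with `previous_production` and 0-based `trial_index`.
#'   Must return a value on the worker grid. See [dsc_policy_random()],
#'   [dsc_policy_anchored()], [dsc_policy_inversion()].
#' @param cfg A [dsc_config()].
#' @param block 1-based block index stamped into the records.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param previous_production Production state at block start; blocks reset
#'   to `cfg$initial_production` by default.
#' @return A data frame with one row per simulated trial: `block`, `trial`,
#'   `start_workforce`, `chosen_workforce`, `error`, `production`,
#'   `on_target`.
#' @export
run_dsc_block <- function(policy, cfg = dsc_config(), block = 1L, seed = NULL,
                          previous_production = cfg$initial_production) {
  if (!is.null(seed)) set.seed(seed)
  grid <- worker_grid(cfg)
  nt <- cfg$trials_per_block
  start_w <- integer(nt)
  chosen_w <- integer(nt)
  err <- numeric(nt)
  prod <- numeric(nt)
  prev <- previous_production
  for (t in seq_len(nt)) {
    start <- sample(grid, 1L)
    state <- list(previous_production = prev, trial_index = t - 1L)
    w <- policy(state, start)
    if (length(w) != 1L || !w %in% grid) {
      stop("policy returned a worker input off the grid")
    }
    e <- sample(cfg$error_values, 1L)
    p <- step_production(w, prev, e, cfg)
    start_w[t] <- start
    chosen_w[t] <- w
    err[t] <- e
    prod[t] <- p
    prev <- p
  }
  data.frame(
    block = as.integer(block),
    trial = seq_len(nt),
    start_workforce = start_w,
    chosen_workforce = chosen_w,
    error = err,
    production = prod,
    on_target = is_on_target(prod, cfg)
  )
}

#' Run a full sugar-factory session
#'
#' Runs `cfg$n_blocks` blocks, resetting the production state to the
#' displayed initial production at the start of every block.
#'
#' @param policy A policy as in [run_dsc_block()], or a list of one policy
#'   per block (e.g. for knowledge that grows with practice).
#' @param cfg A [dsc_config()].
#' @param seed Optional integer seed for the whole session.
#' @return A data frame of all trials across blocks.
#' @export
run_dsc_session <- function(policy, cfg = dsc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pol <- if (is.function(policy)) rep(list(policy), cfg$n_blocks) else policy
  if (length(pol) != cfg$n_blocks) {
    stop("need one policy, or one per block")
  }
  do.call(rbind, lapply(seq_len(cfg$n_blocks), function(b) {
    run_dsc_block(pol[[b]], cfg, block = b)
  }))
}

#' Worker-input policies for simulated sugar-factory agents
#'
#' Constructors for the three agent policies used by the synthetic cohort:
#'
#' * `dsc_policy_random()` chooses uniformly on the grid, ignoring the
#'   randomized start value (the chance-level responder).
#' * `dsc_policy_anchored()` stays near the randomized start value: it moves
#'   by a Poisson-distributed number of circular steps (mean
#'   `anchor_strength`, capped at the antipode) in a random direction.
#'   With `anchor_strength < 2` such an agent is the response-bias case the
#'   data-reduction screen is designed to remove.
#' * `dsc_policy_inversion()` applies the inversion of the production law
#'   with probability `knowledge`: it picks the grid value nearest
#'   `(target + previous_production) / gain`, and otherwise responds
#'   uniformly at random.
#'
#' @param anchor_strength Mean circular adjustment in grid steps, `>= 0`.
#' @param knowledge Probability in `[0, 1]` of applying the inversion rule.
#' @param cfg A [dsc_config()].
#' @return A policy function for [run_dsc_block()].
#' @name dsc_policies
NULL

#' @rdname dsc_policies
#' @export
dsc_policy_random <- function(cfg = dsc_config()) {
  grid <- worker_grid(cfg)
  function(state, start_workforce) sample(grid, 1L)
}

#' @rdname dsc_policies
#' @export
dsc_policy_anchored <- function(anchor_strength, cfg = dsc_config()) {
  stopifnot(anchor_strength >= 0)
  grid <- worker_grid(cfg)
  n <- length(grid)
  function(state, start_workforce) {
    step <- min(stats::rpois(1L, anchor_strength), n %/% 2L)
    dir <- sample(c(-1L, 1L), 1L)
    i <- (match(start_workforce, grid) - 1L + dir * step) %% n + 1L
    grid[i]
  }
}

#' @rdname dsc_policies
#' @export
dsc_policy_inversion <- function(knowledge = 1, cfg = dsc_config()) {
  stopifnot(knowledge >= 0, knowledge <= 1)
  grid <- worker_grid(cfg)
  function(state, start_workforce) {
    if (stats::runif(1L) < knowledge) {
      w_star <- (cfg$target_production + state$previous_production) / cfg$gain
      grid[which.min(abs(grid - w_star))]
    } else {
      sample(grid, 1L)
    }
  }
}
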