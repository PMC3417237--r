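#' Two-step task configuration
#'
#' Defines the generative environment of the two-stage Markov decision task:
#' a first-stage choice between two actions leads probabilistically (the
#' "common" transition, 70% by default) to one of two second-stage states,
#' each offering a choice between two stimuli rewarded with probabilities
#' that drift as bounded Gaussian random walks.
#'
#' @param n_trials number of trials per session (default 201).
#' @param common_prob probability that a first-stage action leads to its
#'   associated second-stage state; must lie in (0.5, 1].
#' @param walk_sd standard deviation of the per-trial Gaussian increment of
#'   each reward probability (probability scale).
#' @param walk_bounds closed interval `c(lo, hi)` within `[0, 1]` to which the
#'   reward-probability walks are confined by reflection.
#' @param init_reward_probs optional vector of 4 initial reward probabilities
#'   (second-stage stimuli in order state0/action0, state0/action1,
#'   state1/action0, state1/action1). If `NULL`, drawn uniformly within
#'   `walk_bounds` at walk generation.
#' @param mapping integer vector of length 2: `mapping[a + 1]` is the
#'   second-stage state commonly reached by first-stage action `a`. Must be a
#'   permutation of `c(0L, 1L)`.
#' @param break_trials trial indices after which a session break occurred;
#'   recorded for provenance only, with no effect on any computation.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials = 201L, common_prob = 0.7, walk_sd = 0.025,
                        walk_bounds = c(0.2, 0.8), init_reward_probs = NULL,
                        mapping = c(0L, 1L), break_trials = c(67L, 134L)) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L)
    stop("`n_trials` must be a positive integer", call. = FALSE)
  if (!is.numeric(common_prob) || common_prob < 0.5 || common_prob > 1)
    stop("`common_prob` must lie in [0.5, 1]", call. = FALSE)
  if (!is.numeric(walk_sd) || walk_sd < 0)
    stop("`walk_sd` must be nonnegative", call. = FALSE)
  if (length(walk_bounds) != 2L || walk_bounds[1] >= walk_bounds[2] ||
      walk_bounds[1] < 0 || walk_bounds[2] > 1)
    stop("`walk_bounds` must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  if (!is.null(init_reward_probs)) {
    if (length(init_reward_probs) != 4L ||
        any(init_reward_probs < walk_bounds[1]) ||
        any(init_reward_probs > walk_bounds[2]))
      stop("`init_reward_probs` must be 4 values within `walk_bounds`",
           call. = FALSE)
  }
  mapping <- as.integer(mapping)
  if (length(mapping) != 2L || !setequal(mapping, c(0L, 1L)))
    stop("`mapping` must be a permutation of c(0L, 1L)", call. = FALSE)
  structure(
    list(n_trials = n_trials, common_prob = common_prob, walk_sd = walk_sd,
         walk_bounds = walk_bounds, init_reward_probs = init_reward_probs,
         mapping = mapping, break_trials = as.integer(break_trials)),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-step task configuration\n")
  cat(sprintf("  trials: %d (breaks after %s)\n", x$n_trials,
              paste(x$break_trials, collapse = ", ")))
  cat(sprintf("  common transition probability: %.2f\n", x$common_prob))
  cat(sprintf("  reward walks: sd %.3f, bounds [%.2f, %.2f]\n",
              x$walk_sd, x$walk_bounds[1], x$walk_bounds[2]))
  invisible(x)
}

#' Generate drifting reward probabilities
#'
#' Simulates the four independent bounded Gaussian random walks that govern
#' the reward probability of each second-stage stimulus. Each walk starts at
#' its initial probability and receives an independent Gaussian increment of
#' standard deviation `walk_sd` per trial; excursions beyond the bounds are
#' reflected back into the interval.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the same seed always yields the same matrix.
#' @return A numeric matrix with `n_trials` rows and 4 columns (one walk per
#'   second-stage stimulus), all entries within `walk_bounds`.
#' @export
generate_reward_walks <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  with_seed(seed, {
    lo <- config$walk_bounds[1]; hi <- config$walk_bounds[2]
    init <- config$init_reward_probs
    if (is.null(init)) init <- stats::runif(4L, lo, hi)
    m <- matrix(NA_real_, nrow = config$n_trials, ncol = 4L)
    m[1L, ] <- init
    if (config$n_trials > 1L) {
      steps <- matrix(stats::rnorm((config$n_trials - 1L) * 4L,
                                   sd = config$walk_sd),
                      ncol = 4L)
      for (t in 2:config$n_trials) {
        m[t, ] <- reflect_into(m[t - 1L, ] + steps[t - 1L, ], lo, hi)
      }
    }
    m
  })
}

# reflect values into [lo, hi]; repeats until inside (one pass suffices for
# steps smaller than the interval width)
reflect_into <- function(x, lo, hi) {
  repeat {
    out_hi <- x > hi
    out_lo <- x < lo
    if (!any(out_hi) && !any(out_lo)) return(x)
    x[out_hi] <- 2 * hi - x[out_hi]
    x[out_lo] <- 2 * lo - x[out_lo]
  }
}

#' Sample second-stage states for first-stage choices
#'
#' Draws the transition outcome of one or more first-stage choices: with
#' probability `common_prob` the action's mapped second-stage state is
#' reached (a "common" transition), otherwise the other state ("rare").
#' Uses the current RNG stream.
#'
#' @param choice1 integer vector of first-stage actions in `{0, 1}`
#'   (recycled against `n`).
#' @param config a [task_config()].
#' @param n number of draws; defaults to `length(choice1)`.
#' @return A list with integer vector `state2` and character vector
#'   `transition` (`"common"` or `"rare"`).
#' @export
sample_transition <- function(choice1, config = task_config(),
                              n = length(choice1)) {
  if (!all(choice1 %in% c(0L, 1L)))
    stop("`choice1` must contain only 0 and 1", call. = FALSE)
  choice1 <- rep_len(as.integer(choice1), n)
  common <- stats::runif(n) < config$common_prob
  mapped <- config$mapping[choice1 + 1L]
  state2 <- ifelse(common, mapped, 1L - mapped)
  list(state2 = as.integer(state2),
       transition = ifelse(common, "common", "rare"))
}

#' Simulate one session of the two-step task
#'
#' Runs an agent through a full session: on each trial the agent's current
#' values determine first- and second-stage choice probabilities, the
#' environment draws the transition and the reward (from the drifting walk
#' probability of the visited stimulus), and the agent's values are updated.
#'
#' @param params an [agent_params()] object (or named list/vector of natural
#'   parameters) for `variant`.
#' @param config a [task_config()].
#' @param seed integer seed; the session is fully reproducible from it.
#' @param variant model variant name; defaults to the variant recorded in
#'   `params` or `"hybrid"`.
#' @param subject,condition labels stored in the session records.
#' @return A `data.frame` of class `twostep_session` with one row per trial
#'   and columns `subject`, `condition`, `trial`, `choice1`, `transition`,
#'   `state2`, `choice2`, `reward`. The reward-walk matrix, config and seed
#'   are attached as attributes.
#' @export
run_session <- function(params, config = task_config(), seed = 1L,
                        variant = NULL, subject = "s01",
                        condition = "placebo") {
  variant <- resolve_variant(params, variant)
  params <- agent_params(params, variant = variant)
  walks <- generate_reward_walks(config, seed = seed)
  nt <- config$n_trials
  choice1 <- state2 <- choice2 <- reward <- integer(nt)
  transition <- character(nt)
  with_seed(seed + 1L, {
    state <- agent_init(variant)
    for (t in seq_len(nt)) {
      p1 <- stage1_probs(state, params, variant, config)
      c1 <- as.integer(stats::runif(1) < p1[2])
      tr <- sample_transition(c1, config, n = 1L)
      s2 <- tr$state2
      p2 <- stage2_probs(state, s2, params, variant)
      c2 <- as.integer(stats::runif(1) < p2[2])
      r <- as.integer(stats::runif(1) < walks[t, s2 * 2L + c2 + 1L])
      choice1[t] <- c1; state2[t] <- s2; choice2[t] <- c2; reward[t] <- r
      transition[t] <- tr$transition
      state <- agent_update(state, list(choice1 = c1, state2 = s2,
                                        choice2 = c2, reward = r),
                            params, variant)
    }
  })
  out <- data.frame(subject = subject, condition = condition,
                    trial = seq_len(nt), choice1 = choice1,
                    transition = transition, state2 = state2,
                    choice2 = choice2, reward = reward,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "reward_walks") <- walks
  class(out) <- c("twostep_session", "data.frame")
  out
}

# validate that a data.frame looks like a single session; returns it with
# integer columns coerced
as_session_df <- function(session) {
  need <- c("trial", "choice1", "transition", "state2", "choice2", "reward")
  miss <- setdiff(need, names(session))
  if (length(miss))
    stop("session is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(session)
  if (n < 1L) stop("session has no trials", call. = FALSE)
  if (!identical(as.integer(session$trial), seq_len(n)))
    stop("trial indices must be 1..n with no gaps", call. = FALSE)
  for (col in c("choice1", "state2", "choice2", "reward")) {
    v <- as.integer(session[[col]])
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
      stop("column `", col, "` must contain only 0 and 1", call. = FALSE)
    session[[col]] <- v
  }
  if (!all(session$transition %in% c("common", "rare")))
    stop("`transition` must be \"common\" or \"rare\"", call. = FALSE)
  session
}
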