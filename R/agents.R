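#' Model variants
#'
#' The package implements a family of hybrid reinforcement-learning models
#' for the two-step task. All variants compute first-stage net values as an
#' `omega`-weighted mixture of a model-based term (forward evaluation over
#' the known transition structure) and a model-free term, and choose through
#' a softmax with an additive perseveration bonus for repeating the previous
#' first-stage choice.
#'
#' * `"hybrid"` — the winning model: one learning rate `alpha`, softmax
#'   inverse temperature `beta`, perseveration `pi`, model-based weight
#'   `omega`; second-stage values are shared between the two systems and the
#'   second-stage prediction error also updates the first-stage model-free
#'   value (eligibility constant `lambda_trace`, fixed at 1 by default).
#' * `"dual_rate"` — separate learning rates for positive (`alpha_pos`) and
#'   negative (`alpha_neg`) prediction errors.
#' * `"separate_values"` — separate second-stage value tables and learning
#'   rates for the model-free (`alpha_mf`) and model-based (`alpha_mb`)
#'   systems.
#' * `"actor_critic"` — the model-free component is an actor-critic: a
#'   critic learns state values with rate `alpha` and an actor accumulates
#'   action preferences with step size `eta`; the preferences replace the
#'   model-free values in the mixture.
#'
#' @return `model_variants()` returns the variant names.
#' @export
model_variants <- function() c("hybrid", "dual_rate", "separate_values",
                               "actor_critic")

# parameter registry: natural name -> transformed name and transform type
.variant_registry <- list(
  hybrid = list(
    params = c("alpha", "beta", "pi", "omega"),
    tnames = c(alpha = "a", beta = "b", pi = "p", omega = "w")),
  dual_rate = list(
    params = c("alpha_pos", "alpha_neg", "beta", "pi", "omega"),
    tnames = c(alpha_pos = "a_pos", alpha_neg = "a_neg", beta = "b",
               pi = "p", omega = "w")),
  separate_values = list(
    params = c("alpha_mf", "alpha_mb", "beta", "pi", "omega"),
    tnames = c(alpha_mf = "a_mf", alpha_mb = "a_mb", beta = "b",
               pi = "p", omega = "w")),
  actor_critic = list(
    params = c("alpha", "eta", "beta", "pi", "omega"),
    tnames = c(alpha = "a", eta = "e", beta = "b", pi = "p", omega = "w")))

# unit-interval parameters use the logistic transform; positive ones log
.logistic_params <- c("alpha", "alpha_pos", "alpha_neg", "alpha_mf",
                      "alpha_mb", "omega", "eta")
.log_params <- c("beta", "pi")

variant_info <- function(variant) {
  info <- .variant_registry[[variant]]
  if (is.null(info))
    stop("unknown model variant \"", variant, "\"; must be one of ",
         paste(model_variants(), collapse = ", "), call. = FALSE)
  info
}

resolve_variant <- function(params, variant) {
  if (!is.null(variant)) return(match.arg(variant, model_variants()))
  v <- attr(params, "variant")
  if (!is.null(v)) v else "hybrid"
}

#' Natural-space agent parameters
#'
#' Builds and validates the parameter set of a model variant. Learning
#' rates, `omega` and `eta` must lie in `[0, 1]`; `beta` and `pi` must be
#' nonnegative. `lambda_trace` (degree to which the second-stage prediction
#' error also updates the first-stage model-free value) is a fixed constant,
#' 1 by default, and is not estimated.
#'
#' @param x a named numeric vector or list of parameters, or `NULL` to build
#'   from the `...` arguments.
#' @param variant model variant name, see [model_variants()].
#' @param lambda_trace eligibility constant in `[0, 1]`.
#' @param ... individual parameters given by name (e.g. `alpha = 0.45`).
#' @return A named numeric vector of class `agent_params` with attributes
#'   `variant` and `lambda_trace`.
#' @export
#' @examples
#' agent_params(alpha = 0.45, beta = 5.4, pi = 1.37, omega = 0.58)
agent_params <- function(x = NULL, variant = "hybrid", lambda_trace = NULL,
                         ...) {
  variant <- match.arg(variant, model_variants())
  if (inherits(x, "agent_params") && identical(attr(x, "variant"), variant) &&
      is.null(lambda_trace) && !length(list(...)))
    return(x)
  if (is.null(lambda_trace))
    lambda_trace <- attr(x, "lambda_trace") %||% 1
  vals <- c(as.list(x), list(...))
  info <- variant_info(variant)
  miss <- setdiff(info$params, names(vals))
  if (length(miss))
    stop("missing parameter(s) for variant \"", variant, "\": ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- vapply(info$params, function(p) as.numeric(vals[[p]]), numeric(1))
  for (p in intersect(names(out), .logistic_params))
    if (out[p] < 0 || out[p] > 1)
      stop("`", p, "` must lie in [0, 1]", call. = FALSE)
  for (p in intersect(names(out), .log_params))
    if (out[p] < 0)
      stop("`", p, "` must be nonnegative", call. = FALSE)
  if (lambda_trace < 0 || lambda_trace > 1)
    stop("`lambda_trace` must lie in [0, 1]", call. = FALSE)
  structure(out, variant = variant, lambda_trace = lambda_trace,
            class = "agent_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("Agent parameters (%s variant, lambda = %g)\n",
              attr(x, "variant"), attr(x, "lambda_trace")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# fresh agent state: all value tables at zero, no previous choice
agent_init <- function(variant) {
  list(q1_mf = c(0, 0),
       q2 = matrix(0, 2, 2),          # rows: second-stage state; cols: action
       q2_mb = matrix(0, 2, 2),       # separate_values variant only
       v = c(0, 0, 0),                # critic: start state, state 0, state 1
       prefs1 = c(0, 0),              # actor first-stage preferences
       prefs2 = matrix(0, 2, 2),      # actor second-stage preferences
       prev_choice1 = NA_integer_)
}

#' Model-based first-stage values
#'
#' Forward evaluation over the known transition structure: the model-based
#' value of a first-stage action is the transition-probability-weighted
#' expectation of the best available second-stage value,
#' `Q_MB(a) = P(common) * max_a' Q2(mapped state, a') +
#' (1 - P(common)) * max_a' Q2(other state, a')`.
#'
#' @param q2 2x2 matrix of second-stage values (rows = states, cols = actions).
#' @param common_prob common-transition probability.
#' @param mapping action-to-state mapping as in [task_config()].
#' @return Numeric vector of 2 first-stage values.
#' @export
mb_first_stage_values <- function(q2, common_prob = 0.7,
                                  mapping = c(0L, 1L)) {
  best <- c(max(q2[1, ]), max(q2[2, ]))
  mapped <- mapping + 1L                       # state reached by action 0, 1
  common_prob * best[mapped] + (1 - common_prob) * best[3L - mapped]
}

#' Mix model-based and model-free values
#'
#' @param q_mb,q_mf numeric vectors of 2 first-stage values.
#' @param omega model-based weight in `[0, 1]`.
#' @return `omega * q_mb + (1 - omega) * q_mf`.
#' @export
combine_values <- function(q_mb, q_mf, omega) {
  if (omega < 0 || omega > 1) stop("`omega` must lie in [0, 1]", call. = FALSE)
  omega * q_mb + (1 - omega) * q_mf
}

#' First-stage choice probabilities
#'
#' Softmax over the net first-stage values with an additive perseveration
#' bonus: `P(a)` is proportional to
#' `exp(beta * net[a] + pi * [a == prev_choice1])`. Before the first trial
#' (`prev_choice1 = NA`) the perseveration term is zero for both actions.
#'
#' @param net numeric vector of 2 net values.
#' @param beta softmax inverse temperature, `>= 0`.
#' @param pi perseveration strength, `>= 0`.
#' @param prev_choice1 previous first-stage action (0, 1 or `NA`).
#' @return Probabilities of actions 0 and 1 (sum to 1).
#' @export
choice_probs_stage1 <- function(net, beta, pi = 0, prev_choice1 = NA) {
  if (any(!is.finite(net))) stop("non-finite net values", call. = FALSE)
  if (beta < 0 || pi < 0) stop("`beta` and `pi` must be >= 0", call. = FALSE)
  stick <- if (is.na(prev_choice1)) c(0, 0) else
    as.numeric(c(0L, 1L) == prev_choice1)
  softmax2(beta * net + pi * stick)
}

#' Second-stage choice probabilities
#'
#' Plain softmax over the visited state's second-stage values with the same
#' inverse temperature as the first stage; no perseveration at stage two.
#'
#' @param q2_row numeric vector of 2 values for the visited state.
#' @param beta softmax inverse temperature, `>= 0`.
#' @return Probabilities of actions 0 and 1.
#' @export
choice_probs_stage2 <- function(q2_row, beta) {
  if (any(!is.finite(q2_row))) stop("non-finite values", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  softmax2(beta * q2_row)
}

softmax2 <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

#' Model-free value update (hybrid model)
#'
#' SARSA-style two-stage delta rule. With the trial outcome
#' `(choice1, state2, choice2, reward)`: the first-stage prediction error
#' `d1 = Q2[state2, choice2] - Q1[choice1]` updates `Q1[choice1]` with rate
#' `alpha`; the second-stage prediction error `d2 = reward - Q2[state2,
#' choice2]` updates `Q2[state2, choice2]` with rate `alpha` and additionally
#' updates `Q1[choice1]` scaled by the eligibility constant `lambda_trace`.
#' Unchosen entries are untouched; `prev_choice1` is set to `choice1`.
#'
#' @param state agent state list as produced by the simulator/likelihood.
#' @param trial list with elements `choice1`, `state2`, `choice2`, `reward`.
#' @param alpha learning rate in `[0, 1]`.
#' @param lambda_trace eligibility constant in `[0, 1]`.
#' @return The updated state.
#' @export
mf_update <- function(state, trial, alpha, lambda_trace = 1) {
  i1 <- trial$choice1 + 1L; is <- trial$state2 + 1L; i2 <- trial$choice2 + 1L
  d1 <- state$q2[is, i2] - state$q1_mf[i1]
  state$q1_mf[i1] <- state$q1_mf[i1] + alpha * d1
  d2 <- trial$reward - state$q2[is, i2]
  state$q2[is, i2] <- state$q2[is, i2] + alpha * d2
  state$q1_mf[i1] <- state$q1_mf[i1] + lambda_trace * alpha * d2
  state$prev_choice1 <- trial$choice1
  state
}

#' Model-free update with separate positive/negative learning rates
#'
#' Identical to [mf_update()] except that each prediction error is applied
#' with `alpha_pos` when positive and `alpha_neg` when negative (a zero
#' error changes nothing under either rate).
#'
#' @inheritParams mf_update
#' @param alpha_pos,alpha_neg learning rates in `[0, 1]` for positive and
#'   negative prediction errors.
#' @return The updated state.
#' @export
dual_rate_update <- function(state, trial, alpha_pos, alpha_neg,
                             lambda_trace = 1) {
  i1 <- trial$choice1 + 1L; is <- trial$state2 + 1L; i2 <- trial$choice2 + 1L
  rate <- function(d) if (d > 0) alpha_pos else alpha_neg
  d1 <- state$q2[is, i2] - state$q1_mf[i1]
  state$q1_mf[i1] <- state$q1_mf[i1] + rate(d1) * d1
  d2 <- trial$reward - state$q2[is, i2]
  state$q2[is, i2] <- state$q2[is, i2] + rate(d2) * d2
  state$q1_mf[i1] <- state$q1_mf[i1] + lambda_trace * rate(d2) * d2
  state$prev_choice1 <- trial$choice1
  state
}

#' Update with separate model-based and model-free second-stage values
#'
#' The model-free table `q2` and first-stage values are updated as in
#' [mf_update()] with rate `alpha_mf`; a separate model-based table `q2_mb`
#' is updated by the same delta rule with rate `alpha_mb`. The model-based
#' first-stage values read `q2_mb`; second-stage choice uses the model-free
#' `q2` row.
#'
#' @inheritParams mf_update
#' @param alpha_mf,alpha_mb learning rates in `[0, 1]`.
#' @return The updated state.
#' @export
separate_values_update <- function(state, trial, alpha_mf, alpha_mb,
                                   lambda_trace = 1) {
  is <- trial$state2 + 1L; i2 <- trial$choice2 + 1L
  state <- mf_update(state, trial, alpha_mf, lambda_trace)
  d_mb <- trial$reward - state$q2_mb[is, i2]
  state$q2_mb[is, i2] <- state$q2_mb[is, i2] + alpha_mb * d_mb
  state
}

#' Actor-critic update
#'
#' The critic learns state values `v` (start state plus the two second-stage
#' states) from temporal-difference errors: after stage one,
#' `d1 = v[state2] - v[start]` updates `v[start]` with rate `alpha`; after
#' the outcome, `d2 = reward - v[state2]` updates `v[state2]`. The actor
#' increments the preference of the action taken at each stage's state by
#' `eta` times that stage's error. A second-stage action-value table (rate
#' `alpha`) is maintained for the model-based component of the hybrid
#' mixture.
#'
#' @inheritParams mf_update
#' @param alpha critic learning rate in `[0, 1]`.
#' @param eta actor (policy) step size in `[0, 1]`.
#' @return The updated state.
#' @export
actor_critic_update <- function(state, trial, alpha, eta) {
  i1 <- trial$choice1 + 1L; is <- trial$state2 + 1L; i2 <- trial$choice2 + 1L
  d1 <- state$v[is + 1L] - state$v[1L]
  state$v[1L] <- state$v[1L] + alpha * d1
  state$prefs1[i1] <- state$prefs1[i1] + eta * d1
  d2 <- trial$reward - state$v[is + 1L]
  state$v[is + 1L] <- state$v[is + 1L] + alpha * d2
  state$prefs2[is, i2] <- state$prefs2[is, i2] + eta * d2
  dq <- trial$reward - state$q2[is, i2]
  state$q2[is, i2] <- state$q2[is, i2] + alpha * dq
  state$prev_choice1 <- trial$choice1
  state
}

# --- dispatch helpers shared by the simulator and the R likelihood path ----

stage1_probs <- function(state, params, variant, config) {
  q2_src <- if (variant == "separate_values") state$q2_mb else state$q2
  mf_src <- if (variant == "actor_critic") state$prefs1 else state$q1_mf
  q_mb <- mb_first_stage_values(q2_src, config$common_prob, config$mapping)
  net <- combine_values(q_mb, mf_src, params[["omega"]])
  choice_probs_stage1(net, params[["beta"]], params[["pi"]],
                      state$prev_choice1)
}

stage2_probs <- function(state, state2, params, variant) {
  row <- if (variant == "actor_critic") state$prefs2[state2 + 1L, ]
         else state$q2[state2 + 1L, ]
  choice_probs_stage2(row, params[["beta"]])
}

agent_update <- function(state, trial, params, variant) {
  lam <- attr(params, "lambda_trace") %||% 1
  switch(variant,
    hybrid = mf_update(state, trial, params[["alpha"]], lam),
    dual_rate = dual_rate_update(state, trial, params[["alpha_pos"]],
                                 params[["alpha_neg"]], lam),
    separate_values = separate_values_update(state, trial,
                                             params[["alpha_mf"]],
                                             params[["alpha_mb"]], lam),
    actor_critic = actor_critic_update(state, trial, params[["alpha"]],
                                       params[["eta"]]))
}
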