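#' Parameter transforms between natural and Gaussian space
#'
#' Bounded parameters are mapped to unbounded, approximately Gaussian
#' coordinates for fitting and parametric testing: unit-interval parameters
#' (`alpha`-type rates, `omega`, `eta`) through the logit, positive
#' parameters (`beta`, `pi`) through the log. Transformed coordinates carry
#' the conventional short names (`a`, `b`, `p`, `w`, ...).
#'
#' Natural unit-interval values are clamped to `[1e-6, 1 - 1e-6]` (and
#' positive values to at least `1e-12`) before transforming, so boundary
#' values never produce infinite coordinates.
#'
#' @param natural an [agent_params()] object or named numeric vector of
#'   natural parameters.
#' @param variant model variant name.
#' @return `transform_params()`: a named numeric vector in transformed
#'   space; `untransform_params()`: the corresponding [agent_params()].
#' @export
#' @examples
#' th <- transform_params(agent_params(alpha = 0.45, beta = 5.4,
#'                                     pi = 1.37, omega = 0.58))
#' untransform_params(th)
transform_params <- function(natural, variant = NULL) {
  variant <- resolve_variant(natural, variant)
  info <- variant_info(variant)
  nat <- vapply(info$params, function(p) as.numeric(natural[[p]]), numeric(1))
  out <- numeric(length(nat))
  for (i in seq_along(nat)) {
    p <- info$params[i]
    if (p %in% .logistic_params) {
      x <- min(max(nat[i], 1e-6), 1 - 1e-6)
      out[i] <- stats::qlogis(x)
    } else {
      out[i] <- log(max(nat[i], 1e-12))
    }
  }
  stats::setNames(out, unname(info$tnames[info$params]))
}

#' @rdname transform_params
#' @param transformed named numeric vector in transformed space (names as
#'   produced by `transform_params()`).
#' @param lambda_trace eligibility constant passed through to the result.
#' @export
untransform_params <- function(transformed, variant = "hybrid",
                               lambda_trace = 1) {
  info <- variant_info(variant)
  nat <- numeric(length(info$params))
  for (i in seq_along(info$params)) {
    p <- info$params[i]
    x <- as.numeric(transformed[[info$tnames[[p]]]])
    nat[i] <- if (p %in% .logistic_params) stats::plogis(x) else exp(x)
  }
  agent_params(stats::setNames(as.list(nat), info$params), variant = variant,
               lambda_trace = lambda_trace)
}

#' Negative log-likelihood of a session
#'
#' Sequentially evaluates the probability of every first- and second-stage
#' choice in a session under a model variant, updating the agent's values
#' after each trial, and returns the summed negative log probability. A
#' zero-probability choice yields `+Inf` rather than an error.
#'
#' The default engine is a compiled kernel; `engine = "R"` evaluates the
#' likelihood by composing the exported per-operation functions
#' ([mf_update()], [choice_probs_stage1()], ...) and is used as an internal
#' cross-check.
#'
#' @param params an [agent_params()] object (or coercible named vector).
#' @param session a session `data.frame` as produced by [run_session()].
#' @param variant model variant name.
#' @param config the [task_config()] (for `common_prob` and the mapping).
#' @param engine `"cpp"` (default) or `"R"`.
#' @return Nonnegative scalar negative log-likelihood.
#' @export
session_nll <- function(params, session, variant = NULL,
                        config = task_config(), engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  variant <- resolve_variant(params, variant)
  params <- agent_params(params, variant = variant)
  session <- as_session_df(session)
  if (engine == "cpp") {
    code <- match(variant, model_variants()) - 1L
    twostep_nll_cpp(as.numeric(params), session$choice1, session$state2,
                    session$choice2, session$reward, code,
                    config$common_prob, attr(params, "lambda_trace"),
                    config$mapping[1])
  } else {
    pr <- session_choice_probs(params, session, variant, config)
    nll <- -sum(log(pr$p1)) - sum(log(pr$p2))
    if (!is.finite(nll)) Inf else nll
  }
}

#' Per-trial choice probabilities under a model
#'
#' Replays a session through a model variant and returns the probability the
#' model assigned to each observed first- and second-stage choice.
#'
#' @inheritParams session_nll
#' @return A `data.frame` with columns `trial`, `p1` (probability of the
#'   observed first-stage choice) and `p2` (second stage).
#' @export
session_choice_probs <- function(params, session, variant = NULL,
                                 config = task_config()) {
  variant <- resolve_variant(params, variant)
  params <- agent_params(params, variant = variant)
  session <- as_session_df(session)
  n <- nrow(session)
  p1 <- p2 <- numeric(n)
  state <- agent_init(variant)
  for (t in seq_len(n)) {
    trial <- list(choice1 = session$choice1[t], state2 = session$state2[t],
                  choice2 = session$choice2[t], reward = session$reward[t])
    pr1 <- stage1_probs(state, params, variant, config)
    pr2 <- stage2_probs(state, trial$state2, params, variant)
    p1[t] <- pr1[trial$choice1 + 1L]
    p2[t] <- pr2[trial$choice2 + 1L]
    state <- agent_update(state, trial, params, variant)
  }
  data.frame(trial = session$trial, p1 = p1, p2 = p2)
}
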