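#' Fit a two-step reinforcement-learning model to choice data
#'
#' The main modelling entry point. Fits one of the hybrid
#' model-based/model-free variants to every subject x condition session in
#' `data`, either by plain per-session maximum likelihood
#' (`method = "mle"`) or by the two-stage hierarchical (empirical-Bayes)
#' procedure (`method = "map"`, the default): stage 1 obtains per-session
#' maximum-likelihood estimates, their pooled Gaussian moments in
#' transformed space form a population prior, and stage 2 re-estimates each
#' session by maximum a posteriori under that prior.
#'
#' @param data a `twostep_cohort`, a list of session `data.frame`s, or one
#'   long trial `data.frame` with columns `subject`, `condition`, `trial`,
#'   `choice1`, `transition`, `state2`, `choice2`, `reward`.
#' @param model model variant name, see [model_variants()].
#' @param method `"map"` (hierarchical) or `"mle"`.
#' @param config a [task_config()]; defaults to the cohort's own task when
#'   `data` is a `twostep_cohort`.
#' @param controls a [fit_controls()] list.
#' @param fixed optional named natural-space parameter values held fixed
#'   (nested reductions).
#' @param seed master seed for the optimiser restarts.
#' @param lambda_trace eligibility constant.
#' @return An object of class `twostep_fit`; see
#'   [summary.twostep_fit()], [coef.twostep_fit()],
#'   [predict.twostep_fit()], [simulate.twostep_fit()],
#'   [plot.twostep_fit()].
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_subjects = 4, seed = 7))
#' fit <- fit_twostep(cohort, controls = fit_controls(n_restarts = 3))
#' summary(fit)
#' }
fit_twostep <- function(data, model = "hybrid", method = c("map", "mle"),
                        config = NULL, controls = fit_controls(),
                        fixed = NULL, seed = 1L, lambda_trace = 1) {
  method <- match.arg(method)
  model <- match.arg(model, model_variants())
  if (inherits(data, "twostep_cohort")) {
    if (is.null(config) && !is.null(data$config)) config <- data$config$task
    data <- data$trials
  }
  if (is.null(config)) config <- task_config()
  sessions <- split_sessions(data)
  if (method == "mle") controls$max_iters <- 1L
  pop <- fit_population(sessions, variant = model, config = config,
                        controls = controls, seed = seed, fixed = fixed,
                        lambda_trace = lambda_trace)
  estimates <- if (method == "map") pop$map else pop$mle
  structure(list(estimates = estimates, mle_estimates = pop$mle,
                 prior = pop$prior, model = model, method = method,
                 config = config, controls = controls, fixed = fixed,
                 lambda_trace = lambda_trace, seed = seed,
                 sessions = sessions, call = match.call()),
            class = "twostep_fit")
}

transformed_names <- function(model) {
  info <- variant_info(model)
  unname(info$tnames[info$params])
}

#' @export
print.twostep_fit <- function(x, ...) {
  est <- x$estimates
  cat(sprintf("Two-step RL fit: %s model, %s estimation\n", x$model,
              if (x$method == "map") "hierarchical (MLE -> MAP)"
              else "maximum-likelihood"))
  cat(sprintf("  %d sessions (%d subjects x %d condition(s)), %d trials each\n",
              nrow(est), length(unique(est$subject)),
              length(unique(est$condition)),
              nrow(x$sessions[[1]])))
  if (!is.null(x$fixed))
    cat("  fixed:", paste(names(x$fixed), x$fixed, sep = " = ",
                          collapse = ", "), "\n")
  cat(sprintf("  total negative log-likelihood: %.2f\n", sum(est$nll)))
  cat("  median natural parameters:\n")
  nat <- variant_info(x$model)$params
  med <- vapply(nat, function(p) stats::median(est[[p]]), numeric(1))
  print(round(med, 3))
  invisible(x)
}

#' Parameter estimates of a two-step fit
#'
#' @param object a `twostep_fit`.
#' @param space `"natural"` (model scale) or `"transformed"` (Gaussian
#'   fitting scale).
#' @param stage `"map"` or `"mle"`; defaults to the fit's method.
#' @param ... unused.
#' @return A numeric matrix, one row per subject x condition session.
#' @export
coef.twostep_fit <- function(object, space = c("natural", "transformed"),
                             stage = NULL, ...) {
  space <- match.arg(space)
  est <- fit_estimates(object, stage)
  cols <- if (space == "natural") variant_info(object$model)$params
          else transformed_names(object$model)
  m <- as.matrix(est[, cols, drop = FALSE])
  rownames(m) <- paste(est$subject, est$condition, sep = ".")
  m
}

fit_estimates <- function(object, stage = NULL) {
  stage <- stage %||% object$method
  if (stage == "mle") object$mle_estimates else object$estimates
}

#' @export
logLik.twostep_fit <- function(object, ...) {
  est <- object$estimates
  k <- length(transformed_names(object$model)) -
    length(object$fixed %||% numeric(0))
  val <- -sum(est$nll)
  attr(val, "df") <- k * nrow(est)
  attr(val, "nobs") <- sum(vapply(object$sessions,
                                  function(s) 2L * nrow(s), integer(1)))
  class(val) <- "logLik"
  val
}

#' Summarise a two-step fit
#'
#' Reports per-condition medians and quartiles of the natural-space
#' estimates and, when the design has exactly two conditions with paired
#' subjects, two-tailed paired t tests on every transformed parameter
#' between conditions.
#'
#' @param object a `twostep_fit`.
#' @param ... unused.
#' @return A list of class `summary.twostep_fit`.
#' @export
summary.twostep_fit <- function(object, ...) {
  est <- object$estimates
  nat <- variant_info(object$model)$params
  tn <- transformed_names(object$model)
  conds <- unique(est$condition)
  quart <- lapply(stats::setNames(conds, conds), function(cn) {
    d <- est[est$condition == cn, nat, drop = FALSE]
    t(vapply(d, function(x) stats::quantile(x, c(0.25, 0.5, 0.75)),
             numeric(3)))
  })
  tests <- NULL
  if (length(conds) == 2L) {
    e1 <- est[est$condition == conds[1], ]
    e2 <- est[est$condition == conds[2], ]
    common <- intersect(e1$subject, e2$subject)
    if (length(common) >= 2L) {
      e1 <- e1[match(common, e1$subject), ]
      e2 <- e2[match(common, e2$subject), ]
      tests <- do.call(rbind, lapply(tn, function(p) {
        tt <- paired_condition_test(e1[[p]], e2[[p]])
        data.frame(parameter = p, mean_diff = tt$mean_diff, t = tt$t,
                   df = tt$df, p_value = tt$p, stringsAsFactors = FALSE)
      }))
    }
  }
  structure(list(model = object$model, method = object$method,
                 quartiles = quart, condition_tests = tests,
                 conditions = conds, n_sessions = nrow(est),
                 total_nll = sum(est$nll),
                 n_converged = sum(est$converged)),
            class = "summary.twostep_fit")
}

#' @export
print.summary.twostep_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-step RL fit summary: %s model (%s), %d sessions, %d converged\n",
              x$model, x$method, x$n_sessions, x$n_converged))
  cat(sprintf("Total negative log-likelihood: %.2f\n", x$total_nll))
  for (cn in names(x$quartiles)) {
    cat(sprintf("\nCondition %s (25%% / median / 75%%):\n", cn))
    print(round(x$quartiles[[cn]], digits))
  }
  if (!is.null(x$condition_tests)) {
    cat(sprintf("\nPaired t tests (%s - %s, transformed space):\n",
                x$conditions[2], x$conditions[1]))
    df <- x$condition_tests
    df$mean_diff <- round(df$mean_diff, digits)
    df$t <- round(df$t, digits)
    df$p_value <- signif(df$p_value, digits)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Fitted per-trial choice probabilities
#'
#' Replays each session under its fitted parameters and returns the
#' probability the model assigned to every observed choice.
#'
#' @param object a `twostep_fit`.
#' @param newdata optional trial data (long `data.frame` or session list);
#'   each session must have a subject/condition pair that was fitted.
#' @param ... unused.
#' @return A `data.frame` with `subject`, `condition`, `trial`, `p1`, `p2`.
#' @export
predict.twostep_fit <- function(object, newdata = NULL, ...) {
  sessions <- if (is.null(newdata)) object$sessions
              else split_sessions(newdata)
  est <- object$estimates
  out <- lapply(sessions, function(s) {
    i <- which(est$subject == s$subject[1] & est$condition == s$condition[1])
    if (!length(i))
      stop("no fitted parameters for ", s$subject[1], "/", s$condition[1],
           call. = FALSE)
    pars <- estimate_params(object, i)
    pr <- session_choice_probs(pars, s, object$model, object$config)
    cbind(data.frame(subject = s$subject[1], condition = s$condition[1],
                     stringsAsFactors = FALSE), pr)
  })
  do.call(rbind, out)
}

estimate_params <- function(object, i) {
  est <- object$estimates
  nat <- variant_info(object$model)$params
  vals <- stats::setNames(as.numeric(est[i, nat]), nat)
  agent_params(vals, variant = object$model,
               lambda_trace = object$lambda_trace)
}

#' First-stage choice residuals
#'
#' Pearson or deviance residuals of the observed first-stage choices
#' against their fitted probabilities.
#'
#' @param object a `twostep_fit`.
#' @param type `"pearson"` or `"deviance"`.
#' @param ... unused.
#' @return A `data.frame` with `subject`, `condition`, `trial`, `residual`.
#' @export
residuals.twostep_fit <- function(object, type = c("pearson", "deviance"),
                                  ...) {
  type <- match.arg(type)
  pr <- predict(object)
  trials <- do.call(rbind, lapply(object$sessions, as.data.frame))
  y <- trials$choice1
  p_choice <- pr$p1                       # prob of the observed choice
  p1 <- ifelse(y == 1L, p_choice, 1 - p_choice)   # prob of choosing action 1
  res <- if (type == "pearson") (y - p1) / sqrt(pmax(p1 * (1 - p1), 1e-12))
         else sign(y - p1) * sqrt(-2 * log(pmax(p_choice, 1e-300)))
  data.frame(subject = pr$subject, condition = pr$condition,
             trial = pr$trial, residual = res, stringsAsFactors = FALSE)
}

#' Simulate sessions from a fitted model
#'
#' Generates new sessions at each subject x condition's fitted parameters
#' on the fit's task configuration.
#'
#' @param object a `twostep_fit`.
#' @param nsim number of replicate sessions per fitted session.
#' @param seed integer seed.
#' @param ... unused.
#' @return A long trial `data.frame`; replicate index in column `sim`.
#' @export
simulate.twostep_fit <- function(object, nsim = 1, seed = 1L, ...) {
  est <- object$estimates
  out <- list()
  for (r in seq_len(nsim)) {
    for (i in seq_len(nrow(est))) {
      pars <- estimate_params(object, i)
      s <- run_session(pars, object$config,
                       seed = derive_seed(seed, 77L, r, i),
                       variant = object$model, subject = est$subject[i],
                       condition = est$condition[i])
      d <- as.data.frame(s)
      d$sim <- r
      out[[length(out) + 1L]] <- d
    }
  }
  do.call(rbind, out)
}

#' Plot per-subject estimates by condition
#'
#' With two conditions, scatters each subject's transformed model-based
#' weight (or another parameter) in condition 1 against condition 2 with
#' the identity line, the classic display of a within-subject parameter
#' shift; with one condition, boxplots of the transformed estimates.
#'
#' @param x a `twostep_fit`.
#' @param parameter transformed parameter name (default `"w"`).
#' @param ... passed to the underlying plotting function.
#' @export
plot.twostep_fit <- function(x, parameter = "w", ...) {
  est <- x$estimates
  conds <- unique(est$condition)
  if (length(conds) == 2L) {
    e1 <- est[est$condition == conds[1], ]
    e2 <- est[est$condition == conds[2], ]
    common <- intersect(e1$subject, e2$subject)
    v1 <- e1[[parameter]][match(common, e1$subject)]
    v2 <- e2[[parameter]][match(common, e2$subject)]
    lim <- range(c(v1, v2))
    graphics::plot(v1, v2, xlab = paste(parameter, "-", conds[1]),
                   ylab = paste(parameter, "-", conds[2]),
                   xlim = lim, ylim = lim,
                   main = sprintf("Per-subject %s by condition", parameter),
                   pch = 19, ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    graphics::boxplot(est[, transformed_names(x$model), drop = FALSE],
                      main = "Transformed parameter estimates", ...)
  }
  invisible(x)
}
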