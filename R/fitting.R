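#' Controls for the hierarchical fitting procedure
#'
#' @param n_restarts number of seeded random starting points for each
#'   subject-level maximum-likelihood optimisation.
#' @param map_restarts number of starting points for each MAP optimisation
#'   (the stage-1 estimate and the prior mean are always included).
#' @param max_iters total number of fitting passes: 2 means the standard
#'   two-stage procedure (stage 1 = per-subject MLE, stage 2 = MAP under the
#'   empirical population prior); values above 2 re-estimate the prior from
#'   the MAP fits and repeat stage 2.
#' @param var_floor floor on the prior variance of each transformed
#'   parameter, preventing prior collapse on small cohorts.
#' @param maxit maximum optimiser iterations per start.
#' @return A list of class `fit_controls`.
#' @export
fit_controls <- function(n_restarts = 10L, map_restarts = 4L, max_iters = 2L,
                         var_floor = 1e-3, maxit = 500L) {
  stopifnot(n_restarts >= 1L, map_restarts >= 0L, max_iters >= 1L,
            var_floor > 0)
  structure(list(n_restarts = as.integer(n_restarts),
                 map_restarts = as.integer(map_restarts),
                 max_iters = as.integer(max_iters),
                 var_floor = var_floor, maxit = as.integer(maxit)),
            class = "fit_controls")
}

# starting-point box in transformed space, per transformed parameter name;
# spans the plausible natural regimes (rates/weights well inside (0,1),
# beta roughly 0.5-12, pi roughly 0.05-3)
start_box <- function(tname) {
  switch(tname,
         b = c(-0.7, 2.5),
         p = c(-3, 1.2),
         w = c(-3, 3),
         c(-2.5, 2.5))
}

# fast closure over the compiled likelihood for free transformed coordinates
make_nll_fn <- function(session, variant, config, lambda_trace, fixed_t) {
  info <- variant_info(variant)
  tn <- unname(info$tnames[info$params])
  is_logit <- info$params %in% .logistic_params
  code <- match(variant, model_variants()) - 1L
  session <- as_session_df(session)
  c1 <- session$choice1; s2 <- session$state2
  c2 <- session$choice2; rw <- session$reward
  cp <- config$common_prob; map0 <- config$mapping[1]
  full <- stats::setNames(numeric(length(tn)), tn)
  full[names(fixed_t)] <- fixed_t
  free <- setdiff(tn, names(fixed_t))
  fn <- function(theta) {
    full[free] <- theta
    nat <- ifelse(is_logit, stats::plogis(full), exp(full))
    val <- twostep_nll_cpp(nat, c1, s2, c2, rw, code, cp, lambda_trace, map0)
    if (!is.finite(val)) 1e10 else val
  }
  list(fn = fn, free = free, tn = tn, full = full)
}

# convert natural-space fixed values (e.g. c(omega = 0)) to transformed space
fixed_to_transformed <- function(fixed, variant) {
  if (is.null(fixed) || !length(fixed)) return(stats::setNames(numeric(0), character(0)))
  info <- variant_info(variant)
  bad <- setdiff(names(fixed), info$params)
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- vapply(names(fixed), function(p) {
    if (p %in% .logistic_params)
      stats::qlogis(min(max(fixed[[p]], 1e-6), 1 - 1e-6))
    else log(max(fixed[[p]], 1e-12))
  }, numeric(1))
  stats::setNames(out, unname(info$tnames[names(fixed)]))
}

run_optim <- function(start, fn, maxit) {
  res <- tryCatch(
    stats::optim(start, fn, method = "BFGS", control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value))
    res <- tryCatch(
      stats::optim(start, fn, method = "Nelder-Mead",
                   control = list(maxit = 4 * maxit)),
      error = function(e) NULL)
  res
}

optimize_from_starts <- function(starts, fn, maxit) {
  best <- NULL
  ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- run_optim(starts[i, ], fn, maxit)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      ok <- res$convergence == 0
    }
  }
  list(best = best, converged = ok)
}

finish_fit <- function(opt, helper, variant, lambda_trace, session,
                       n_restarts, stage, nll_fn = NULL) {
  theta <- helper$full
  if (is.null(opt$best)) {
    converged <- FALSE
    nll <- Inf
  } else {
    theta[helper$free] <- opt$best$par
    converged <- opt$converged
    nll <- if (is.null(nll_fn)) opt$best$value else nll_fn(opt$best$par)
  }
  natural <- untransform_params(theta, variant, lambda_trace)
  list(subject = session$subject[1] %||% NA_character_,
       condition = session$condition[1] %||% NA_character_,
       model = variant, stage = stage, theta = theta, natural = natural,
       nll = nll, n_restarts = n_restarts, converged = converged)
}

#' Maximum-likelihood fit of one session
#'
#' Minimises [session_nll()] over the transformed parameter space from
#' `n_restarts` seeded starting points drawn uniformly from a fixed box
#' (first start at the box centre), using quasi-Newton optimisation with a
#' simplex fallback. Deterministic given the seed.
#'
#' @param session a session `data.frame`.
#' @param variant model variant name.
#' @param config a [task_config()].
#' @param n_restarts number of starting points.
#' @param seed integer seed for the starting points.
#' @param fixed optional named natural-space values to hold fixed (defining
#'   nested reductions, e.g. `c(omega = 0)` for a pure model-free agent).
#' @param lambda_trace eligibility constant.
#' @param maxit maximum optimiser iterations per start.
#' @return A list with elements `subject`, `condition`, `model`, `stage`
#'   (`"mle"`), `theta` (transformed estimates), `natural`
#'   ([agent_params()]), `nll`, `n_restarts`, `converged`.
#' @export
fit_subject_mle <- function(session, variant = "hybrid",
                            config = task_config(), n_restarts = 10L,
                            seed = 1L, fixed = NULL, lambda_trace = 1,
                            maxit = 500L) {
  variant <- match.arg(variant, model_variants())
  fixed_t <- fixed_to_transformed(fixed, variant)
  helper <- make_nll_fn(session, variant, config, lambda_trace, fixed_t)
  k <- length(helper$free)
  if (k == 0L) {
    opt <- list(best = list(par = numeric(0), value = helper$fn(numeric(0)),
                            convergence = 0), converged = TRUE)
    return(finish_fit(opt, helper, variant, lambda_trace, session, 0L, "mle"))
  }
  box <- vapply(helper$free, start_box, numeric(2))
  starts <- with_seed(seed, {
    s <- matrix(stats::runif(n_restarts * k, rep(box[1, ], each = n_restarts),
                             rep(box[2, ], each = n_restarts)),
                nrow = n_restarts)
    s[1, ] <- colMeans(box)
    s
  })
  opt <- optimize_from_starts(starts, helper$fn, maxit)
  finish_fit(opt, helper, variant, lambda_trace, session, n_restarts, "mle")
}

#' Empirical-Bayes population prior
#'
#' Gaussian moments of the transformed subject-level estimates, pooled
#' across all subjects and conditions, with the variance floored.
#'
#' @param thetas matrix of transformed estimates (rows = subject x
#'   condition fits).
#' @param var_floor floor on each prior variance.
#' @return A list with `mean` and `sd` (named numeric vectors) and
#'   `floored` (logical per parameter).
#' @export
population_prior <- function(thetas, var_floor = 1e-3) {
  mu <- colMeans(thetas)
  sdv <- apply(thetas, 2, stats::sd)
  sdv[is.na(sdv)] <- 0
  floored <- sdv^2 < var_floor
  sdv[floored] <- sqrt(var_floor)
  list(mean = mu, sd = sdv, floored = floored)
}

# MAP fit of one session under a Gaussian prior in transformed space
fit_subject_map <- function(session, prior, variant = "hybrid",
                            config = task_config(), start_theta = NULL,
                            map_restarts = 4L, seed = 1L, fixed = NULL,
                            lambda_trace = 1, maxit = 500L) {
  fixed_t <- fixed_to_transformed(fixed, variant)
  helper <- make_nll_fn(session, variant, config, lambda_trace, fixed_t)
  free <- helper$free
  mu <- prior$mean[free]; sdv <- prior$sd[free]
  fn_map <- function(theta) helper$fn(theta) + sum(((theta - mu) / sdv)^2) / 2
  starts <- rbind(if (!is.null(start_theta)) start_theta[free], mu)
  if (map_restarts > nrow(starts)) {
    extra <- with_seed(seed, matrix(stats::rnorm((map_restarts - nrow(starts)) *
                                                 length(free), mean = mu,
                                                 sd = sdv),
                                    ncol = length(free), byrow = TRUE))
    starts <- rbind(starts, extra)
  }
  opt <- optimize_from_starts(starts, fn_map, maxit)
  finish_fit(opt, helper, variant, lambda_trace, session, nrow(starts),
             "map", nll_fn = helper$fn)
}

fits_to_df <- function(fits) {
  tn <- names(fits[[1]]$theta)
  natn <- names(fits[[1]]$natural)
  rows <- lapply(fits, function(f) {
    row <- data.frame(subject = f$subject, condition = f$condition,
                      model = f$model, stage = f$stage,
                      stringsAsFactors = FALSE)
    for (j in seq_along(tn)) row[[tn[j]]] <- unname(f$theta[j])
    for (j in seq_along(natn)) row[[natn[j]]] <- unname(f$natural[j])
    row$nll <- f$nll
    row$converged <- f$converged
    row
  })
  do.call(rbind, rows)
}

#' Two-stage hierarchical (empirical-Bayes) fitting of a cohort
#'
#' Stage 1 fits every subject x condition session by maximum likelihood;
#' the per-parameter Gaussian moments of those estimates, pooled across
#' conditions, form an empirical population prior; stage 2 refits every
#' session by maximum a posteriori under that prior, which regularises the
#' individual estimates against overfitting. This is the simplified
#' two-stage form of the iterative expectation-maximisation scheme; extra
#' prior/MAP iterations are available through `controls$max_iters`.
#'
#' @param sessions a list of session `data.frame`s, or one long trial
#'   `data.frame` containing `subject` and `condition` columns.
#' @param variant model variant name.
#' @param config a [task_config()].
#' @param controls a [fit_controls()] list.
#' @param seed master seed; per-session optimisation seeds are derived from
#'   it.
#' @param fixed optional named natural-space values held fixed for all
#'   subjects.
#' @param lambda_trace eligibility constant.
#' @return A list of class `twostep_popfit` with elements `prior`, `mle`
#'   and `map` (per-session estimate `data.frame`s), `variant`, `controls`.
#' @export
fit_population <- function(sessions, variant = "hybrid",
                           config = task_config(), controls = fit_controls(),
                           seed = 1L, fixed = NULL, lambda_trace = 1) {
  variant <- match.arg(variant, model_variants())
  sessions <- split_sessions(sessions)
  if (length(sessions) < 2L)
    stop("hierarchical fitting needs at least 2 sessions", call. = FALSE)
  mle_fits <- lapply(seq_along(sessions), function(i)
    fit_subject_mle(sessions[[i]], variant, config,
                    n_restarts = controls$n_restarts,
                    seed = derive_seed(seed, 1L, i), fixed = fixed,
                    lambda_trace = lambda_trace, maxit = controls$maxit))
  thetas <- do.call(rbind, lapply(mle_fits, function(f) f$theta))
  prior <- population_prior(thetas, controls$var_floor)
  if (any(prior$floored))
    message("prior variance floored for: ",
            paste(names(prior$mean)[prior$floored], collapse = ", "))
  map_fits <- mle_fits
  for (pass in seq_len(max(controls$max_iters - 1L, 0L))) {
    map_fits <- lapply(seq_along(sessions), function(i)
      fit_subject_map(sessions[[i]], prior, variant, config,
                      start_theta = map_fits[[i]]$theta,
                      map_restarts = controls$map_restarts,
                      seed = derive_seed(seed, 1L + pass, i), fixed = fixed,
                      lambda_trace = lambda_trace, maxit = controls$maxit))
    if (pass < controls$max_iters - 1L) {
      thetas <- do.call(rbind, lapply(map_fits, function(f) f$theta))
      prior <- population_prior(thetas, controls$var_floor)
    }
  }
  structure(list(prior = prior, mle = fits_to_df(mle_fits),
                 map = if (controls$max_iters > 1L) fits_to_df(map_fits)
                       else NULL,
                 variant = variant, controls = controls, seed = seed),
            class = "twostep_popfit")
}

# split a long trial data.frame into per subject x condition sessions,
# preserving first-appearance order; lists pass through (validated)
split_sessions <- function(data) {
  if (inherits(data, "twostep_cohort")) data <- data$trials
  if (is.list(data) && !is.data.frame(data)) {
    return(lapply(data, as_session_df))
  }
  if (!all(c("subject", "condition") %in% names(data)))
    stop("trial data must contain `subject` and `condition` columns",
         call. = FALSE)
  key <- paste(data$subject, data$condition, sep = "\r")
  parts <- split(data, factor(key, levels = unique(key)))
  lapply(parts, function(d) as_session_df(d[order(d$trial), , drop = FALSE]))
}

#' Paired comparison of per-subject estimates between conditions
#'
#' Classical two-tailed paired t test on per-subject values (typically
#' transformed parameter estimates) from two conditions; the statistic is
#' computed on `values_b - values_a`, so a positive `t` means higher values
#' in the second condition. Zero variance of the differences is signalled
#' with a warning: identical vectors give `t = 0, p = 1`; constant nonzero
#' differences give an infinite `t` with `p = 0`.
#'
#' @param values_a,values_b equal-length paired numeric vectors.
#' @return A list with `t`, `df`, `p`, `mean_diff` and `n`.
#' @export
paired_condition_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(values_a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- values_b - values_a
  if (stats::sd(d) == 0) {
    m <- mean(d)
    if (m == 0) {
      warning("zero variance and zero mean of differences; t undefined, ",
              "reported as 0")
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0, n = n))
    }
    warning("zero variance of differences; t is infinite")
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, mean_diff = m, n = n))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), n = n)
}

#' Pairwise correlations between fitted parameters
#'
#' Pearson correlations with two-tailed p values among per-subject
#' (transformed) parameter estimates; substantial correlations would
#' indicate parameter redundancy. Constant columns are flagged and their
#' correlations reported as `NA`.
#'
#' @param estimates numeric matrix or `data.frame`, rows = subjects,
#'   columns = parameters.
#' @return A list of class `param_correlations` with matrices `r` and `p`,
#'   the sample size `n`, and `constant` (logical per column).
#' @export
param_correlations <- function(estimates) {
  est <- as.matrix(estimates)
  if (nrow(est) < 3L) stop("need at least 3 subjects", call. = FALSE)
  k <- ncol(est)
  constant <- apply(est, 2, function(x) stats::sd(x) == 0)
  if (any(constant))
    warning("constant column(s): ",
            paste(colnames(est)[constant], collapse = ", "))
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(est),
                                                   colnames(est)))
  diag(r) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (constant[i] || constant[j]) next
    ct <- stats::cor.test(est[, i], est[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = nrow(est), constant = constant),
            class = "param_correlations")
}

#' @export
print.param_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise parameter correlations (n = %d subjects)\n", x$n))
  cat("r:\n"); print(round(x$r, digits))
  cat("two-tailed p:\n"); print(round(x$p, digits))
  invisible(x)
}
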