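#' Configuration of a synthetic within-subject crossover cohort
#'
#' Describes the study design the package emulates: a cohort of subjects
#' each completing one session per condition on the same two-step task,
#' with per-subject generating parameters drawn around condition-specific
#' population values in transformed (Gaussian) space. The default
#' population means are the reported per-condition median estimates of the
#' winning hybrid model (placebo: alpha 0.45, beta 5.4, pi 1.37, omega
#' 0.58; L-DOPA: alpha 0.37, beta 4.7, pi 0.70, omega 0.78), and the
#' default between-subject spread is 0.5 on every transformed coordinate.
#'
#' @param n_subjects number of subjects (default 18).
#' @param condition_means named list, one element per condition, each a
#'   named vector of natural-space population means for `variant`.
#' @param between_sd between-subject standard deviation(s) in transformed
#'   space; a scalar (recycled) or a vector named by transformed parameter.
#' @param variant model variant generating the behaviour.
#' @param task a [task_config()].
#' @param seed master seed; all per-session seeds are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 18L,
                          condition_means = list(
                            placebo = c(alpha = 0.45, beta = 5.4,
                                        pi = 1.37, omega = 0.58),
                            ldopa = c(alpha = 0.37, beta = 4.7,
                                      pi = 0.70, omega = 0.78)),
                          between_sd = 0.5, variant = "hybrid",
                          task = task_config(), seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("`n_subjects` must be at least 2", call. = FALSE)
  variant <- match.arg(variant, model_variants())
  if (is.null(names(condition_means)) || length(condition_means) < 1L)
    stop("`condition_means` must be a named list of parameter vectors",
         call. = FALSE)
  for (cm in condition_means) agent_params(cm, variant = variant)
  if (any(between_sd < 0))
    stop("`between_sd` must be nonnegative", call. = FALSE)
  structure(list(n_subjects = n_subjects, condition_means = condition_means,
                 between_sd = between_sd, variant = variant, task = task,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d condition(s) x %d trials (%s)\n",
              x$n_subjects, length(x$condition_means), x$task$n_trials,
              x$variant))
  for (cn in names(x$condition_means)) {
    cat(sprintf("  %s: %s\n", cn,
                paste(sprintf("%s=%.3g", names(x$condition_means[[cn]]),
                              x$condition_means[[cn]]), collapse = ", ")))
  }
  cat(sprintf("  between-subject sd (transformed): %s; seed %d\n",
              paste(format(x$between_sd), collapse = ", "), x$seed))
  invisible(x)
}

# expand between_sd to a named vector over the variant's transformed names
expand_between_sd <- function(between_sd, variant) {
  info <- variant_info(variant)
  tn <- unname(info$tnames[info$params])
  if (is.null(names(between_sd))) {
    stats::setNames(rep_len(between_sd, length(tn)), tn)
  } else {
    miss <- setdiff(tn, names(between_sd))
    if (length(miss))
      stop("`between_sd` missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    between_sd[tn]
  }
}

#' Generate a complete synthetic cohort
#'
#' Each subject receives one Gaussian deviation vector in transformed
#' space (standard deviation `between_sd`), shared across conditions so
#' that the condition manipulation is a pure within-subject mean shift;
#' the subject's parameters in a condition are the condition's transformed
#' population mean plus that deviation, mapped back to natural space, and
#' a full session is simulated with [run_session()]. Reward walks are
#' drawn independently for every session; the task structure (transition
#' mapping and probability) is shared by all. Fully reproducible from the
#' master seed.
#'
#' @param config a [cohort_config()].
#' @return A list of class `twostep_cohort` with elements `trials` (one
#'   long `data.frame`, all sessions stacked), `truth` (per subject x
#'   condition generating parameters, natural space), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  variant <- config$variant
  sds <- expand_between_sd(config$between_sd, variant)
  conds <- names(config$condition_means)
  trials <- list(); truth <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", s)
    # one deviation per subject, shared across conditions: the crossover
    # design manipulates the condition means within subject
    dev <- with_seed(derive_seed(config$seed, 101L, s),
                     stats::rnorm(length(sds), 0, sds))
    for (ci in seq_along(conds)) {
      mu <- transform_params(
        agent_params(config$condition_means[[conds[ci]]], variant = variant),
        variant)
      theta <- stats::setNames(mu + dev, names(mu))
      pars <- untransform_params(theta, variant)
      sess <- run_session(pars, config$task,
                          seed = derive_seed(config$seed, 202L, s, ci),
                          variant = variant, subject = sid,
                          condition = conds[ci])
      d <- as.data.frame(sess)
      attr(d, "config") <- NULL
      attr(d, "reward_walks") <- NULL
      attr(d, "seed") <- NULL
      trials[[length(trials) + 1L]] <- d
      tr <- data.frame(subject = sid, condition = conds[ci],
                       stringsAsFactors = FALSE)
      for (p in names(pars)) tr[[p]] <- unname(pars[p])
      truth[[length(truth) + 1L]] <- tr
    }
  }
  structure(list(trials = do.call(rbind, trials),
                 truth = do.call(rbind, truth), config = config),
            class = "twostep_cohort")
}

#' @export
print.twostep_cohort <- function(x, ...) {
  cat(sprintf("Two-step cohort: %d subjects, conditions: %s, %d trials/session\n",
              length(unique(x$trials$subject)),
              paste(unique(x$trials$condition), collapse = ", "),
              max(x$trials$trial)))
  if (is.null(x$truth)) cat("  generating parameters: not available (blind)\n")
  invisible(x)
}

#' Total earnings per session
#'
#' @param data a cohort, session list or long trial `data.frame`.
#' @return A `data.frame` with `subject`, `condition` and `earnings` (sum of
#'   rewards).
#' @export
session_earnings <- function(data) {
  sessions <- split_sessions(data)
  do.call(rbind, lapply(sessions, function(s)
    data.frame(subject = s$subject[1], condition = s$condition[1],
               earnings = sum(s$reward), stringsAsFactors = FALSE)))
}

#' Write and read a cohort as plain-text files
#'
#' `write_cohort()` writes one session CSV per subject x condition, a
#' `manifest.csv` with the design constants, and (if truths are present) a
#' `truth.csv` sidecar holding the generating parameters, kept separate so
#' the analysis can be run blind. `read_cohort()` reads the directory back,
#' validating every session; a missing sidecar yields a cohort with
#' `truth = NULL`.
#'
#' @param cohort a `twostep_cohort`.
#' @param dir directory to create/read.
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   `twostep_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twostep_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- split_sessions(cohort$trials)
  files <- character(0)
  for (s in sessions) {
    f <- sprintf("session_%s_%s.csv", s$subject[1], s$condition[1])
    utils::write.csv(as.data.frame(s), file.path(dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- cohort$config
  manifest <- data.frame(
    key = c("n_subjects", "variant", "n_trials", "common_prob", "walk_sd",
            "walk_lo", "walk_hi", "seed", "files"),
    value = c(cfg$n_subjects, cfg$variant, cfg$task$n_trials,
              cfg$task$common_prob, cfg$task$walk_sd,
              cfg$task$walk_bounds[1], cfg$task$walk_bounds[2], cfg$seed,
              paste(files, collapse = ";")),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  val <- function(k) manifest$value[manifest$key == k]
  files <- strsplit(val("files"), ";", fixed = TRUE)[[1]]
  trials <- lapply(files, function(f) {
    d <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    ok <- try(as_session_df(d), silent = TRUE)
    if (inherits(ok, "try-error")) {
      gap <- which(diff(as.integer(d$trial)) != 1L)
      stop("malformed session file ", f,
           if (length(gap)) paste0(" (trial index break after row ",
                                   gap[1] + 1L, ")"),
           ": ", attr(ok, "condition")$message, call. = FALSE)
    }
    ok
  })
  task <- task_config(n_trials = as.integer(val("n_trials")),
                      common_prob = as.numeric(val("common_prob")),
                      walk_sd = as.numeric(val("walk_sd")),
                      walk_bounds = c(as.numeric(val("walk_lo")),
                                      as.numeric(val("walk_hi"))))
  tf <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tf)) utils::read.csv(tf, stringsAsFactors = FALSE)
           else NULL
  all_trials <- do.call(rbind, lapply(trials, as.data.frame))
  conds <- unique(all_trials$condition)
  means <- if (!is.null(truth)) {
    lapply(stats::setNames(conds, conds), function(cn) {
      t_c <- truth[truth$condition == cn, setdiff(names(truth),
                                                  c("subject", "condition")),
                   drop = FALSE]
      vapply(t_c, stats::median, numeric(1))
    })
  } else NULL
  cfg <- if (!is.null(means))
    cohort_config(n_subjects = length(unique(all_trials$subject)),
                  condition_means = means, variant = val("variant"),
                  task = task, seed = as.integer(val("seed")))
  else NULL
  structure(list(trials = all_trials, truth = truth, config = cfg),
            class = "twostep_cohort")
}
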