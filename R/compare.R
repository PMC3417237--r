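#' Default model-comparison candidate set
#'
#' The fully parameterised hybrid model, its nested reductions (no
#' perseveration, pure model-free, pure model-based), and the three
#' alternative variants.
#'
#' @return A named list of model specifications, each a list with `variant`
#'   and optional `fixed` (natural-space values held fixed).
#' @export
default_model_set <- function() {
  list(hybrid = list(variant = "hybrid"),
       no_perseveration = list(variant = "hybrid", fixed = c(pi = 0)),
       model_free_only = list(variant = "hybrid", fixed = c(omega = 0)),
       model_based_only = list(variant = "hybrid", fixed = c(omega = 1)),
       dual_rate = list(variant = "dual_rate"),
       separate_values = list(variant = "separate_values"),
       actor_critic = list(variant = "actor_critic"))
}

#' Compare model variants and nested reductions on a common session set
#'
#' Fits every candidate model to every session by maximum likelihood and
#' aggregates fit quality across subjects. Models are scored by BIC summed
#' over subjects, with the per-subject penalty `k * log(n_choices)` counting
#' each session's two choices per trial as observations; the lowest total
#' BIC is flagged best.
#'
#' @param sessions list of session `data.frame`s or one long trial
#'   `data.frame`.
#' @param models named list of model specifications as in
#'   [default_model_set()].
#' @param config a [task_config()].
#' @param n_restarts,seed,maxit optimisation settings per session (see
#'   [fit_subject_mle()]).
#' @return A `data.frame` of class `twostep_model_comparison` with one row
#'   per model: `model`, `variant`, `k` (free parameters), `total_nll`,
#'   `total_bic`, `delta_bic`, `best`.
#' @export
compare_models <- function(sessions, models = default_model_set(),
                           config = task_config(), n_restarts = 10L,
                           seed = 1L, maxit = 500L) {
  sessions <- split_sessions(sessions)
  if (!length(sessions)) stop("no sessions to fit", call. = FALSE)
  if (is.null(names(models)) || any(names(models) == ""))
    stop("`models` must be a named list", call. = FALSE)
  rows <- lapply(seq_along(models), function(m) {
    spec <- models[[m]]
    variant <- spec$variant
    info <- variant_info(variant)
    fixed <- spec$fixed
    k <- length(info$params) - length(fixed)
    fits <- lapply(seq_along(sessions), function(i)
      fit_subject_mle(sessions[[i]], variant, config,
                      n_restarts = n_restarts,
                      seed = derive_seed(seed, m, i), fixed = fixed,
                      maxit = maxit))
    nll <- vapply(fits, function(f) f$nll, numeric(1))
    nobs <- vapply(sessions, function(s) 2 * nrow(s), numeric(1))
    data.frame(model = names(models)[m], variant = variant, k = k,
               total_nll = sum(nll), total_bic = sum(2 * nll + k * log(nobs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_bic <- out$total_bic - min(out$total_bic)
  out$best <- out$delta_bic == 0
  class(out) <- c("twostep_model_comparison", "data.frame")
  out
}

#' @export
print.twostep_model_comparison <- function(x, digits = 1, ...) {
  cat("Model comparison (BIC summed over subjects)\n")
  df <- as.data.frame(x)
  df$total_nll <- round(df$total_nll, digits)
  df$total_bic <- round(df$total_bic, digits)
  df$delta_bic <- round(df$delta_bic, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
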