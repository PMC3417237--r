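stay_cells <- function() c("rewarded_common", "rewarded_rare",
                           "unrewarded_common", "unrewarded_rare")

#' Stay probabilities conditioned on the previous trial
#'
#' For every trial after the first, a "stay" is repeating the previous
#' trial's first-stage choice. Each such trial is assigned to one of four
#' cells by the *previous* trial's reward (rewarded/unrewarded) and
#' transition type (common/rare); the stay probability of a cell is the
#' proportion of stays among its eligible trials. The first trial of a
#' session contributes no observation; trials straddling the in-session
#' breaks are treated like any other consecutive pair. A cell with no
#' eligible trials has `p_stay = NA`.
#'
#' @param session a session `data.frame` (see [run_session()]).
#' @return A `data.frame` with 4 rows: `subject`, `condition`,
#'   `prev_reward`, `prev_transition`, `cell`, `n`, `n_stay`, `p_stay`.
#' @export
stay_table <- function(session) {
  session <- as_session_df(session)
  n <- nrow(session)
  if (n < 2L) stop("session must have at least 2 trials", call. = FALSE)
  stay <- session$choice1[-1L] == session$choice1[-n]
  prev_rew <- ifelse(session$reward[-n] == 1L, "rewarded", "unrewarded")
  prev_tr <- session$transition[-n]
  cell <- paste(prev_rew, prev_tr, sep = "_")
  out <- data.frame(subject = session$subject[1] %||% NA_character_,
                    condition = session$condition[1] %||% NA_character_,
                    prev_reward = rep(c("rewarded", "unrewarded"), each = 2),
                    prev_transition = rep(c("common", "rare"), 2),
                    stringsAsFactors = FALSE)
  out$cell <- paste(out$prev_reward, out$prev_transition, sep = "_")
  out$n <- vapply(out$cell, function(cl) sum(cell == cl), numeric(1))
  out$n_stay <- vapply(out$cell, function(cl) sum(stay[cell == cl]),
                       numeric(1))
  out$p_stay <- ifelse(out$n > 0, out$n_stay / out$n, NA_real_)
  rownames(out) <- NULL
  out
}

#' Stay tables for a whole cohort
#'
#' @param data a `twostep_cohort`, a list of sessions, or a long trial
#'   `data.frame` with `subject` and `condition` columns.
#' @return Row-bound [stay_table()] results for every subject x condition.
#' @export
stay_tables <- function(data) {
  sessions <- split_sessions(data)
  do.call(rbind, lapply(sessions, stay_table))
}

# subjects with all 4 cells observed in both conditions; warns about and
# drops incomplete ones
complete_stay_subjects <- function(tables) {
  tables <- as.data.frame(tables)
  conds <- unique(tables$condition)
  if (length(conds) != 2L)
    stop("stay-switch analysis needs exactly 2 conditions", call. = FALSE)
  ok <- vapply(split(tables, tables$subject), function(d)
    nrow(d) == 8L && !anyNA(d$p_stay), logical(1))
  if (any(!ok))
    warning(sum(!ok), " subject(s) excluded for incomplete stay cells")
  subs <- names(ok)[ok]
  if (length(subs) < 2L)
    stop("fewer than 2 complete subjects", call. = FALSE)
  tables[tables$subject %in% subs, , drop = FALSE]
}

#' Three-way repeated-measures ANOVA on stay probabilities
#'
#' Per-subject cell-mean stay probabilities enter a 2x2x2 within-subject
#' ANOVA with factors condition (drug), previous reward and previous
#' transition, yielding the three main effects, three two-way interactions
#' and the three-way interaction, each on (1, n-1) degrees of freedom. In
#' this all-two-level design every F equals the squared paired t of the
#' corresponding per-subject contrast score. Subjects with any empty cell
#' are excluded with a warning.
#'
#' @param tables stacked [stay_table()] rows for every subject in both
#'   conditions (see [stay_tables()]).
#' @return A `data.frame` of class `stay_anova` with columns `effect`,
#'   `df1`, `df2`, `F`, `p`.
#' @export
rm_anova_2x2x2 <- function(tables) {
  tables <- complete_stay_subjects(tables)
  d <- data.frame(subject = factor(tables$subject),
                  drug = factor(tables$condition),
                  reward = factor(tables$prev_reward),
                  transition = factor(tables$prev_transition),
                  p_stay = tables$p_stay)
  if (stats::sd(d$p_stay) == 0) {
    warning("constant stay probabilities; all effects undefined")
    eff <- c("drug", "reward", "transition", "drug:reward",
             "drug:transition", "reward:transition",
             "drug:reward:transition")
    out <- data.frame(effect = eff, df1 = 1L,
                      df2 = nlevels(d$subject) - 1L, F = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    class(out) <- c("stay_anova", "data.frame")
    return(out)
  }
  fit <- stats::aov(p_stay ~ drug * reward * transition +
                      Error(subject / (drug * reward * transition)),
                    data = d)
  out <- do.call(rbind, lapply(summary(fit), function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    data.frame(effect = eff[keep], df1 = tab$Df[keep],
               df2 = tab$Df[!keep], F = tab$`F value`[keep],
               p = tab$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  }))
  out <- out[out$effect != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stay_anova", "data.frame")
  out
}

#' @export
print.stay_anova <- function(x, digits = 3, ...) {
  cat("Repeated-measures ANOVA on stay probabilities (2 x 2 x 2 within)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$p <- signif(df$p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# per-subject matrix of condition differences (cond2 - cond1), one column
# per stay cell in stay_cells() order
stay_difference_matrix <- function(tables, conditions = NULL) {
  tables <- complete_stay_subjects(tables)
  if (is.null(conditions)) conditions <- unique(tables$condition)
  stopifnot(length(conditions) == 2L)
  subs <- unique(tables$subject)
  cells <- stay_cells()
  diffs <- matrix(NA_real_, length(subs), length(cells),
                  dimnames = list(subs, cells))
  for (s in seq_along(subs)) {
    d <- tables[tables$subject == subs[s], ]
    for (j in seq_along(cells)) {
      p2 <- d$p_stay[d$cell == cells[j] & d$condition == conditions[2]]
      p1 <- d$p_stay[d$cell == cells[j] & d$condition == conditions[1]]
      diffs[s, j] <- p2 - p1
    }
  }
  diffs
}

#' Mean-corrected condition-difference profile of stay probabilities
#'
#' For each of the four stay cells, the mean over subjects of the
#' between-condition difference in stay probability, centred by subtracting
#' the grand mean of the four differences (i.e. corrected for the main
#' effect of drug). The four values sum to zero by construction.
#'
#' @param tables stacked stay tables for both conditions.
#' @param conditions optional length-2 character vector giving the
#'   condition order; the difference is `conditions[2] - conditions[1]`.
#'   Defaults to first-appearance order.
#' @return Named numeric vector of 4 mean-corrected differences, in
#'   [stay_cells()] order.
#' @export
drug_difference_profile <- function(tables, conditions = NULL) {
  diffs <- stay_difference_matrix(tables, conditions)
  m <- colMeans(diffs)
  m - mean(m)
}

#' Post hoc contrast: differential drug effect after unrewarded trials
#'
#' Tests whether the between-condition change in stay probability differs
#' after unrewarded versus rewarded previous trials. Per subject, the drug
#' effect (averaged over transition type) after unrewarded trials minus
#' that after rewarded trials forms a contrast score; the within-subject F
#' on (1, n-1) df is the squared paired t of those scores.
#'
#' @inheritParams drug_difference_profile
#' @return A list with `F`, `df` (length-2), `p`, `t` and the per-subject
#'   contrast `scores`.
#' @export
posthoc_unrewarded_contrast <- function(tables, conditions = NULL) {
  diffs <- stay_difference_matrix(tables, conditions)
  scores <- (diffs[, "unrewarded_common"] + diffs[, "unrewarded_rare"]) / 2 -
    (diffs[, "rewarded_common"] + diffs[, "rewarded_rare"]) / 2
  n <- length(scores)
  tt <- paired_condition_test(numeric(n), scores)
  list(F = tt$t^2, df = c(1L, n - 1L), p = tt$p, t = tt$t, scores = scores)
}

#' Sign templates for hypothetical drug effects on stay behaviour
#'
#' Qualitative, mean-centred sign patterns describing how four hypothetical
#' drug effects would show up in the mean-corrected condition-difference
#' profile ([drug_difference_profile()]):
#'
#' * `model_free_shift` — a shift toward model-free control: more staying
#'   after rewarded rare trials, more switching after unrewarded rare
#'   trials; common-transition cells are nondiscriminative.
#' * `stronger_model_free` — stronger/faster model-free learning: more
#'   staying after any rewarded trial, less after any unrewarded trial.
#' * `positive_negative_asymmetry` — enhanced positive with impaired
#'   negative updating: the two shifts cancel after mean correction, so the
#'   template is zero.
#' * `model_based_shift` — a shift toward model-based control: enhanced
#'   sensitivity to the task structure, opposite in sign to
#'   `model_free_shift` on the rare-transition cells.
#'
#' @return A 4 x 4 numeric matrix (templates x cells, columns in
#'   [stay_cells()] order); every row sums to zero.
#' @export
hypothesis_templates <- function() {
  m <- rbind(model_free_shift = c(0, 1, 0, -1),
             stronger_model_free = c(1, 1, -1, -1),
             positive_negative_asymmetry = c(0, 0, 0, 0),
             model_based_shift = c(0, -1, 0, 1))
  colnames(m) <- stay_cells()
  m
}

#' Sign agreement between a difference profile and a template
#'
#' A profile matches a template when its sign agrees with the template's on
#' every cell where the template is nonzero (the all-zero template matches
#' only profiles that are numerically negligible everywhere,
#' `|x| < tol`).
#'
#' @param profile numeric vector of 4 mean-corrected differences in
#'   [stay_cells()] order.
#' @param template one row of [hypothesis_templates()] or its row name.
#' @param tol magnitude below which a profile entry counts as zero for the
#'   all-zero template.
#' @return Logical scalar.
#' @export
template_sign_match <- function(profile, template, tol = 1e-3) {
  if (is.character(template))
    template <- hypothesis_templates()[template, ]
  nz <- template != 0
  if (!any(nz)) return(all(abs(profile) < tol))
  all(sign(profile[nz]) == sign(template[nz]))
}
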