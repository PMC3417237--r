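# shared fixture builders (all data generated in code)

placebo_medians <- c(alpha = 0.45, beta = 5.4, pi = 1.37, omega = 0.58)
ldopa_medians <- c(alpha = 0.37, beta = 4.7, pi = 0.70, omega = 0.78)

# a small, fast session for unit tests
tiny_session <- function(seed = 42, n_trials = 100,
                         params = placebo_medians, variant = "hybrid") {
  run_session(agent_params(params, variant = variant),
              task_config(n_trials = n_trials), seed = seed,
              variant = variant)
}

# hand-build a session data.frame from first-stage choices, transitions and
# rewards (stage-2 fields filled consistently with the mapping)
build_session <- function(choice1, transition, reward, subject = "s01",
                          condition = "placebo") {
  mapped <- c(0L, 1L)[choice1 + 1L]
  state2 <- ifelse(transition == "common", mapped, 1L - mapped)
  data.frame(subject = subject, condition = condition,
             trial = seq_along(choice1), choice1 = choice1,
             transition = transition, state2 = as.integer(state2),
             choice2 = 0L, reward = reward, stringsAsFactors = FALSE)
}

# random per-subject stay tables in the long format rm_anova_2x2x2 expects
random_stay_tables <- function(n_subjects, effects = list(), sd = 0.08,
                               seed = 1) {
  cells <- expand.grid(prev_reward = c("rewarded", "unrewarded"),
                       prev_transition = c("common", "rare"),
                       condition = c("placebo", "ldopa"),
                       stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_subjects), function(s) {
      d <- cells
      d$subject <- sprintf("s%02d", s)
      d$cell <- paste(d$prev_reward, d$prev_transition, sep = "_")
      mu <- 0.6 +
        (if (!is.null(effects$reward))
           effects$reward * ifelse(d$prev_reward == "rewarded", 0.5, -0.5)
         else 0) +
        (if (!is.null(effects$drug_unrewarded))
           effects$drug_unrewarded *
             (d$condition == "ldopa") * (d$prev_reward == "unrewarded")
         else 0)
      d$n <- 40L
      d$p_stay <- pmin(pmax(stats::rnorm(nrow(d), mu, sd), 0), 1)
      d$n_stay <- round(d$p_stay * d$n)
      d
    })
    do.call(rbind, out)
  })
}

# independent contrast-score oracle for the all-two-level within-subject
# ANOVA: F of each effect as the squared paired t of its contrast score
anova_contrast_oracle <- function(tables) {
  tables$d_sign <- ifelse(tables$condition == sort(unique(tables$condition))[1],
                          -1, 1)
  tables$r_sign <- ifelse(tables$prev_reward ==
                            sort(unique(tables$prev_reward))[1], -1, 1)
  tables$t_sign <- ifelse(tables$prev_transition ==
                            sort(unique(tables$prev_transition))[1], -1, 1)
  effects <- list(drug = "d", reward = "r", transition = "t",
                  `drug:reward` = c("d", "r"),
                  `drug:transition` = c("d", "t"),
                  `reward:transition` = c("r", "t"),
                  `drug:reward:transition` = c("d", "r", "t"))
  sapply(effects, function(terms) {
    sgn <- Reduce(`*`, lapply(terms, function(k)
      tables[[paste0(k, "_sign")]]))
    scores <- tapply(tables$p_stay * sgn, tables$subject, mean)
    tt <- stats::t.test(scores)
    unname(tt$statistic^2)
  })
}
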