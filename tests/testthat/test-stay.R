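test_that("stay tables match exhaustive hand enumeration", {
  # degenerate repeat/alternate agents
  tr_cycle <- rep(c("common", "rare", "common", "rare"), 4)
  rw_cycle <- rep(c(1L, 1L, 0L, 0L), 4)
  rep_sess <- build_session(rep(0L, 16), tr_cycle, rw_cycle)
  st <- stay_table(rep_sess)
  expect_true(all(st$n > 0))
  expect_true(all(st$p_stay == 1))
  alt_sess <- build_session(rep(c(0L, 1L), 8), tr_cycle, rw_cycle)
  expect_true(all(stay_table(alt_sess)$p_stay == 0))

  # 7-trial session, cells enumerated by hand
  s7 <- build_session(choice1 = c(0L, 0L, 1L, 1L, 0L, 0L, 0L),
                      transition = c("common", "rare", "common", "common",
                                     "rare", "common", "rare"),
                      reward = c(1L, 0L, 1L, 1L, 0L, 0L, 1L))
  st7 <- stay_table(s7)
  get <- function(cell, col) st7[[col]][st7$cell == cell]
  expect_equal(get("rewarded_common", "n"), 3)
  expect_equal(get("rewarded_common", "p_stay"), 2 / 3)
  expect_equal(get("rewarded_rare", "n"), 0)
  expect_true(is.na(get("rewarded_rare", "p_stay")))
  expect_equal(get("unrewarded_rare", "p_stay"), 1 / 2)
  expect_equal(get("unrewarded_common", "p_stay"), 1)
})

test_that("cell assignment always uses the preceding trial's attributes", {
  s <- tiny_session(seed = 44, n_trials = 150)
  st <- stay_table(s)
  # independent re-count with a different code path
  for (rw in c("rewarded", "unrewarded")) for (tr in c("common", "rare")) {
    idx <- which(s$reward[-nrow(s)] == (rw == "rewarded") &
                   s$transition[-nrow(s)] == tr) + 1L
    stays <- sum(s$choice1[idx] == s$choice1[idx - 1L])
    row <- st[st$prev_reward == rw & st$prev_transition == tr, ]
    expect_equal(row$n, length(idx))
    expect_equal(row$n_stay, stays)
  }
})

test_that("every RM-ANOVA F equals the squared paired t of its contrast", {
  tabs <- random_stay_tables(10, seed = 6)
  an <- rm_anova_2x2x2(tabs)
  oracle <- anova_contrast_oracle(tabs)
  expect_equal(an$df1, rep(1L, 7))
  expect_equal(an$df2, rep(9L, 7))
  for (e in an$effect) {
    expect_equal(an$F[an$effect == e], unname(oracle[[e]]),
                 tolerance = 1e-8)
  }
})

test_that("a pure additive reward effect loads on the reward main effect only", {
  big_f <- null_f <- numeric(8)
  for (r in 1:8) {
    tabs <- random_stay_tables(14, effects = list(reward = 0.2), seed = 40 + r)
    an <- rm_anova_2x2x2(tabs)
    big_f[r] <- an$F[an$effect == "reward"]
    null_f[r] <- an$F[an$effect == "drug:reward:transition"]
  }
  expect_true(all(big_f > 10))
  expect_lt(stats::median(null_f), stats::qf(0.9, 1, 13))
})

test_that("constant stay probabilities are flagged as undefined", {
  tabs <- random_stay_tables(5, sd = 0, seed = 1)
  tabs$p_stay <- 0.6
  expect_warning(an <- rm_anova_2x2x2(tabs), "undefined")
  expect_true(all(is.na(an$F)))
})

test_that("incomplete subjects are excluded with a warning", {
  tabs <- random_stay_tables(6, seed = 2)
  tabs$p_stay[tabs$subject == "s01" & tabs$cell == "rewarded_rare" &
                tabs$condition == "placebo"] <- NA
  expect_warning(an <- rm_anova_2x2x2(tabs), "excluded")
  expect_equal(unique(an$df2), 4L)
})

test_that("the drug-difference profile is mean-centred and null under no effect", {
  prof <- drug_difference_profile(random_stay_tables(12, seed = 5))
  expect_equal(sum(prof), 0, tolerance = 1e-12)
  profs <- sapply(1:20, function(r)
    drug_difference_profile(random_stay_tables(12, seed = 100 + r)))
  expect_lt(max(abs(rowMeans(profs))), 0.02)
})

test_that("the unrewarded-trials contrast is calibrated and powered", {
  # no differential effect: near-null contrast
  ps <- sapply(1:20, function(r)
    posthoc_unrewarded_contrast(random_stay_tables(12, seed = 200 + r))$p)
  expect_gt(mean(ps > 0.05), 0.75)
  # drug effect confined to unrewarded trials: detected in most replicates
  hits <- sapply(1:20, function(r) {
    tabs <- random_stay_tables(18, effects = list(drug_unrewarded = 0.12),
                               seed = 400 + r)
    posthoc_unrewarded_contrast(tabs, conditions = c("placebo", "ldopa"))$p < 0.05
  })
  expect_gte(mean(hits), 0.75)
  # oracle identity: F is the squared paired t of the contrast scores
  tabs <- random_stay_tables(9, seed = 3)
  ph <- posthoc_unrewarded_contrast(tabs)
  tt <- stats::t.test(ph$scores)
  expect_equal(ph$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(ph$df, c(1L, 8L))
})

test_that("hypothesis templates encode the four drug-effect signatures", {
  tm <- hypothesis_templates()
  expect_equal(rowSums(tm), stats::setNames(rep(0, 4), rownames(tm)))
  expect_equal(unname(tm["positive_negative_asymmetry", ]), rep(0, 4))
  rare <- c("rewarded_rare", "unrewarded_rare")
  expect_equal(tm["model_based_shift", rare],
               -tm["model_free_shift", rare])
  expect_true(template_sign_match(c(0.001, -0.05, -0.002, 0.051),
                                  "model_based_shift"))
  expect_false(template_sign_match(c(0.001, 0.05, -0.002, -0.049),
                                   "model_based_shift"))
  expect_true(template_sign_match(c(1e-4, -1e-4, 2e-4, -2e-4),
                                  "positive_negative_asymmetry"))
})
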