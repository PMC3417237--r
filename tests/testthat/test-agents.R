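test_that("model-based first-stage values follow the forward-evaluation rule", {
  q2 <- rbind(c(1, 0), c(0, 0))
  expect_equal(mb_first_stage_values(q2, 0.7), c(0.7, 0.3))
  expect_equal(mb_first_stage_values(matrix(0, 2, 2), 0.7), c(0, 0))
  # uninformative transitions make both actions equivalent
  withr::with_seed(9, for (i in 1:20) {
    q2r <- matrix(rnorm(4), 2, 2)
    v <- mb_first_stage_values(q2r, 0.5)
    expect_equal(v[1], v[2])
  })
  # swapped mapping swaps the values
  expect_equal(mb_first_stage_values(q2, 0.7, mapping = c(1L, 0L)),
               c(0.3, 0.7))
})

test_that("value mixing respects the boundary and midpoint weights", {
  q_mb <- c(1, 0); q_mf <- c(0, 1)
  expect_identical(combine_values(q_mb, q_mf, 1), q_mb)
  expect_identical(combine_values(q_mb, q_mf, 0), q_mf)
  expect_equal(combine_values(q_mb, q_mf, 0.5), c(0.5, 0.5))
  expect_error(combine_values(q_mb, q_mf, 1.2), "omega")
})

test_that("first-stage softmax with perseveration behaves as specified", {
  expect_equal(choice_probs_stage1(c(2, -1), beta = 0, pi = 0, NA),
               c(0.5, 0.5))
  p <- choice_probs_stage1(c(0.4, 0.4), beta = 3, pi = 0.8, prev_choice1 = 1L)
  expect_gt(p[2], 0.5)
  expect_equal(choice_probs_stage1(c(1, 0), beta = 5, pi = 0, NA)[1],
               stats::plogis(5))
  expect_error(choice_probs_stage1(c(NaN, 0), 1, 0, NA), "non-finite")
})

test_that("second-stage softmax is plain and monotone in beta", {
  expect_equal(choice_probs_stage2(c(0.9, 0.1), beta = 0), c(0.5, 0.5))
  expect_equal(choice_probs_stage2(c(1, 0), beta = 2)[1], stats::plogis(2))
  probs <- vapply(c(0.5, 1, 2, 4, 8), function(b)
    choice_probs_stage2(c(0.8, 0.2), b)[1], numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("choice probabilities are valid distributions across the parameter space", {
  withr::with_seed(14, for (i in 1:50) {
    net <- rnorm(2, sd = 2)
    p1 <- choice_probs_stage1(net, beta = runif(1, 0, 20),
                              pi = runif(1, 0, 5),
                              prev_choice1 = sample(c(NA, 0L, 1L), 1))
    p2 <- choice_probs_stage2(rnorm(2), beta = runif(1, 0, 20))
    for (p in list(p1, p2)) {
      expect_equal(sum(p), 1)
      expect_true(all(p >= 0 & p <= 1))
    }
  })
})

test_that("the SARSA-style update matches hand calculations", {
  st <- twostepRL:::agent_init("hybrid")
  trial <- list(choice1 = 0L, state2 = 1L, choice2 = 1L, reward = 1L)

  same <- mf_update(st, trial, alpha = 0, lambda_trace = 1)
  expect_identical(same$q1_mf, st$q1_mf)
  expect_identical(same$q2, st$q2)
  expect_identical(same$prev_choice1, 0L)

  up <- mf_update(st, trial, alpha = 1, lambda_trace = 1)
  expect_equal(up$q2[2, 2], 1)
  expect_equal(up$q1_mf[1], 1)
  expect_equal(up$q1_mf[2], 0)      # unchosen untouched
  expect_equal(up$q2[1, 1], 0)

  st2 <- st
  st2$q2[2, 2] <- 0.4
  up2 <- mf_update(st2, trial, alpha = 0.5, lambda_trace = 0)
  expect_equal(up2$q2[2, 2], 0.7)
})

test_that("dual-rate updating selects the rate by error sign", {
  st <- twostepRL:::agent_init("hybrid")
  trial <- list(choice1 = 0L, state2 = 0L, choice2 = 0L, reward = 1L)

  # equal rates are bitwise identical to the single-rate rule
  withr::with_seed(3, {
    cur_a <- st; cur_b <- st
    for (i in 1:30) {
      tr <- list(choice1 = sample(0:1, 1), state2 = sample(0:1, 1),
                 choice2 = sample(0:1, 1), reward = sample(0:1, 1))
      a <- runif(1)
      cur_a <- mf_update(cur_a, tr, a, 1)
      cur_b <- dual_rate_update(cur_b, tr, a, a, 1)
    }
    expect_identical(cur_a, cur_b)
  })

  # reward from all-zero values: both errors positive, only alpha_pos acts
  up <- dual_rate_update(st, trial, alpha_pos = 0.5, alpha_neg = 0, 1)
  up_ref <- mf_update(st, trial, alpha = 0.5, 1)
  expect_identical(up, up_ref)

  # zero negative rate freezes values on omission
  st_pos <- st; st_pos$q2[1, 1] <- 0.6
  om <- list(choice1 = 0L, state2 = 0L, choice2 = 0L, reward = 0L)
  up0 <- dual_rate_update(st_pos, om, alpha_pos = 0.9, alpha_neg = 0, 1)
  expect_equal(up0$q2[1, 1], 0.6)
})

test_that("separate-values updating couples and decouples the two tables", {
  st <- twostepRL:::agent_init("separate_values")
  withr::with_seed(4, {
    cur <- st
    for (i in 1:40) {
      tr <- list(choice1 = sample(0:1, 1), state2 = sample(0:1, 1),
                 choice2 = sample(0:1, 1), reward = sample(0:1, 1))
      cur <- separate_values_update(cur, tr, alpha_mf = 0.3, alpha_mb = 0.3, 1)
    }
    expect_equal(cur$q2, cur$q2_mb)
  })
  tr <- list(choice1 = 0L, state2 = 1L, choice2 = 0L, reward = 1L)
  ow <- separate_values_update(st, tr, alpha_mf = 0.2, alpha_mb = 1, 1)
  expect_equal(ow$q2_mb[2, 1], 1)   # full overwrite with the last reward
  fz <- separate_values_update(st, tr, alpha_mf = 0.2, alpha_mb = 0, 1)
  expect_equal(fz$q2_mb, st$q2_mb)  # frozen at initial values
})

test_that("actor-critic updating separates values and policies", {
  st <- twostepRL:::agent_init("actor_critic")
  tr <- list(choice1 = 0L, state2 = 1L, choice2 = 0L, reward = 1L)

  frozen <- actor_critic_update(st, tr, alpha = 0.5, eta = 0)
  expect_identical(frozen$prefs1, st$prefs1)
  expect_identical(frozen$prefs2, st$prefs2)

  up <- actor_critic_update(st, tr, alpha = 1, eta = 0.3)
  expect_equal(up$v[3], 1)          # v[state2 = 1] jumps to the reward

  # repeated reward of one second-stage action accumulates preference
  cur <- st
  prefs <- numeric(10)
  for (i in 1:10) {
    cur <- actor_critic_update(cur, tr, alpha = 0.3, eta = 0.3)
    prefs[i] <- cur$prefs2[2, 1]
  }
  expect_true(all(diff(prefs) > 0))
})
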