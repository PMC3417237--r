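test_that("reward walks respect the zero-increment, dimension and bound contracts", {
  init <- c(0.3, 0.4, 0.5, 0.6)
  cfg0 <- task_config(walk_sd = 0, init_reward_probs = init)
  m0 <- generate_reward_walks(cfg0, seed = 1)
  expect_true(all(apply(m0, 1, function(r) identical(r, init))))

  cfg <- task_config()
  m <- generate_reward_walks(cfg, seed = 7)
  expect_equal(dim(m), c(201L, 4L))
  expect_true(all(m >= cfg$walk_bounds[1] & m <= cfg$walk_bounds[2]))

  expect_identical(m, generate_reward_walks(cfg, seed = 7))
  expect_false(identical(m, generate_reward_walks(cfg, seed = 8)))

  # reflection keeps even very volatile walks inside the bounds
  wild <- generate_reward_walks(task_config(walk_sd = 0.2), seed = 3)
  expect_true(all(wild >= 0.2 & wild <= 0.8))

  expect_error(task_config(walk_bounds = c(0.8, 0.2)), "lo < hi")
})

test_that("walk increments away from the boundaries are Gaussian", {
  cfg <- task_config(n_trials = 3000L)
  m <- generate_reward_walks(cfg, seed = 11)
  inc <- diff(m[, 1])
  interior <- m[-nrow(m), 1] > 0.3 & m[-nrow(m), 1] < 0.7 &
    m[-1, 1] > 0.3 & m[-1, 1] < 0.7
  ks <- stats::ks.test(inc[interior], "pnorm", 0, cfg$walk_sd)
  expect_gt(ks$p.value, 0.01)
})

test_that("transition sampling honours the common-transition probability", {
  cfg1 <- task_config(common_prob = 1)
  tr <- withr::with_seed(1, sample_transition(rep(0L, 50), cfg1))
  expect_true(all(tr$state2 == 0L))
  expect_true(all(tr$transition == "common"))

  tr <- withr::with_seed(2, sample_transition(rep(1L, 10000), task_config()))
  expect_equal(mean(tr$transition == "common"), 0.7, tolerance = 0.015)
  expect_true(all((tr$transition == "common") == (tr$state2 == 1L)))

  cfg5 <- task_config(common_prob = 0.5)
  tr5 <- withr::with_seed(3, sample_transition(rep(0L, 10000), cfg5))
  expect_equal(mean(tr5$transition == "common"), 0.5, tolerance = 0.02)

  expect_error(sample_transition(2L), "0 and 1")
})

test_that("simulated sessions have consistent structure", {
  s <- tiny_session(seed = 5, n_trials = 201)
  expect_s3_class(s, "twostep_session")
  expect_equal(nrow(s), 201L)
  expect_identical(s$trial, 1:201)
  # transition label and reached state must agree on every trial
  mapped <- task_config()$mapping[s$choice1 + 1L]
  expect_identical(s$transition == "common", s$state2 == mapped)
})

test_that("a zero-temperature agent chooses uniformly", {
  p0 <- agent_params(alpha = 0.45, beta = 0, pi = 0, omega = 0.5)
  s <- run_session(p0, task_config(n_trials = 10000L), seed = 21)
  expect_equal(mean(s$choice1), 0.5, tolerance = 0.02)
  expect_equal(mean(s$choice2), 0.5, tolerance = 0.02)
})

test_that("an accurate model-based agent outearns a random agent", {
  greedy <- agent_params(alpha = 0.6, beta = 8, pi = 0, omega = 1)
  random <- agent_params(alpha = 0.6, beta = 0, pi = 0, omega = 1)
  cfg <- task_config()
  diffs <- vapply(1:100, function(i) {
    # same seed -> identical reward walks for both agents
    sum(run_session(greedy, cfg, seed = 1000 + i)$reward) -
      sum(run_session(random, cfg, seed = 1000 + i)$reward)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(stats::t.test(diffs)$statistic, 2)
})

test_that("malformed sessions are rejected with a diagnostic", {
  s <- as.data.frame(tiny_session(seed = 1, n_trials = 20))
  gap <- s[-5, ]
  expect_error(session_nll(agent_params(placebo_medians), gap), "no gaps")
  bad <- s
  bad$choice1[3] <- 2L
  expect_error(session_nll(agent_params(placebo_medians), bad), "choice1")
})
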