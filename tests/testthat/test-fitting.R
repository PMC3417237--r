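test_that("subject-level MLE is deterministic, optimal and recovers long sessions", {
  sess <- tiny_session(seed = 77, n_trials = 201)
  f1 <- fit_subject_mle(sess, n_restarts = 5, seed = 10)
  f2 <- fit_subject_mle(sess, n_restarts = 5, seed = 10)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$nll, f2$nll)

  gen <- agent_params(placebo_medians)
  expect_lte(f1$nll, session_nll(gen, sess) + 1e-6)

  long <- run_session(gen, task_config(n_trials = 5000L), seed = 99)
  fl <- fit_subject_mle(long, n_restarts = 5, seed = 2)
  expect_lt(abs(fl$natural[["omega"]] - 0.58), 0.1)
  expect_true(fl$converged)
})

test_that("a flat prior reproduces the maximum-likelihood estimates", {
  sess <- tiny_session(seed = 55, n_trials = 150)
  mle <- fit_subject_mle(sess, n_restarts = 6, seed = 4)
  flat <- list(mean = mle$theta * 0, sd = mle$theta * 0 + 1e6)
  map <- twostepRL:::fit_subject_map(sess, flat, start_theta = mle$theta,
                                     map_restarts = 2, seed = 4)
  expect_equal(map$nll, mle$nll, tolerance = 1e-4)
  expect_equal(map$theta, mle$theta, tolerance = 0.05)
})

test_that("hierarchical MAP estimates shrink toward the prior mean and cut recovery error", {
  cc <- cohort_config(n_subjects = 12,
                      condition_means = list(placebo = placebo_medians),
                      seed = 3)
  coh <- generate_cohort(cc)
  fit <- fit_twostep(coh, seed = 9)
  tn <- c("a", "b", "p", "w")
  mle <- as.matrix(fit$mle_estimates[, tn])
  map <- as.matrix(fit$estimates[, tn])
  mu <- matrix(fit$prior$mean[tn], nrow(mle), 4, byrow = TRUE)

  # MAP coordinates lie between the MLE and the prior mean for the large
  # majority of subject x parameter combinations (the likelihood is not
  # globally concave, so occasional exceptions are expected)
  between <- map >= pmin(mle, mu) - 1e-6 & map <= pmax(mle, mu) + 1e-6
  expect_gte(mean(between), 0.8)
  # ... and are never farther from the prior mean than the MLE, on average
  expect_lte(mean(abs(map - mu)), mean(abs(mle - mu)))

  truth_w <- stats::qlogis(coh$truth$omega)
  rmse <- function(x) sqrt(mean((x - truth_w)^2))
  expect_lte(rmse(map[, "w"]), rmse(mle[, "w"]))
})

test_that("paired condition tests handle regular and degenerate input", {
  x <- c(0.2, 0.5, 0.9, 0.4, 0.6)
  expect_warning(r0 <- paired_condition_test(x, x), "zero variance")
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  expect_warning(ri <- paired_condition_test(c(0, 0, 0, 0), c(1, 1, 1, 1)),
                 "infinite")
  expect_identical(ri$t, Inf); expect_equal(ri$p, 0)

  # closed-form oracle on a fixed vector pair
  a <- c(12.1, 9.8, 11.5, 10.2, 13.0, 8.9)
  b <- c(13.4, 10.1, 12.9, 10.0, 14.2, 9.7)
  d <- b - a
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * stats::pt(-abs(t_manual), length(d) - 1)
  r <- paired_condition_test(a, b)
  expect_equal(r$t, t_manual, tolerance = 1e-12)
  expect_equal(r$p, p_manual, tolerance = 1e-12)
  expect_equal(r$df, 5)
})

test_that("parameter correlation matrices are symmetric with sound nulls", {
  withr::with_seed(20, {
    est <- matrix(rnorm(4000), ncol = 4,
                  dimnames = list(NULL, c("a", "b", "p", "w")))
    pc <- param_correlations(est)
    expect_true(all(abs(pc$r[upper.tri(pc$r)]) < 0.1))
    expect_identical(pc$r, t(pc$r))
    expect_equal(unname(diag(pc$r)), rep(1, 4))
  })
  dup <- cbind(a = rnorm(30))
  dup <- cbind(dup, a2 = dup[, 1], c = rnorm(30))
  pc2 <- param_correlations(dup)
  expect_equal(pc2$r["a", "a2"], 1)
  cst <- cbind(a = rnorm(10), k = rep(2, 10))
  expect_warning(pc3 <- param_correlations(cst), "constant")
  expect_true(is.na(pc3$r["a", "k"]))
})

test_that("model comparison respects nesting and recovers the generating model", {
  cc <- cohort_config(n_subjects = 4,
                      condition_means = list(placebo = placebo_medians),
                      seed = 17)
  coh <- generate_cohort(cc)
  cmp <- compare_models(coh,
                        models = list(hybrid = list(variant = "hybrid"),
                                      mf_only = list(variant = "hybrid",
                                                     fixed = c(omega = 0)),
                                      no_persev = list(variant = "hybrid",
                                                       fixed = c(pi = 0))),
                        n_restarts = 5, seed = 2)
  expect_s3_class(cmp, "twostep_model_comparison")
  # a nested reduction can never beat its parent in raw likelihood
  nll <- stats::setNames(cmp$total_nll, cmp$model)
  expect_lte(nll[["hybrid"]], nll[["mf_only"]] + 1e-4)
  expect_lte(nll[["hybrid"]], nll[["no_persev"]] + 1e-4)
  expect_equal(sum(cmp$best), 1L)

  # data simulated from the hybrid model select it over the pure
  # model-free reduction in the large majority of seeded cohorts
  wins <- 0L
  for (r in 1:20) {
    coh_r <- generate_cohort(cohort_config(
      n_subjects = 4, condition_means = list(placebo = placebo_medians),
      seed = 300 + r))
    cmp_r <- compare_models(coh_r,
                            models = list(hybrid = list(variant = "hybrid"),
                                          mf_only = list(variant = "hybrid",
                                                         fixed = c(omega = 0))),
                            n_restarts = 5, seed = r)
    if (cmp_r$model[cmp_r$best] == "hybrid") wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("the BIC penalty rejects a superfluous parameter in most cohorts", {
  wins <- 0L
  for (r in 1:6) {
    coh_r <- generate_cohort(cohort_config(
      n_subjects = 4, condition_means = list(placebo = placebo_medians),
      seed = 800 + r))
    cmp_r <- compare_models(coh_r,
                            models = list(hybrid = list(variant = "hybrid"),
                                          dual = list(variant = "dual_rate")),
                            n_restarts = 5, seed = r)
    if (cmp_r$model[cmp_r$best] == "hybrid") wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
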