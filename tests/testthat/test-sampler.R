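# MCMC sampler, convergence diagnostics, posterior predictives

test_that("R-hat matches the between/within variance formula", {
  # two chains with means 0 and 10, SD 1
  set.seed(31)
  n <- 2000
  x <- cbind(rnorm(n, 0), rnorm(n, 10))
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  expect_equal(rhat(x), sqrt((n - 1) / n + B_over_n / W), tolerance = 1e-12)
  expect_gt(rhat(x), 5)

  # chains from the same distribution -> ~1
  y <- cbind(rnorm(n), rnorm(n), rnorm(n))
  expect_lt(abs(rhat(y) - 1), 0.01)

  # degenerate constant chains
  expect_warning(r0 <- rhat(cbind(rep(1, 10), rep(1, 10))), "zero")
  expect_equal(r0, 1)
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_no_error(rhat(matrix(rnorm(10), ncol = 1), split = TRUE))
})

test_that("sampling is reproducible given the seed", {
  st <- small_study(seed = 8, P = 4, blocks = 1, tpb = 20)
  m <- build_model("M1_start", st$data)
  f1 <- sample_posterior(m, n_chains = 1, n_iter = 60, burn_in = 30,
                         seed = 2)
  f2 <- sample_posterior(m, n_chains = 1, n_iter = 60, burn_in = 30,
                         seed = 2)
  expect_identical(f1$group, f2$group)
  expect_identical(f1$participant, f2$participant)
})

test_that("prior-only sampling recovers the prior means of group locations", {
  st <- small_study(seed = 9, P = 4, blocks = 1, tpb = 10)
  m <- build_model("M1_start", st$data)
  fit <- sample_posterior(m, n_chains = 2, n_iter = 4000, burn_in = 1000,
                          seed = 3, prior_only = TRUE)
  # prior means of the truncated-normal hyperpriors by direct quadrature
  tn_mean <- function(mu, sd, lo, hi)
    integrate(function(x) x * cueddm:::dtnorm(x, mu, sd, lo, hi),
              lo, hi)$value
  expect_equal(mean(fit$group[, "mu_tau"]), tn_mean(0.3, 0.25, 0.05, 1),
               tolerance = 0.03)
  expect_equal(mean(fit$group[, "mu_alpha"]), tn_mean(1.5, 1, 0.1, 5),
               tolerance = 0.1)
  # theta prior is symmetric: posterior mass balances around zero
  expect_lt(abs(mean(fit$group[, "theta_beta"] > 0) - 0.5), 0.1)
})

test_that("with all-neutral data the starting-point effect stays at its prior", {
  cfg <- synth_config(n_participants = 8, n_blocks = 2, trials_per_block = 30,
                      p_neutral = 1, censor_misses = FALSE, seed = 12)
  st <- generate_study(cfg)
  m <- build_model("M1_start", st$data)
  fit <- sample_posterior(m, n_chains = 1, n_iter = 2500, burn_in = 1000,
                          seed = 4)
  # no cue conditions -> theta cannot be updated by the data; its posterior
  # mass stays balanced like the symmetric Cauchy prior
  expect_lt(abs(mean(fit$group[, "theta_beta"] > 0) - 0.5), 0.12)
})

test_that("the invalid-condition starting point mirrors beta2 exactly", {
  st <- small_study(seed = 10, P = 3, blocks = 1, tpb = 30)
  fit <- quick_fit(st$data, n_iter = 80, burn_in = 40)
  expect_equal(beta_invalid(fit), 1 - fit$participant$beta2)
  expect_true(all(fit$participant$beta2 > 0 & fit$participant$beta2 < 1))
})

test_that("posterior predictive is deterministic and calibrated shape-wise", {
  st <- small_study(seed = 11, P = 6, blocks = 2, tpb = 30)
  fit <- quick_fit(st$data, n_iter = 400, burn_in = 200)
  p1 <- posterior_predict(fit, st$data, n_rep = 1, seed = 6)
  p2 <- posterior_predict(fit, st$data, n_rep = 1, seed = 6)
  expect_identical(p1$table, p2$table)
  expect_equal(sort(unique(p1$table$stat)),
               sort(c("accuracy", "rt_q10", "rt_q30", "rt_q50", "rt_q70",
                      "rt_q90")))
  # self-generated data: most observed cells inside the 95% bands
  p <- posterior_predict(fit, st$data, n_rep = 60, seed = 7)
  tab <- p$table[!is.na(p$table$observed), ]
  inside <- mean(tab$observed >= tab$pred_lower &
                   tab$observed <= tab$pred_upper)
  expect_gte(inside, 0.8)
})

test_that("gelman_rubin reports near-1 values for a converged short fit", {
  st <- small_study(seed = 14, P = 8, blocks = 5, tpb = 40)
  fit <- quick_fit(st$data, n_chains = 2, n_iter = 1600, burn_in = 800)
  rh <- gelman_rubin(fit)
  expect_equal(names(rh), fit$model$group_names)
  expect_true(all(is.finite(rh)))
  expect_lt(max(rh), 1.2)
  rh_all <- gelman_rubin(fit, "all")
  expect_gt(length(rh_all), length(rh))
})
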