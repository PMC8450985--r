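# plausible-values machinery and the analytic correlation posterior

# independent oracle: Fisher's integral representation of the sampling
# density of r given rho, integrated numerically
dr_oracle <- function(r, rho, n) {
  pre <- (n - 2) * (1 - rho^2)^((n - 1) / 2) * (1 - r^2)^((n - 4) / 2) / pi
  int <- integrate(function(u) (cosh(u) - rho * r)^-(n - 1), 0, Inf,
                   rel.tol = 1e-12)$value
  pre * int
}

test_that("analytic rho-posterior matches the integral-representation oracle", {
  post <- cor_posterior(0.3, 50)
  h <- post$rho[2] - post$rho[1]
  oracle <- vapply(post$rho, function(rh) dr_oracle(0.3, rh, 50), numeric(1))
  oracle <- oracle / sum(oracle * h)
  expect_lt(max(abs(post$density - oracle)), 1e-4)
  expect_equal(sum(post$density * h), 1, tolerance = 1e-6)
})

test_that("r = 0 gives a symmetric posterior with Bayesian p exactly 1/2", {
  post <- cor_posterior(0, 50)
  expect_equal(post$p_above, 0.5, tolerance = 1e-12)
  expect_equal(post$bayes_p, 0.5, tolerance = 1e-12)
  expect_equal(post$density, rev(post$density), tolerance = 1e-12)
})

test_that("large-n posterior approaches the Fisher-z approximation", {
  post <- cor_posterior(0.2, 1e4)
  h <- post$rho[2] - post$rho[1]
  expect_lt(abs(post$rho[which.max(post$density)] - 0.2), 0.005)
  sd_post <- sqrt(sum(post$rho^2 * post$density * h) - post$mean^2)
  expect_lt(abs(sd_post - (1 - 0.2^2) / sqrt(1e4)) / sd_post, 0.1)
})

test_that("degenerate and invalid inputs error", {
  expect_error(cor_posterior(1, 50), "degenerate")
  expect_error(cor_posterior(0.2, 3), "at least 4")
})

test_that("averaging identical singles is idempotent; mirrors are symmetric", {
  single <- cor_posterior(0.25, 40)
  avg <- average_posteriors(rep(0.25, 5), n = 40)
  expect_equal(avg$density, single$density, tolerance = 1e-10)
  expect_equal(avg$ci, single$ci, tolerance = 1e-10)

  mirror <- average_posteriors(c(0.3, -0.3), n = 40)
  expect_equal(mirror$bayes_p, 0.5, tolerance = 1e-10)
  expect_equal(mirror$density, rev(mirror$density), tolerance = 1e-10)
  expect_error(average_posteriors(numeric(0), n = 40), "no plausible")
})

test_that("averaged posterior is at least as wide as the mean-r posterior", {
  r <- c(-0.1, 0.05, 0.2, 0.35, 0.3, -0.05)
  avg <- average_posteriors(r, n = 60)
  point <- cor_posterior(mean(r), 60)
  expect_gte(diff(avg$ci) + 1e-10, diff(point$ci))
})

test_that("Bayesian p is stable under grid refinement", {
  p1 <- average_posteriors(c(0.1, 0.3), n = 50, n_grid = 2001)$bayes_p
  p2 <- average_posteriors(c(0.1, 0.3), n = 50, n_grid = 5001)$bayes_p
  expect_lt(abs(p1 - p2), 1e-3)
})

fake_fit <- function(mat_beta2, trait, chains = 1) {
  P <- ncol(mat_beta2)
  pts <- sprintf("P%03d", seq_len(P))
  structure(list(
    group = matrix(0, nrow(mat_beta2), 1, dimnames = list(NULL, "mu_delta")),
    participant = list(beta2 = mat_beta2,
                       alpha = mat_beta2 * 0 + rep(seq_len(P), each =
                                                     nrow(mat_beta2))),
    chain = rep(seq_len(chains), length.out = nrow(mat_beta2)),
    model = list(spec = "M1_start",
                 data = list(P = P, participants = pts),
                 covariates = data.frame(participant = pts, aq = trait)),
    n_chains = chains), class = "ddm_fit")
}

test_that("plausible correlations: perfect, null and dropped-draw cases", {
  P <- 12
  trait <- seq_len(P)
  # every draw's beta2 vector is an affine image of the trait -> r = 1
  mat <- matrix(rep(0.4 + 0.01 * trait, each = 50), 50, P, byrow = FALSE)
  fit <- fake_fit(mat, trait)
  pc <- plausible_correlations(fit, "delta_beta", n_draws = 50)
  expect_true(all(abs(pc$r - 1) < 1e-12))

  # independent posterior and permuted trait: mean r near 0
  set.seed(15)
  mat2 <- matrix(runif(400 * P, 0.3, 0.7), 400, P)
  fit2 <- fake_fit(mat2, sample(trait))
  pc2 <- plausible_correlations(fit2, "delta_beta", n_draws = 400)
  expect_lt(abs(mean(pc2$r)), 3 / sqrt(P))

  # zero-variance draws are dropped and counted
  mat3 <- mat2
  mat3[1:5, ] <- 0.5
  pc3 <- plausible_correlations(fake_fit(mat3, trait), "delta_beta",
                                n_draws = 400)
  expect_equal(pc3$n_dropped, 5)
  expect_equal(length(pc3$r), 395)
})

test_that("correlate_trait recovers a generator-linked correlation", {
  # strong linkage, low posterior noise: posterior draws tightly around truth
  set.seed(16)
  P <- 100
  truth <- rnorm(P, 0.55, 0.05)
  trait <- round(pmin(50, pmax(0, 17 + 6.77 * scale(truth)[, 1] * 0.98 +
                                 rnorm(P, 0, 6.77 * sqrt(1 - 0.98^2)))))
  draws <- matrix(rep(truth, each = 300), 300, P) +
    matrix(rnorm(300 * P, 0, 0.005), 300, P)
  fit <- fake_fit(draws, trait)
  tc <- correlate_trait(fit, "delta_beta", n_draws = 300)
  expect_gt(mean(tc$plausible$r), 0.8)
  expect_lt(tc$posterior$bayes_p, 0.05)
  expect_gt(tc$posterior$ci[1], 0)
})
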