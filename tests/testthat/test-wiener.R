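# Wiener first-passage-time kernel

# independent R implementations of the two series representations, fixed at
# 60 terms each, used to validate the C-level automatic switching
fpt_small_time <- function(t, w, K = 60) {
  k <- -K:K
  sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * t))) / sqrt(2 * pi * t^3)
}
fpt_large_time <- function(t, w, K = 60) {
  k <- 1:K
  pi * sum(k * exp(-k^2 * pi^2 * t / 2) * sin(k * pi * w))
}
dwiener_ref <- function(t, delta, alpha, tau, w, boundary, series) {
  u <- t - tau
  if (boundary == "upper") { delta <- -delta; w <- 1 - w }
  ts <- u / alpha^2
  f <- if (series == "small") fpt_small_time(ts, w) else fpt_large_time(ts, w)
  exp(-delta * alpha * w - delta^2 * u / 2) / alpha^2 * f
}

test_that("density matches both series representations in a central window", {
  grid <- expand.grid(delta = c(-1, 0.5, 2), alpha = c(0.8, 1.5, 3),
                      w = c(0.3, 0.5, 0.7))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (t in c(0.4, 0.8, 1.5)) {
      d <- dwiener(t, g$delta, g$alpha, 0.2, g$w, "upper")
      expect_equal(d, dwiener_ref(t, g$delta, g$alpha, 0.2, g$w, "upper",
                                  "small"), tolerance = 1e-8)
      expect_equal(d, dwiener_ref(t, g$delta, g$alpha, 0.2, g$w, "upper",
                                  "large"), tolerance = 1e-8)
    }
  }
})

test_that("density is zero at and before the non-decision time", {
  expect_equal(dwiener(0.3, 1, 2, 0.3, 0.5), 0)
  expect_equal(dwiener(0.1, 1, 2, 0.3, 0.5), 0)
  expect_equal(dwiener(0.1, 1, 2, 0.3, 0.5, log = TRUE), -Inf)
})

test_that("total absorption probability over both boundaries is 1", {
  for (p in list(c(1, 2, 0.3, 0.5), c(-0.8, 1.2, 0.2, 0.35),
                 c(2.5, 0.9, 0.4, 0.7))) {
    mass <- integrate(function(t)
      dwiener(t, p[1], p[2], p[3], p[4], "upper") +
        dwiener(t, p[1], p[2], p[3], p[4], "lower"),
      p[3], 80, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("upper/lower boundary symmetry holds on a grid", {
  t <- seq(0.35, 4, length.out = 40)
  expect_equal(dwiener(t, 1.2, 1.5, 0.3, 0.35, "upper"),
               dwiener(t, -1.2, 1.5, 0.3, 0.65, "lower"), tolerance = 1e-12)
})

test_that("non-finite parameters are rejected", {
  expect_error(dwiener(0.5, NaN, 2, 0.3, 0.5), "finite")
  expect_error(dwiener(0.5, 1, -1, 0.3, 0.5), "boundary separation")
  expect_error(dwiener(0.5, 1, 2, 0.3, 1.2), "starting point")
})

test_that("choice probability has the closed form and its limits", {
  expect_equal(choice_probability(0, 2, 0.5), 0.5)
  expect_equal(choice_probability(0, 2, 0.3), 0.3)
  expect_equal(choice_probability(1, 2, 0.5),
               (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  # monotone in w and in delta
  w <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(choice_probability(0.7, 1.5, w)) > 0))
  d <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(choice_probability(d, 1.5, 0.4)) > 0))
})

test_that("log-likelihood sums densities with accuracy coding", {
  expect_equal(wiener_loglik(0.8, TRUE, 1.5, 1.2, 0.25, 0.6),
               dwiener(0.8, 1.5, 1.2, 0.25, 0.6, "upper", log = TRUE))
  expect_equal(wiener_loglik(0.8, FALSE, 1.5, 1.2, 0.25, 0.6),
               dwiener(0.8, 1.5, 1.2, 0.25, 0.6, "lower", log = TRUE))
  expect_equal(wiener_loglik(numeric(0), logical(0), 1, 2, 0.3, 0.5), 0)
  expect_equal(wiener_loglik(c(0.8, 0.2), c(TRUE, TRUE), 1, 2, 0.3, 0.5),
               -Inf)
})

test_that("likelihood concentrates at the generating parameters", {
  set.seed(71)
  wins <- 0
  for (rep in 1:40) {
    x <- rwiener(100, 1.2, 1.5, 0.3, 0.55)
    ll_true <- wiener_loglik(x$rt, x$correct, 1.2, 1.5, 0.3, 0.55)
    ll_pert <- wiener_loglik(x$rt, x$correct, 2.2, 1.5, 0.3, 0.55)
    wins <- wins + (ll_true > ll_pert)
  }
  expect_gte(wins / 40, 0.95)
})

test_that("sampler is deterministic, respects support, matches closed forms", {
  set.seed(4)
  a <- rwiener(200, 1, 2, 0.3, 0.5)
  set.seed(4)
  b <- rwiener(200, 1, 2, 0.3, 0.5)
  expect_identical(a, b)
  expect_true(all(a$rt > 0.3))

  set.seed(8)
  x <- rwiener(4e4, 0.8, 1.8, 0.25, 0.4)
  p <- choice_probability(0.8, 1.8, 0.4)
  se <- sqrt(p * (1 - p) / 4e4)
  expect_lt(abs(mean(x$correct) - p), 3 * se)

  # mean decision time against quadrature
  m_quad <- integrate(function(t)
    t * (dwiener(t, 0.8, 1.8, 0.25, 0.4, "upper") +
           dwiener(t, 0.8, 1.8, 0.25, 0.4, "lower")),
    0.25, 80, rel.tol = 1e-10)$value - 0.25
  m_emp <- mean(x$rt) - 0.25
  se_m <- sd(x$rt) / sqrt(4e4)
  expect_lt(abs(m_emp - m_quad), 3 * se_m)
})

test_that("Euler fallback agrees with the closed-form choice probability", {
  set.seed(12)
  y <- rwiener(5000, 1.5, 1.2, 0.25, 0.6, method = "euler")
  expect_true(all(y$rt > 0.25, na.rm = TRUE))
  p <- choice_probability(1.5, 1.2, 0.6)
  expect_lt(abs(mean(y$correct, na.rm = TRUE) - p),
            3 * sqrt(p * (1 - p) / 5000))
  expect_error(rwiener(10, 1, 2, 0.3, 0.5, method = "euler", dt = 1e-3),
               "dt")
})
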