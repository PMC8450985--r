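# Plausible-values correlation analysis.
#
# Each retained posterior draw provides one plausible realisation of the
# participant-level parameter vector; correlating each with the trait score
# gives a distribution of plausible sample correlations r_k. For each r_k the
# exact posterior of the bivariate-normal population correlation rho (under a
# stretched-beta prior) is computed analytically and the densities are
# averaged across draws, propagating both posterior and sampling uncertainty
# into one population-correlation posterior.

# Gauss hypergeometric 2F1(1/2, 1/2; c; x) for 0 <= x < 1, vectorised over x
# (plain power series; c is large in practice so convergence is fast)
.hyp2f1_half <- function(x, c, tol = 1e-12, max_terms = 5000) {
  term <- rep(1, length(x))
  total <- term
  for (k in 0:(max_terms - 1)) {
    term <- term * ((0.5 + k)^2 / ((c + k) * (k + 1))) * x
    total <- total + term
    if (max(term) < tol * max(total)) break
  }
  total
}

# log sampling density of the sample correlation r given population rho and
# sample size n (bivariate normal, means and variances unknown)
.log_dr_given_rho <- function(r, rho, n) {
  log(n - 2) + lgamma(n - 1) - lgamma(n - 0.5) - 0.5 * log(2 * pi) +
    ((n - 1) / 2) * log1p(-rho^2) + ((n - 4) / 2) * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r) +
    log(.hyp2f1_half((1 + rho * r) / 2, n - 0.5))
}

.stretched_beta_logprior <- function(rho, alpha = 1) {
  # Beta(alpha, alpha) stretched to (-1, 1); alpha = 1 is uniform
  (alpha - 1) * log1p(-rho^2) - lbeta(alpha, alpha) - (2 * alpha - 1) * log(2)
}

.rho_grid <- function(n_grid) {
  # open interval: endpoints carry zero density for n >= 4 anyway
  seq(-1, 1, length.out = n_grid + 2)[2:(n_grid + 1)]
}

#' Analytic posterior of a population correlation
#'
#' Exact posterior density of the bivariate-normal population correlation
#' `rho` given an observed sample correlation `r` from `n` pairs, under a
#' stretched-beta prior on (-1, 1) (`prior_alpha = 1`, the default, is
#' uniform). Evaluated on a regular grid and normalised by the trapezoidal
#' rule.
#'
#' @param r sample correlation, |r| < 1.
#' @param n number of pairs (>= 4).
#' @param n_grid number of interior grid points (default 2001).
#' @param prior_alpha stretched-beta shape; 1 = uniform prior.
#' @return object of class `cor_posterior`: list with `rho` (grid), `density`,
#'   `ci` (95% equal-tail), `p_above`, `p_below`, `bayes_p`, `mean`.
#' @export
cor_posterior <- function(r, n, n_grid = 2001, prior_alpha = 1) {
  if (abs(r) >= 1) stop("|r| = 1 is degenerate: population correlation ",
                        "posterior undefined")
  if (n < 4) stop("need at least 4 pairs")
  rho <- .rho_grid(n_grid)
  ld <- .log_dr_given_rho(r, rho, n) + .stretched_beta_logprior(rho,
                                                                prior_alpha)
  .make_cor_posterior(rho, exp(ld - max(ld)))
}

# normalise a density over the rho grid and derive interval summaries
.make_cor_posterior <- function(rho, dens) {
  h <- rho[2] - rho[1]
  wts <- rep(h, length(rho))  # interior grid, trapezoid ~ midpoint here
  Z <- sum(dens * wts)
  dens <- dens / Z
  cdf <- cumsum(dens * wts)
  qfun <- function(p) approx(cdf - dens * wts / 2, rho, xout = p,
                             ties = "ordered", rule = 2)$y
  p_below <- approx(rho, cdf - dens * wts / 2, xout = 0, rule = 2)$y
  p_above <- 1 - p_below
  structure(list(rho = rho, density = dens,
                 ci = c(lower = qfun(0.025), upper = qfun(0.975)),
                 p_above = p_above, p_below = p_below,
                 bayes_p = min(p_above, p_below),
                 mean = sum(rho * dens * wts)),
            class = "cor_posterior")
}

#' @export
print.cor_posterior <- function(x, ...) {
  cat("population-correlation posterior: mean",
      format(x$mean, digits = 3), ", 95% equal-tail CI [",
      format(x$ci[1], digits = 3), ",", format(x$ci[2], digits = 3),
      "], Bayesian p =", format(x$bayes_p, digits = 3), "\n")
  invisible(x)
}

#' Plausible sample correlations from a fitted model
#'
#' Subsamples up to `n_draws` retained posterior draws (without replacement,
#' evenly across chains) and computes the Pearson correlation between the
#' participant-parameter vector of each draw and the trait scores. Draws in
#' which the parameter vector has zero variance are dropped with a count.
#'
#' @param fit a [sample_posterior()] fit.
#' @param parameter `"delta_beta"` (starting-point effect `beta2 - 0.5`),
#'   `"alpha"` (boundary separation) or `"delta_effect"` (valid minus neutral
#'   drift).
#' @param trait named vector of trait scores (names = participant ids), or
#'   `NULL` to use the covariates attached to the model.
#' @param n_draws number of plausible draws (default 3000; capped at the
#'   number of retained draws).
#' @param seed optional RNG seed for the subsample.
#' @return object of class `plausible_cors`: list with `r` (correlations),
#'   `n` (participants), `parameter`, `n_dropped`.
#' @export
plausible_correlations <- function(fit, parameter = c("delta_beta", "alpha",
                                                      "delta_effect"),
                                   trait = NULL, n_draws = 3000,
                                   seed = NULL) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(fit, "ddm_fit"))
  if (!is.null(seed)) set.seed(seed)
  pts <- fit$model$data$participants
  if (is.null(trait)) {
    cv <- fit$model$covariates
    trait <- setNames(cv$aq, cv$participant)
  }
  trait <- trait[pts]
  if (anyNA(trait)) stop("trait scores missing for some participants")
  if (length(pts) < 4) stop("need at least 4 participants")

  mat <- switch(parameter,
                delta_beta = {
                  if (is.null(fit$participant$beta2))
                    stop("model has no starting-point effect")
                  fit$participant$beta2 - 0.5
                },
                alpha = fit$participant$alpha,
                delta_effect = {
                  if (is.null(fit$participant$delta2))
                    stop("model has no condition-specific drift")
                  fit$participant$delta2 - fit$participant$delta1
                })
  N <- nrow(mat)
  n_use <- min(n_draws, N)
  # even subsample across the chain-ordered draws
  ks <- unique(round(seq(1, N, length.out = n_use)))
  sds <- apply(mat[ks, , drop = FALSE], 1, sd)
  ok <- sds > 0
  if (sd(trait) == 0) ok[] <- FALSE
  r <- rep(NA_real_, length(ks))
  r[ok] <- apply(mat[ks[ok], , drop = FALSE], 1, cor, y = trait)
  structure(list(r = r[ok], n = length(pts), parameter = parameter,
                 n_dropped = sum(!ok)), class = "plausible_cors")
}

#' @export
print.plausible_cors <- function(x, ...) {
  cat(length(x$r), "plausible correlations for", x$parameter, "(",
      x$n, "participants ): mean r =", format(mean(x$r), digits = 3), "\n")
  if (x$n_dropped) cat(x$n_dropped, "zero-variance draws dropped\n")
  invisible(x)
}

#' Average analytic posteriors across plausible draws
#'
#' Computes the analytic population-correlation posterior for each plausible
#' sample correlation and averages the densities pointwise (then
#' renormalises). The 95% equal-tail credible interval and the Bayesian
#' p-value -- the smaller of the posterior mass above and below zero -- are
#' taken from the averaged posterior.
#'
#' @param r vector of plausible sample correlations (or a `plausible_cors`
#'   object).
#' @param n number of participants (taken from the object if given).
#' @param n_grid,prior_alpha see [cor_posterior()].
#' @return a `cor_posterior` (averaged).
#' @export
average_posteriors <- function(r, n = NULL, n_grid = 2001, prior_alpha = 1) {
  if (inherits(r, "plausible_cors")) {
    n <- r$n
    r <- r$r
  }
  if (!length(r)) stop("no plausible correlations to average")
  if (is.null(n)) stop("`n` (number of participants) is required")
  rho <- .rho_grid(n_grid)
  lprior <- .stretched_beta_logprior(rho, prior_alpha)
  # vectorised over the grid x draws matrix
  x <- (1 + outer(rho, r)) / 2
  lhyp <- log(.hyp2f1_half(as.vector(x), n - 0.5))
  ld <- log(n - 2) + lgamma(n - 1) - lgamma(n - 0.5) - 0.5 * log(2 * pi) +
    ((n - 1) / 2) * log1p(-rho^2) +
    rep(((n - 4) / 2) * log1p(-r^2), each = length(rho)) -
    (n - 1.5) * log1p(-outer(rho, r)) + lhyp + lprior
  dim(ld) <- c(length(rho), length(r))
  dens <- rowMeans(exp(ld - max(ld)))
  .make_cor_posterior(rho, dens)
}

#' Full plausible-values analysis of a trait correlation
#'
#' Runs [plausible_correlations()] followed by [average_posteriors()] and
#' also reports the naive posterior based on the mean plausible correlation
#' alone (a diagnostic: the averaged posterior is at least as wide).
#'
#' @inheritParams plausible_correlations
#' @inheritParams average_posteriors
#' @return list of class `trait_correlation`: `plausible` (the r draws),
#'   `posterior` (averaged `cor_posterior`), `point_posterior`
#'   (`cor_posterior` at the mean r), `parameter`.
#' @export
correlate_trait <- function(fit, parameter = c("delta_beta", "alpha",
                                               "delta_effect"),
                            trait = NULL, n_draws = 3000, seed = NULL,
                            n_grid = 2001, prior_alpha = 1) {
  pc <- plausible_correlations(fit, parameter, trait, n_draws, seed)
  post <- average_posteriors(pc, n_grid = n_grid, prior_alpha = prior_alpha)
  point <- cor_posterior(mean(pc$r), pc$n, n_grid = n_grid,
                         prior_alpha = prior_alpha)
  structure(list(plausible = pc, posterior = post, point_posterior = point,
                 parameter = pc$parameter), class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat("Plausible-values correlation for", x$parameter, ":\n")
  cat("  mean plausible r:", format(mean(x$plausible$r), digits = 3), "\n")
  print(x$posterior)
  invisible(x)
}

#' Plot a plausible-values analysis
#'
#' Histogram of plausible sample correlations with the averaged
#' population-correlation posterior overlaid.
#'
#' @param x a [correlate_trait()] result.
#' @return a ggplot object.
#' @export
plot_trait_correlation <- function(x) {
  stopifnot(inherits(x, "trait_correlation"))
  df_r <- data.frame(r = x$plausible$r)
  df_p <- data.frame(rho = x$posterior$rho, density = x$posterior$density)
  ggplot2::ggplot() +
    ggplot2::geom_histogram(data = df_r,
                            ggplot2::aes(x = r, y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = df_p, ggplot2::aes(x = rho, y = density),
                       colour = "red") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "correlation", y = "density",
                  title = paste("Plausible correlations and population",
                                "posterior:", x$parameter))
}
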