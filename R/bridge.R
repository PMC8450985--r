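# Marginal likelihood by warp-III bridge sampling.
#
# The posterior draws (in unconstrained space) are split in half: the first
# half fixes the warp (mean vector m and covariance Cholesky factor L), the
# second half enters the bridge identity. Warp-III additionally symmetrises
# skew by mixing the density over sign-flipped residuals,
#   h(z) = 0.5 * [ p(m - L z) + p(m + L z) ] * |L|,
# so the warped posterior is compared against a standard-normal proposal in
# z-space. The optimal-bridge (Meng-Wong) fixed point is iterated on the two
# sets of log ratios until the relative change in the estimate falls below
# `tol`.

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# one bridge estimate from log ratios at posterior draws (l1) and proposal
# draws (l2): returns log r where r solves the Meng-Wong fixed point
.bridge_iterate <- function(l1, l2, tol = 1e-10, max_iter = 20000) {
  n1 <- length(l1)
  n2 <- length(l2)
  s1 <- n1 / (n1 + n2)
  s2 <- n2 / (n1 + n2)
  lstar <- median(l1[is.finite(l1)])
  e1 <- exp(l1 - lstar)
  e2 <- exp(l2 - lstar)
  r <- 1
  logml <- lstar
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    num <- mean(e2 / (s1 * e2 + s2 * r))
    den <- mean(1 / (s1 * e1 + s2 * r))
    r_new <- num / den
    logml_new <- log(r_new) + lstar
    if (is.finite(logml) && abs(logml_new - logml) <=
        tol * abs(logml_new)) {
      logml <- logml_new
      converged <- TRUE
      break
    }
    r <- r_new
    logml <- logml_new
  }
  list(logml = logml, iterations = i, converged = converged)
}

#' Log marginal likelihood by warp-III bridge sampling
#'
#' Estimates the log normalising constant of an unnormalised density from
#' posterior draws. Constrained parameters must already be transformed to
#' unbounded space with Jacobians included in `log_post` (see
#' [log_posterior_fn()]). Each repetition draws a fresh standard-normal
#' proposal sample; the pooled estimate is the median across repetitions.
#'
#' @param samples matrix of posterior draws (iterations x dimensions) in
#'   unconstrained space.
#' @param log_post function taking one unconstrained parameter vector and
#'   returning the unnormalised log posterior density.
#' @param n_proposal proposal draws per repetition; defaults to the number of
#'   posterior draws reserved for the bridge (half of `samples`).
#' @param n_repetitions independent repetitions (default 6).
#' @param max_iter cap on bridge fixed-point iterations.
#' @param tol relative-change convergence tolerance of the fixed point.
#' @param seed optional RNG seed.
#' @param warp3 symmetrise skew (warp-III)? With `FALSE` only mean and
#'   covariance are matched (warp-II).
#' @return object of class `logml_estimate`: list with `logml` (pooled,
#'   median), `repetitions` (per-repetition estimates), `converged` flags and
#'   iteration counts.
#' @export
warp3_logml <- function(samples, log_post, n_proposal = NULL,
                        n_repetitions = 6, max_iter = 20000, tol = 1e-10,
                        seed = NULL, warp3 = TRUE) {
  samples <- as.matrix(samples)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(samples)
  D <- ncol(samples)
  if (N < 2 * D + 2)
    warning("few posterior draws (", N, ") relative to dimension (", D,
            "); the proposal covariance may be unstable")
  i1 <- seq_len(floor(N / 2))
  fit_half <- samples[i1, , drop = FALSE]
  bridge_half <- samples[-i1, , drop = FALSE]
  m <- colMeans(fit_half)
  S <- stats::cov(fit_half)
  L <- tryCatch(t(chol(S)), error = function(e)
    stop("rank-deficient posterior covariance; consider pruning constant ",
         "parameters"))

  n1 <- nrow(bridge_half)
  if (is.null(n_proposal)) n_proposal <- n1

  # log of the warped unnormalised posterior at standardised points z
  log_h <- function(zmat) {
    ldetL <- sum(log(diag(L)))
    apply(zmat, 1, function(z) {
      x1 <- m - as.vector(L %*% z)
      lp1 <- log_post(x1)
      if (warp3) {
        x2 <- m + as.vector(L %*% z)
        lp2 <- log_post(x2)
        .logsumexp2(lp1, lp2) - log(2) + ldetL
      } else {
        lp1 + ldetL
      }
    })
  }
  log_phi <- function(zmat) -0.5 * rowSums(zmat^2) - 0.5 * D * log(2 * pi)

  # z-space coordinates of the posterior bridge half
  z_post <- t(forwardsolve(L, t(sweep(bridge_half, 2, m))))
  if (warp3) {
    # randomise the sign so the mixture representation matches the draws
    flip <- sample(c(-1, 1), n1, replace = TRUE)
    z_post <- z_post * flip
  }
  l1 <- log_h(z_post) - log_phi(z_post)

  reps <- numeric(n_repetitions)
  conv <- logical(n_repetitions)
  iters <- integer(n_repetitions)
  for (j in seq_len(n_repetitions)) {
    z_prop <- matrix(rnorm(n_proposal * D), n_proposal, D)
    l2 <- log_h(z_prop) - log_phi(z_prop)
    b <- .bridge_iterate(l1, l2, tol = tol, max_iter = max_iter)
    reps[j] <- b$logml
    conv[j] <- b$converged
    iters[j] <- b$iterations
  }
  if (!all(conv))
    warning(sum(!conv), " bridge repetition(s) did not reach the fixed-point ",
            "tolerance")
  structure(list(logml = median(reps), repetitions = reps, converged = conv,
                 iterations = iters, n_posterior = n1,
                 n_proposal = n_proposal, dimension = D),
            class = "logml_estimate")
}

#' @export
print.logml_estimate <- function(x, ...) {
  cat("log marginal likelihood:", format(x$logml, digits = 8),
      "(median of", length(x$repetitions), "repetitions, SD",
      format(sd(x$repetitions), digits = 3), ")\n")
  invisible(x)
}

#' Log marginal likelihood of a fitted hierarchical diffusion model
#'
#' Convenience wrapper: transforms the retained draws of a [sample_posterior()]
#' fit to unconstrained space and calls [warp3_logml()] with the model's
#' unnormalised log posterior.
#'
#' @param fit a `ddm_fit`.
#' @param ... passed to [warp3_logml()].
#' @return a `logml_estimate`.
#' @export
model_logml <- function(fit, ...) {
  stopifnot(inherits(fit, "ddm_fit"))
  model <- fit$model
  N <- nrow(fit$group)
  draws <- matrix(NA_real_, N,
                  length(model$group_names) +
                    length(model$participant_names) * model$data$P)
  for (k in seq_len(N)) {
    st <- c(list(group = fit$group[k, ]),
            lapply(fit$participant, function(mat) mat[k, ]))
    draws[k, ] <- state_to_vector(model, st)
  }
  est <- warp3_logml(draws, log_posterior_fn(model), ...)
  est$model <- model$spec
  est$n_trials <- length(model$data$rt)
  est
}

#' Pairwise log Bayes factors
#'
#' Differences of pooled log marginal likelihoods for every model pair. The
#' resulting table is antisymmetric and transitive by construction.
#'
#' @param estimates named list of `logml_estimate` objects fitted to the same
#'   data.
#' @return object of class `bf_table`: list with `logml` (named vector),
#'   `log_bf` (matrix, entry (A, B) = logml(A) - logml(B)) and `preferred`.
#' @export
bayes_factors <- function(estimates) {
  stopifnot(length(estimates) >= 2)
  if (is.null(names(estimates)) || any(names(estimates) == ""))
    names(estimates) <- vapply(estimates, function(e)
      e$model %||% "model", character(1))
  nt <- unique(unlist(lapply(estimates, `[[`, "n_trials")))
  if (length(nt) > 1)
    stop("marginal likelihoods were computed on different datasets")
  lm <- vapply(estimates, `[[`, numeric(1), "logml")
  bf <- outer(lm, lm, `-`)
  structure(list(logml = lm, log_bf = bf,
                 preferred = names(which.max(lm))), class = "bf_table")
}

#' @export
print.bf_table <- function(x, ...) {
  cat("log marginal likelihoods:\n")
  print(x$logml, digits = 8)
  cat("\nlog Bayes factors (row vs column):\n")
  print(x$log_bf, digits = 4)
  cat("\npreferred model:", x$preferred, "\n")
  invisible(x)
}
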