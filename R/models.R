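# Hierarchical condition-effect models.
#
# M1_start: cue condition shifts the starting point. Neutral trials have
#   w = 0.5; valid trials use beta2_p ~ TruncNormal(0.5 + theta*sigma_eps,
#   sigma_eps) on (0.01, 0.99); invalid trials use 1 - beta2_p exactly. Drift
#   is shared across conditions.
# M2_drift: cue condition shifts drift. delta_pc ~ TruncNormal(mu_delta +
#   x_c * theta*sigma_eps, sigma_eps) with x = 0/+1/-1 for
#   neutral/valid/invalid; starting point fixed at 0.5 everywhere.
# M3_both: both effects, with separate (theta, sigma_eps) pairs.
#
# Participant-level truncation bounds: delta (-5, 10), alpha (0.1, 5),
# tau (0.05, 1) s, beta2 (0.01, 0.99).

PARAM_BOUNDS <- list(delta = c(-5, 10), alpha = c(0.1, 5), tau = c(0.05, 1),
                     beta2 = c(0.01, 0.99))

#' Default prior configuration
#'
#' Weakly informative group-level priors on the diffusion-coefficient-1
#' scale: `mu_delta ~ Normal(1.5, 2)` truncated to (-5, 10); `mu_alpha ~
#' Normal(1.5, 1)` truncated to (0.1, 5); `mu_tau ~ Normal(0.3, 0.25)`
#' truncated to (0.05, 1); group SDs half-Normal(0, 1); standardised
#' condition effects `theta ~ Cauchy(0, 1/sqrt(2))`; residual SDs
#' half-Normal(0, 0.5) for the starting point and half-Normal(0, 1) for
#' drift. All entries can be overridden.
#'
#' @param ... named overrides, e.g. `mu_delta = c(1, 3)` (mean, sd).
#' @return named list of prior hyperparameters.
#' @export
default_priors <- function(...) {
  pr <- list(mu_delta = c(1.5, 2), mu_alpha = c(1.5, 1), mu_tau = c(0.3, 0.25),
             sigma_delta = 1, sigma_alpha = 1, sigma_tau = 1,
             theta_scale = 1 / sqrt(2),
             sigma_eps_beta = 0.5, sigma_eps_delta = 1)
  ov <- list(...)
  pr[names(ov)] <- ov
  pr
}

.group_param_names <- function(spec) {
  base <- c("mu_delta", "mu_alpha", "sigma_alpha", "mu_tau", "sigma_tau")
  switch(spec,
         M1_start = c(base, "sigma_delta", "theta_beta", "sigma_eps_beta"),
         M2_drift = c(base, "theta_delta", "sigma_eps_delta"),
         M3_both = c(base, "theta_delta", "sigma_eps_delta",
                     "theta_beta", "sigma_eps_beta"))
}

.participant_param_names <- function(spec) {
  switch(spec,
         M1_start = c("delta", "alpha", "tau", "beta2"),
         M2_drift = c("delta1", "delta2", "delta3", "alpha", "tau"),
         M3_both = c("delta1", "delta2", "delta3", "alpha", "tau", "beta2"))
}

.bounds_of <- function(name) {
  if (grepl("^delta", name)) PARAM_BOUNDS$delta
  else PARAM_BOUNDS[[name]]
}

# log hyperprior of the group-parameter vector
.log_hyperprior <- function(g, spec, pr) {
  lp <- dtnorm(g[["mu_delta"]], pr$mu_delta[1], pr$mu_delta[2], -5, 10,
               log = TRUE) +
    dtnorm(g[["mu_alpha"]], pr$mu_alpha[1], pr$mu_alpha[2], 0.1, 5,
           log = TRUE) +
    dtnorm(g[["mu_tau"]], pr$mu_tau[1], pr$mu_tau[2], 0.05, 1, log = TRUE)
  half_norm <- function(x, s) {
    if (x <= 0) return(-Inf)
    dnorm(x, 0, s, log = TRUE) + log(2)
  }
  lp <- lp + half_norm(g[["sigma_alpha"]], pr$sigma_alpha) +
    half_norm(g[["sigma_tau"]], pr$sigma_tau)
  if (spec == "M1_start")
    lp <- lp + half_norm(g[["sigma_delta"]], pr$sigma_delta)
  if (spec %in% c("M2_drift", "M3_both"))
    lp <- lp + dcauchy(g[["theta_delta"]], 0, pr$theta_scale, log = TRUE) +
      half_norm(g[["sigma_eps_delta"]], pr$sigma_eps_delta)
  if (spec %in% c("M1_start", "M3_both")) {
    lp <- lp + dcauchy(g[["theta_beta"]], 0, pr$theta_scale, log = TRUE) +
      half_norm(g[["sigma_eps_beta"]], pr$sigma_eps_beta)
    m <- 0.5 + g[["theta_beta"]] * g[["sigma_eps_beta"]]
    if (!is.finite(m) || m <= 0 || m >= 1) lp <- -Inf
  }
  lp
}

# participant-level prior means and SDs implied by the group parameters, for
# each participant parameter block
.participant_prior <- function(name, g, spec) {
  switch(name,
         delta = c(g[["mu_delta"]], g[["sigma_delta"]]),
         delta1 = c(g[["mu_delta"]], g[["sigma_eps_delta"]]),
         delta2 = c(g[["mu_delta"]] +
                      g[["theta_delta"]] * g[["sigma_eps_delta"]],
                    g[["sigma_eps_delta"]]),
         delta3 = c(g[["mu_delta"]] -
                      g[["theta_delta"]] * g[["sigma_eps_delta"]],
                    g[["sigma_eps_delta"]]),
         alpha = c(g[["mu_alpha"]], g[["sigma_alpha"]]),
         tau = c(g[["mu_tau"]], g[["sigma_tau"]]),
         beta2 = c(0.5 + g[["theta_beta"]] * g[["sigma_eps_beta"]],
                   g[["sigma_eps_beta"]]))
}

#' Build a hierarchical diffusion model
#'
#' Prepares the data arrays and returns a model object holding the design
#' (which parameter carries the condition effect), the priors, and the joint
#' unnormalised log posterior over group- and participant-level parameters.
#' The log posterior combines the Wiener first-passage likelihood (accuracy
#' coded: upper boundary = correct) with truncated-normal participant priors
#' and the group hyperpriors of [default_priors()].
#'
#' @param spec `"M1_start"`, `"M2_drift"` or `"M3_both"`.
#' @param data a filtered [study_data] object (accuracy coding is applied if
#'   it has not been already).
#' @param priors prior configuration from [default_priors()].
#' @return object of class `ddm_model`.
#' @export
build_model <- function(spec = c("M1_start", "M2_drift", "M3_both"), data,
                        priors = default_priors()) {
  spec <- match.arg(spec)
  stopifnot(inherits(data, "study_data"))
  if (!isTRUE(attr(data, "accuracy_coded"))) data <- accuracy_code(data)
  tr <- data$trials
  if (nrow(tr) == 0L) stop("no trials to fit")
  pts <- sort(unique(tr$participant))
  P <- length(pts)
  pid0 <- match(tr$participant, pts) - 1L
  cond <- as.integer(tr$condition)
  dat <- list(rt = as.numeric(tr$rt),
              correct = as.integer(tr$correct),
              pid0 = pid0, cond = cond,
              cell0 = pid0 + P * (cond - 1L),
              # starting-point sign per trial: 0 neutral, +1 valid, -1 invalid
              wsign = c(0, 1, -1)[cond],
              P = P, participants = pts,
              min_rt = as.numeric(tapply(tr$rt, factor(tr$participant, pts),
                                         min)))
  structure(list(spec = spec, priors = priors, data = dat,
                 group_names = .group_param_names(spec),
                 participant_names = .participant_param_names(spec),
                 covariates = data$covariates),
            class = "ddm_model")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat("ddm_model", x$spec, ":", x$data$P, "participants,",
      length(x$data$rt), "trials\n")
  cat("group parameters:", paste(x$group_names, collapse = ", "), "\n")
  invisible(x)
}

# per-trial parameter vectors implied by a state (list of participant-param
# vectors + named group vector)
.trial_params <- function(model, st) {
  d <- model$data
  i <- d$pid0 + 1L
  v <- if (model$spec == "M1_start") st$delta[i] else
    cbind(st$delta1, st$delta2, st$delta3)[cbind(i, d$cond)]
  w <- if (model$spec == "M2_drift") rep(0.5, length(i)) else
    0.5 + d$wsign * (st$beta2[i] - 0.5)
  list(v = v, a = st$alpha[i], w = w, tau = st$tau[i])
}

# total log-likelihood per participant for a state
.loglik_state <- function(model, st) {
  d <- model$data
  tp <- .trial_params(model, st)
  wiener_loglik_by(d$rt, d$correct, d$pid0, tp$v, tp$a, tp$tau, tp$w, d$P)
}

# joint unnormalised log posterior of a constrained state
.log_posterior_state <- function(model, st) {
  g <- st$group
  lp <- .log_hyperprior(g, model$spec, model$priors)
  if (!is.finite(lp)) return(-Inf)
  for (nm in model$participant_names) {
    pr <- .participant_prior(nm, g, model$spec)
    b <- .bounds_of(nm)
    mass <- pnorm(b[2], pr[1], pr[2]) - pnorm(b[1], pr[1], pr[2])
    if (!is.finite(mass) || mass < 1e-6) return(-Inf)
    lp <- lp + sum(dtnorm(st[[nm]], pr[1], pr[2], b[1], b[2], log = TRUE))
    if (!is.finite(lp)) return(-Inf)
  }
  ll <- sum(.loglik_state(model, st))
  lp + ll
}

# ---- unconstrained parameterisation (for bridge sampling) -----------------

# transform types: "interval" (logit on (lo, hi)), "log" (positives),
# "identity" (standardised effects)
.group_transforms <- function(spec) {
  tt <- list(mu_delta = c("interval", -5, 10), mu_alpha = c("interval", 0.1, 5),
             sigma_alpha = "log", mu_tau = c("interval", 0.05, 1),
             sigma_tau = "log", sigma_delta = "log", theta_beta = "identity",
             sigma_eps_beta = "log", theta_delta = "identity",
             sigma_eps_delta = "log")
  tt[.group_param_names(spec)]
}

.to_unconstrained <- function(x, tr) {
  if (identical(tr, "log")) return(log(x))
  if (identical(tr, "identity")) return(x)
  lo <- as.numeric(tr[2]); hi <- as.numeric(tr[3])
  stats::qlogis((x - lo) / (hi - lo))
}

.from_unconstrained <- function(y, tr) {
  if (identical(tr, "log")) return(exp(y))
  if (identical(tr, "identity")) return(y)
  lo <- as.numeric(tr[2]); hi <- as.numeric(tr[3])
  lo + (hi - lo) * stats::plogis(y)
}

.log_jacobian <- function(y, tr) {
  if (identical(tr, "log")) return(sum(y))
  if (identical(tr, "identity")) return(0)
  lo <- as.numeric(tr[2]); hi <- as.numeric(tr[3])
  p <- stats::plogis(y)
  sum(log(hi - lo) + log(p) + log1p(-p))
}

# flatten a state to an unconstrained vector and back; layout: group params
# in .group_param_names order, then participant blocks, P entries each
state_to_vector <- function(model, st) {
  gt <- .group_transforms(model$spec)
  yg <- vapply(model$group_names,
               function(nm) .to_unconstrained(st$group[[nm]], gt[[nm]]),
               numeric(1))
  yp <- unlist(lapply(model$participant_names, function(nm) {
    b <- .bounds_of(nm)
    .to_unconstrained(st[[nm]], c("interval", b[1], b[2]))
  }))
  unname(c(yg, yp))
}

vector_to_state <- function(model, y) {
  gt <- .group_transforms(model$spec)
  ng <- length(model$group_names)
  g <- setNames(numeric(ng), model$group_names)
  for (k in seq_len(ng))
    g[k] <- .from_unconstrained(y[k], gt[[model$group_names[k]]])
  st <- list(group = g)
  P <- model$data$P
  off <- ng
  for (nm in model$participant_names) {
    b <- .bounds_of(nm)
    st[[nm]] <- unname(.from_unconstrained(y[off + seq_len(P)],
                                           c("interval", b[1], b[2])))
    off <- off + P
  }
  st
}

#' Unnormalised log posterior in unconstrained space
#'
#' Returns a function of a single numeric vector (group parameters followed
#' by participant-parameter blocks, logit/log transformed) evaluating the
#' joint unnormalised log posterior density including the log Jacobian of the
#' transformation. This is the integrand handed to [warp3_logml()].
#'
#' @param model a [build_model()] object.
#' @return function `(y) -> scalar`.
#' @export
log_posterior_fn <- function(model) {
  gt <- .group_transforms(model$spec)
  ng <- length(model$group_names)
  P <- model$data$P
  function(y) {
    st <- vector_to_state(model, y)
    lp <- .log_posterior_state(model, st)
    if (!is.finite(lp)) return(-Inf)
    lj <- 0
    for (k in seq_len(ng))
      lj <- lj + .log_jacobian(y[k], gt[[model$group_names[k]]])
    off <- ng
    for (nm in model$participant_names) {
      b <- .bounds_of(nm)
      lj <- lj + .log_jacobian(y[off + seq_len(P)],
                               c("interval", b[1], b[2]))
      off <- off + P
    }
    lp + lj
  }
}
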