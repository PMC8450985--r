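# Blocked adaptive Metropolis-within-Gibbs sampler.
#
# Participant-level parameters are updated in vectorised blocks (one proposal
# per participant, accepted independently -- the likelihood and participant
# priors factorise over participants given the group parameters), so each
# sweep costs a handful of C-level likelihood passes regardless of P. Group
# parameters are updated by scalar random-walk steps against the participant
# priors only (they do not enter the Wiener likelihood directly). Proposal
# scales adapt towards 44% acceptance during burn-in and are frozen
# afterwards.

# which likelihood cells (conditions) and trial subsets a block touches
.block_info <- function(spec) {
  switch(spec,
         M1_start = list(delta = list(cols = 1:3, sub = "all"),
                         alpha = list(cols = 1:3, sub = "all"),
                         tau = list(cols = 1:3, sub = "all"),
                         beta2 = list(cols = 2:3, sub = "c23")),
         M2_drift = list(delta1 = list(cols = 1L, sub = "c1"),
                         delta2 = list(cols = 2L, sub = "c2"),
                         delta3 = list(cols = 3L, sub = "c3"),
                         alpha = list(cols = 1:3, sub = "all"),
                         tau = list(cols = 1:3, sub = "all")),
         M3_both = list(delta1 = list(cols = 1L, sub = "c1"),
                        delta2 = list(cols = 2L, sub = "c2"),
                        delta3 = list(cols = 3L, sub = "c3"),
                        alpha = list(cols = 1:3, sub = "all"),
                        tau = list(cols = 1:3, sub = "all"),
                        beta2 = list(cols = 2:3, sub = "c23")))
}

.init_state <- function(model) {
  d <- model$data
  P <- d$P
  st <- list()
  for (nm in model$participant_names) {
    st[[nm]] <- switch(substr(nm, 1, 4),
                       delt = runif(P, -2, 4),
                       alph = runif(P, 0.5, 2.5),
                       tau = runif(P, 0.05, pmin(0.8 * d$min_rt, 0.9)),
                       beta = runif(P, 0.2, 0.8))
  }
  gi <- c(mu_delta = NA, sigma_delta = NA, mu_alpha = NA, sigma_alpha = NA,
          mu_tau = NA, sigma_tau = NA, theta_beta = NA, sigma_eps_beta = NA,
          theta_delta = NA, sigma_eps_delta = NA)
  gi["mu_delta"] <- runif(1, 0, 2.5)
  gi["sigma_delta"] <- runif(1, 0.2, 1)
  gi["mu_alpha"] <- runif(1, 0.8, 2)
  gi["sigma_alpha"] <- runif(1, 0.1, 0.6)
  gi["mu_tau"] <- runif(1, 0.15, 0.45)
  gi["sigma_tau"] <- runif(1, 0.02, 0.15)
  gi["theta_beta"] <- runif(1, -0.5, 0.5)
  gi["sigma_eps_beta"] <- runif(1, 0.05, 0.2)
  gi["theta_delta"] <- runif(1, -0.5, 0.5)
  gi["sigma_eps_delta"] <- runif(1, 0.2, 0.6)
  st$group <- gi[model$group_names]
  st
}

# conditional log density of the group parameters given participant values
.group_logdens <- function(model, g, st) {
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
  lp
}

.mcmc_chain <- function(model, n_iter, burn_in, thin, prior_only = FALSE,
                        adapt_every = 25L) {
  d <- model$data
  P <- d$P
  blocks <- .block_info(model$spec)
  subsets <- list(all = seq_along(d$rt), c1 = which(d$cond == 1L),
                  c2 = which(d$cond == 2L), c3 = which(d$cond == 3L),
                  c23 = which(d$cond != 1L))

  ll_cells <- function(st, idx) {
    if (prior_only) return(matrix(0, P, 3))
    tp <- .trial_params(model, st)
    matrix(wiener_loglik_by(d$rt[idx], d$correct[idx], d$cell0[idx],
                            tp$v[idx], tp$a[idx], tp$tau[idx], tp$w[idx],
                            3L * P), P, 3)
  }

  st <- .init_state(model)
  llpc <- ll_cells(st, subsets$all)

  sc_part <- list()
  for (nm in names(blocks))
    sc_part[[nm]] <- rep(switch(substr(nm, 1, 4), delt = 0.4, alph = 0.15,
                                tau = 0.04, beta = 0.05), P)
  sc_group <- setNames(rep(0.15, length(model$group_names)),
                       model$group_names)
  acc_part <- lapply(sc_part, function(s) numeric(P))
  acc_group <- sc_group * 0

  n_keep <- max(0L, (n_iter - burn_in) %/% thin)
  keep_group <- matrix(NA_real_, n_keep, length(model$group_names),
                       dimnames = list(NULL, model$group_names))
  keep_part <- lapply(setNames(model$participant_names,
                               model$participant_names),
                      function(nm) matrix(NA_real_, n_keep, P))
  k_out <- 0L

  for (it in seq_len(n_iter)) {
    # participant blocks
    for (nm in names(blocks)) {
      bi <- blocks[[nm]]
      b <- .bounds_of(nm)
      pr <- .participant_prior(nm, st$group, model$spec)
      x <- st[[nm]]
      xp <- x + sc_part[[nm]] * rnorm(P)
      ok <- xp > b[1] & xp < b[2]
      if (nm == "tau" && !prior_only) ok <- ok & xp < d$min_rt
      st2 <- st
      st2[[nm]] <- ifelse(ok, xp, x)
      llp <- ll_cells(st2, subsets[[bi$sub]])
      dll <- rowSums(llp[, bi$cols, drop = FALSE]) -
        rowSums(llpc[, bi$cols, drop = FALSE])
      dpr <- dnorm(xp, pr[1], pr[2], log = TRUE) -
        dnorm(x, pr[1], pr[2], log = TRUE)
      lr <- dll + dpr
      lr[!ok] <- -Inf
      lr[is.na(lr)] <- -Inf
      acc <- log(runif(P)) < lr
      if (any(acc)) {
        st[[nm]][acc] <- xp[acc]
        llpc[acc, bi$cols] <- llp[acc, bi$cols]
      }
      acc_part[[nm]] <- acc_part[[nm]] + acc
    }
    # group parameters (scalar random-walk; no likelihood involved)
    lg_cur <- .group_logdens(model, st$group, st)
    for (gn in model$group_names) {
      gp <- st$group
      gp[gn] <- gp[gn] + sc_group[gn] * rnorm(1)
      lg_new <- .group_logdens(model, gp, st)
      if (log(runif(1)) < lg_new - lg_cur) {
        st$group <- gp
        lg_cur <- lg_new
        acc_group[gn] <- acc_group[gn] + 1
      }
    }
    # adaptation (burn-in only)
    if (it <= burn_in && it %% adapt_every == 0L) {
      step <- max(0.05, min(0.5, 5 / sqrt(it)))
      for (nm in names(blocks)) {
        rate <- acc_part[[nm]] / adapt_every
        sc_part[[nm]] <- sc_part[[nm]] * exp(step * (rate - 0.44))
        acc_part[[nm]][] <- 0
      }
      rate_g <- acc_group / adapt_every
      sc_group <- sc_group * exp(step * (rate_g - 0.44))
      acc_group[] <- 0
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      k_out <- k_out + 1L
      keep_group[k_out, ] <- st$group
      for (nm in model$participant_names)
        keep_part[[nm]][k_out, ] <- st[[nm]]
    }
  }
  list(group = keep_group, participant = keep_part)
}

#' Sample from the posterior by adaptive Metropolis-within-Gibbs
#'
#' Runs `n_chains` independent chains of `n_iter` iterations each, discards
#' `burn_in` iterations per chain, and retains the rest (optionally thinned).
#' Initial values are drawn uniformly within the admissible parameter ranges;
#' proposal scales adapt during burn-in only, so the retained draws come from
#' a fixed-kernel Markov chain. Reproducible given `seed` (chain `j` is seeded
#' with `seed + j`).
#'
#' @param model a [build_model()] object.
#' @param n_chains,n_iter,burn_in MCMC schedule; the defaults (3 chains of
#'   15000 with 6000 burn-in, 27000 retained draws) suit a full analysis and
#'   should be scaled down for quick runs.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed.
#' @param prior_only drop the likelihood term and sample from the joint prior
#'   (useful for prior-recovery checks).
#' @return object of class `ddm_fit` with elements `group` (matrix of retained
#'   draws by group parameter), `participant` (list of draw-by-participant
#'   matrices), `chain` (chain index per draw), `model` and the schedule.
#' @export
sample_posterior <- function(model, n_chains = 3, n_iter = 15000,
                             burn_in = 6000, thin = 1, seed = 1,
                             prior_only = FALSE) {
  stopifnot(inherits(model, "ddm_model"), n_iter > burn_in)
  res <- vector("list", n_chains)
  for (j in seq_len(n_chains)) {
    set.seed(seed + j)
    res[[j]] <- .mcmc_chain(model, n_iter, burn_in, thin, prior_only)
  }
  n_keep <- nrow(res[[1]]$group)
  fit <- list(group = do.call(rbind, lapply(res, `[[`, "group")),
              participant = lapply(setNames(model$participant_names,
                                            model$participant_names),
                                   function(nm)
                                     do.call(rbind,
                                             lapply(res, function(r)
                                               r$participant[[nm]]))),
              chain = rep(seq_len(n_chains), each = n_keep),
              model = model,
              n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
              thin = thin, seed = seed, prior_only = prior_only)
  class(fit) <- "ddm_fit"
  fit
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("ddm_fit:", x$model$spec, "-", nrow(x$group), "retained draws (",
      x$n_chains, "chains x", x$n_iter, "iterations,", x$burn_in,
      "burn-in)\n")
  s <- apply(x$group, 2, function(v)
    c(mean = mean(v), sd = sd(v), `2.5%` = unname(quantile(v, 0.025)),
      `97.5%` = unname(quantile(v, 0.975))))
  print(t(s), digits = 3)
  invisible(x)
}

#' Starting-point draws for the invalid condition
#'
#' Mirror identity `beta3 = 1 - beta2`, applied draw by draw.
#'
#' @param fit a [sample_posterior()] fit of a model with a starting-point
#'   effect.
#' @return matrix of invalid-condition starting points (draws x participants).
#' @export
beta_invalid <- function(fit) {
  if (is.null(fit$participant$beta2))
    stop("model has no starting-point effect")
  1 - fit$participant$beta2
}

# ---- convergence diagnostics ----------------------------------------------

#' Gelman-Rubin statistic for a draws matrix
#'
#' Classic (potential scale reduction) R-hat from between- and within-chain
#' variances; `split = TRUE` first splits each chain in half (usable with a
#' single chain).
#'
#' @param x matrix of draws, iterations x chains.
#' @param split split each chain in half first?
#' @return scalar R-hat.
#' @export
rhat <- function(x, split = FALSE) {
  x <- as.matrix(x)
  if (split) {
    n2 <- floor(nrow(x) / 2)
    x <- cbind(x[seq_len(n2), , drop = FALSE],
               x[nrow(x) - n2 + seq_len(n2), , drop = FALSE])
  }
  m <- ncol(x)
  if (m < 2) stop("need at least 2 chains (or use split = TRUE)")
  n <- nrow(x)
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  if (W == 0) {
    warning("zero within-chain variance")
    return(if (B_over_n == 0) 1 else Inf)
  }
  sqrt((n - 1) / n + B_over_n / W)
}

#' Gelman-Rubin diagnostics for a fitted model
#'
#' @param fit a [sample_posterior()] fit with at least 2 chains (or
#'   `split = TRUE`).
#' @param parameters `"group"` (default) for the group-level parameters,
#'   `"all"` to include every participant-level parameter.
#' @param split use split-R-hat?
#' @return named vector of R-hat values.
#' @export
gelman_rubin <- function(fit, parameters = c("group", "all"), split = FALSE) {
  parameters <- match.arg(parameters)
  stopifnot(inherits(fit, "ddm_fit"))
  per_chain <- function(v) {
    do.call(cbind, lapply(split(v, fit$chain), identity))
  }
  out <- vapply(colnames(fit$group),
                function(nm) rhat(per_chain(fit$group[, nm]), split),
                numeric(1))
  if (parameters == "all") {
    for (nm in names(fit$participant)) {
      mat <- fit$participant[[nm]]
      r <- vapply(seq_len(ncol(mat)),
                  function(p) rhat(per_chain(mat[, p]), split), numeric(1))
      names(r) <- paste0(nm, "[", fit$model$data$participants, "]")
      out <- c(out, r)
    }
  }
  out
}

# ---- posterior predictive checks ------------------------------------------

#' Posterior predictive accuracy and RT quantiles
#'
#' For `n_rep` randomly chosen retained draws, simulates a full replicate
#' dataset with the observed trial counts per participant and condition,
#' applies the same response window (0.2-1.5 s) as the observed data, and
#' summarises each replicate by condition-level accuracy and correct-RT
#' quantiles. Returns observed statistics with 95% predictive bands.
#'
#' @param fit a [sample_posterior()] fit.
#' @param data the [study_data] the model was fitted to.
#' @param n_rep number of posterior replicates.
#' @param probs RT quantiles to track.
#' @param seed optional RNG seed.
#' @param filter apply the 0.2-1.5 s response window to replicates?
#' @return object of class `ddm_ppc`: data.frame with columns `condition`,
#'   `stat`, `observed`, `pred_mean`, `pred_lower`, `pred_upper`.
#' @export
posterior_predict <- function(fit, data, n_rep = 100,
                              probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              seed = NULL, filter = TRUE) {
  stopifnot(inherits(fit, "ddm_fit"), inherits(data, "study_data"))
  if (!is.null(seed)) set.seed(seed)
  model <- fit$model
  d <- model$data
  P <- d$P
  tr <- data$trials
  tr <- tr[tr$participant %in% d$participants, ]
  counts <- table(factor(tr$participant, d$participants), tr$condition)

  stat_names <- c("accuracy", paste0("rt_q", probs * 100))
  summarise_trials <- function(df) {
    out <- matrix(NA_real_, 3, length(stat_names),
                  dimnames = list(CONDITION_LEVELS, stat_names))
    for (cc in CONDITION_LEVELS) {
      s <- df[df$condition == cc, ]
      if (!nrow(s)) next
      out[cc, 1] <- 100 * mean(s$correct)
      crt <- s$rt[s$correct]
      if (length(crt)) out[cc, -1] <- quantile(crt, probs, names = FALSE)
    }
    out
  }
  obs <- summarise_trials(tr)

  draw_params <- function(k) {
    if (model$spec == "M1_start")
      v <- cbind(fit$participant$delta[k, ], fit$participant$delta[k, ],
                 fit$participant$delta[k, ])
    else
      v <- cbind(fit$participant$delta1[k, ], fit$participant$delta2[k, ],
                 fit$participant$delta3[k, ])
    b2 <- if (is.null(fit$participant$beta2)) rep(0.5, P)
    else fit$participant$beta2[k, ]
    list(v = v, w = cbind(rep(0.5, P), b2, 1 - b2),
         a = fit$participant$alpha[k, ], tau = fit$participant$tau[k, ])
  }

  reps <- array(NA_real_, c(n_rep, 3, length(stat_names)))
  ks <- sample(nrow(fit$group), n_rep, replace = n_rep > nrow(fit$group))
  for (r in seq_len(n_rep)) {
    pp <- draw_params(ks[r])
    sim <- vector("list", P * 3)
    idx <- 0
    for (p in seq_len(P)) for (ci in 1:3) {
      n_pc <- counts[p, ci]
      if (n_pc == 0) next
      s <- rwiener(n_pc, pp$v[p, ci], pp$a[p], pp$tau[p], pp$w[p, ci])
      idx <- idx + 1
      sim[[idx]] <- data.frame(condition = CONDITION_LEVELS[ci],
                               correct = s$correct, rt = s$rt)
    }
    df <- do.call(rbind, sim[seq_len(idx)])
    if (filter) df <- df[df$rt >= 0.2 & df$rt <= 1.5, ]
    reps[r, , ] <- summarise_trials(df)
  }

  out <- expand.grid(condition = CONDITION_LEVELS, stat = stat_names,
                     stringsAsFactors = FALSE)
  out$observed <- mapply(function(cc, ss) obs[cc, ss],
                         out$condition, out$stat)
  out$pred_mean <- mapply(function(cc, ss)
    mean(reps[, match(cc, CONDITION_LEVELS), match(ss, stat_names)],
         na.rm = TRUE), out$condition, out$stat)
  out$pred_lower <- mapply(function(cc, ss)
    quantile(reps[, match(cc, CONDITION_LEVELS), match(ss, stat_names)],
             0.025, na.rm = TRUE, names = FALSE), out$condition, out$stat)
  out$pred_upper <- mapply(function(cc, ss)
    quantile(reps[, match(cc, CONDITION_LEVELS), match(ss, stat_names)],
             0.975, na.rm = TRUE, names = FALSE), out$condition, out$stat)
  structure(list(table = out, n_rep = n_rep), class = "ddm_ppc")
}

#' @export
print.ddm_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$n_rep, "replicates):\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Plot a posterior predictive check
#'
#' Observed condition-level statistics over 95% posterior predictive bands.
#'
#' @param ppc a [posterior_predict()] result.
#' @return a ggplot object.
#' @export
plot_ppc <- function(ppc) {
  stopifnot(inherits(ppc, "ddm_ppc"))
  df <- ppc$table
  ggplot2::ggplot(df, ggplot2::aes(x = condition)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pred_lower, ymax = pred_upper),
                           width = 0.2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = pred_mean), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = observed), colour = "red",
                        shape = 4, size = 2) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(y = NULL, x = "cue condition",
                  title = "Posterior predictive check (x = observed)")
}
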