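# Synthetic cued random-dot-motion studies with known ground truth.
# Design defaults mirror the emulated study: 222 participants, 5 blocks of 40
# trials, half neutral cues, 80% cue validity, trait score with mean 17 and
# SD 6.77 clipped to [0, 50].

# truncated-normal helpers -------------------------------------------------

.tn_check <- function(mean, sd, lo, hi) {
  mass <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  if (any(mass < 1e-6))
    stop("truncated normal has mass < 1e-6 inside [", lo, ", ", hi,
         "]; infeasible truncation")
  mass
}

# inverse-CDF draw through a supplied standard-normal score, so a latent
# score can be shared with the trait for correlation linkage
rtnorm_z <- function(z, mean, sd, lo, hi) {
  .tn_check(mean, sd, lo, hi)
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- pnorm(z)
  qnorm(plo + u * (phi - plo), mean, sd)
}

rtnorm <- function(n, mean, sd, lo, hi) rtnorm_z(rnorm(n), mean, sd, lo, hi)

dtnorm <- function(x, mean, sd, lo, hi, log = FALSE) {
  ld <- dnorm(x, mean, sd, log = TRUE) -
    log(pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
  ld[x < lo | x > hi] <- -Inf
  if (log) ld else exp(ld)
}

# configuration -------------------------------------------------------------

#' Configuration for a synthetic cued-decision study
#'
#' Defaults reproduce the emulated design: 222 participants, 5 blocks of 40
#' trials, half neutral cues, 80% of directional cues valid, and a trait score
#' with population mean 17 and SD 6.77 (integer, clipped to `[0, 50]`).
#' Group-level diffusion parameters default to values that yield accuracy and
#' median correct RTs close to the observed behavioural pattern (neutral
#' accuracy near 79%, valid above neutral, invalid below; median RT around
#' 0.6 s).
#'
#' @param n_participants,n_blocks,trials_per_block design counts.
#' @param p_neutral fraction of neutral-cue trials.
#' @param cue_validity probability that a directional cue is valid.
#' @param model generating model: `"M1_start"` (condition effect on starting
#'   point), `"M2_drift"` (on drift rate), `"M3_both"`.
#' @param group named list of group-level truth: `mu_delta`, `sigma_delta`,
#'   `mu_alpha`, `sigma_alpha`, `mu_tau`, `sigma_tau`, and the condition
#'   effects `theta_beta`, `sigma_eps_beta` (starting point; used by M1/M3)
#'   and `theta_delta`, `sigma_eps_delta` (drift; used by M2/M3). The group
#'   starting-point shift is `theta_beta * sigma_eps_beta` and the group drift
#'   shift is `theta_delta * sigma_eps_delta`.
#' @param trait_correlation population correlation `rho` between the trait
#'   score and the latent score of `trait_param`, in (-1, 1).
#' @param trait_param which participant parameter the trait tracks:
#'   `"delta_beta"` (starting-point effect), `"alpha"` (boundary separation)
#'   or `"delta_effect"` (valid-cue drift rate).
#' @param trait_mean,trait_sd trait population moments before rounding and
#'   clipping to `[0, 50]`.
#' @param censor_misses drop trials whose simulated RT exceeds the 1.5 s
#'   response deadline (emulating "miss" trials absent from data files)?
#' @param exact_counts assign condition counts deterministically within
#'   participant (default) rather than Bernoulli per trial.
#' @param seed integer seed used by [generate_study()].
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 222, n_blocks = 5,
                         trials_per_block = 40, p_neutral = 0.5,
                         cue_validity = 0.8,
                         model = c("M1_start", "M2_drift", "M3_both"),
                         group = list(), trait_correlation = 0,
                         trait_param = c("delta_beta", "alpha", "delta_effect"),
                         trait_mean = 17, trait_sd = 6.77,
                         censor_misses = TRUE, exact_counts = TRUE,
                         seed = NULL) {
  model <- match.arg(model)
  trait_param <- match.arg(trait_param)
  g <- list(mu_delta = 1.0, sigma_delta = 0.6,
            mu_alpha = 1.35, sigma_alpha = 0.3,
            mu_tau = 0.25, sigma_tau = 0.05,
            theta_beta = 1.6, sigma_eps_beta = 0.05,
            theta_delta = 0.8, sigma_eps_delta = 0.25)
  g[names(group)] <- group
  stopifnot(n_participants >= 1, n_blocks >= 1, trials_per_block >= 1,
            p_neutral >= 0, p_neutral <= 1,
            cue_validity >= 0, cue_validity <= 1,
            abs(trait_correlation) < 1)
  structure(list(n_participants = n_participants, n_blocks = n_blocks,
                 trials_per_block = trials_per_block, p_neutral = p_neutral,
                 cue_validity = cue_validity, model = model, group = g,
                 trait_correlation = trait_correlation,
                 trait_param = trait_param, trait_mean = trait_mean,
                 trait_sd = trait_sd, censor_misses = censor_misses,
                 exact_counts = exact_counts, seed = seed),
            class = "synth_config")
}

# participant-level truth ----------------------------------------------------

#' Draw participant-level parameters and trait scores
#'
#' Participant-level drift, boundary and non-decision time are drawn from
#' truncated normals around the group truth (bounds: drift (-5, 10), boundary
#' (0.1, 5), non-decision time (0.05, 1) s). The condition-affected
#' parameter(s) follow the generating model: under a starting-point effect the
#' valid-cue start is TruncNormal(0.5 + theta*sigma_eps, sigma_eps) on
#' (0.01, 0.99) with the invalid start mirrored at 1 - beta_valid; under a
#' drift effect the condition drifts are TruncNormal(mu_delta + x_c *
#' theta*sigma_eps, sigma_eps) with x = 0 / +1 / -1 for neutral / valid /
#' invalid. The trait score is linked to the chosen parameter's latent
#' standard-normal score at population correlation `trait_correlation`, then
#' rounded and clipped to `[0, 50]`.
#'
#' @param config a [synth_config].
#' @return data.frame with one row per participant: `participant`,
#'   `delta_neutral`, `delta_valid`, `delta_invalid`, `alpha`, `tau`,
#'   `beta_valid`, `trait`.
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$group
  P <- config$n_participants
  rho <- config$trait_correlation

  z <- list(delta = rnorm(P), alpha = rnorm(P), tau = rnorm(P),
            beta = rnorm(P), delta_valid = rnorm(P), delta_invalid = rnorm(P))
  z_target <- switch(config$trait_param,
                     delta_beta = "beta", alpha = "alpha",
                     delta_effect = "delta_valid")
  z_trait <- rho * z[[z_target]] + sqrt(1 - rho^2) * rnorm(P)

  start_fx <- config$model %in% c("M1_start", "M3_both")
  drift_fx <- config$model %in% c("M2_drift", "M3_both")

  if (drift_fx) {
    # sigma_eps_delta is the participant-level SD of every condition drift;
    # the condition means are shifted symmetrically by theta*sigma_eps
    dn <- rtnorm_z(z$delta, g$mu_delta, g$sigma_eps_delta, -5, 10)
    dv <- rtnorm_z(z$delta_valid,
                   g$mu_delta + g$theta_delta * g$sigma_eps_delta,
                   g$sigma_eps_delta, -5, 10)
    di <- rtnorm_z(z$delta_invalid,
                   g$mu_delta - g$theta_delta * g$sigma_eps_delta,
                   g$sigma_eps_delta, -5, 10)
  } else {
    dn <- rtnorm_z(z$delta, g$mu_delta, g$sigma_delta, -5, 10)
    dv <- di <- dn
  }
  bv <- if (start_fx) {
    m <- 0.5 + g$theta_beta * g$sigma_eps_beta
    if (m <= 0 || m >= 1) stop("valid-condition starting-point mean outside (0,1)")
    rtnorm_z(z$beta, m, g$sigma_eps_beta, 0.01, 0.99)
  } else rep(0.5, P)

  trait <- pmin(pmax(round(config$trait_mean + config$trait_sd * z_trait), 0), 50)

  data.frame(participant = sprintf("P%03d", seq_len(P)),
             delta_neutral = dn, delta_valid = dv, delta_invalid = di,
             alpha = rtnorm_z(z$alpha, g$mu_alpha, g$sigma_alpha, 0.1, 5),
             tau = rtnorm_z(z$tau, g$mu_tau, g$sigma_tau, 0.05, 1),
             beta_valid = bv, trait = trait, stringsAsFactors = FALSE)
}

# trial generation -----------------------------------------------------------

#' Simulate trials for generated participants
#'
#' Assigns cue conditions within participant (deterministic counts by default:
#' with the design defaults 100 neutral, 80 valid, 20 invalid trials), draws
#' choice and RT from the Wiener process with that condition's parameters, and
#' (by default) censors trials slower than the 1.5 s response deadline as
#' misses absent from the output. Stimulus direction is balanced within
#' participant and the cue direction follows from condition and validity.
#'
#' @param participants output of [generate_participants()].
#' @param config the same [synth_config].
#' @return a [study_data] object.
#' @export
generate_trials <- function(participants, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_blocks * config$trials_per_block
  out <- vector("list", nrow(participants))
  for (p in seq_len(nrow(participants))) {
    pp <- participants[p, ]
    if (config$exact_counts) {
      n_neutral <- round(n * config$p_neutral)
      n_valid <- round((n - n_neutral) * config$cue_validity)
      n_invalid <- n - n_neutral - n_valid
      cond <- rep(CONDITION_LEVELS, c(n_neutral, n_valid, n_invalid))
    } else {
      dir_cue <- runif(n) >= config$p_neutral
      valid <- runif(n) < config$cue_validity
      cond <- ifelse(!dir_cue, "neutral", ifelse(valid, "valid", "invalid"))
    }
    cond <- sample(cond)
    w <- c(neutral = 0.5, valid = pp$beta_valid,
           invalid = 1 - pp$beta_valid)
    dl <- c(neutral = pp$delta_neutral, valid = pp$delta_valid,
            invalid = pp$delta_invalid)
    rt <- numeric(n); correct <- logical(n)
    for (cc in CONDITION_LEVELS) {
      sel <- cond == cc
      if (!any(sel)) next
      sim <- rwiener(sum(sel), dl[cc], pp$alpha, pp$tau, w[cc])
      rt[sel] <- sim$rt; correct[sel] <- sim$correct
    }
    stim <- sample(rep(c("left", "right"), length.out = n))
    cue <- ifelse(cond == "neutral", "none",
                  ifelse(cond == "valid", stim,
                         ifelse(stim == "left", "right", "left")))
    df <- data.frame(participant = pp$participant,
                     block = rep(seq_len(config$n_blocks),
                                 each = config$trials_per_block),
                     condition = cond, correct = correct, rt = rt,
                     stimulus_direction = stim, cue_direction = cue,
                     stringsAsFactors = FALSE)
    if (config$censor_misses) df <- df[df$rt <= 1.5, , drop = FALSE]
    out[[p]] <- df
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  covariates <- data.frame(participant = participants$participant,
                           aq = participants$trait, stringsAsFactors = FALSE)
  study_data(trials, covariates)
}

#' Generate a complete synthetic study
#'
#' Seeds the RNG from `config$seed` (when set), draws participants and trials,
#' and returns the study together with its ground truth.
#'
#' @param config a [synth_config].
#' @return list with `data` (a [study_data]), `participants` (ground-truth
#'   parameters) and `config`.
#' @export
generate_study <- function(config = synth_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  participants <- generate_participants(config)
  data <- generate_trials(participants, config)
  list(data = data, participants = participants, config = config)
}
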