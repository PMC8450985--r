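# shared fixtures: small synthetic studies and reduced fitting schedules

small_study <- function(seed = 1, P = 10, blocks = 2, tpb = 30,
                        model = "M1_start", censor = FALSE, ...) {
  generate_study(synth_config(n_participants = P, n_blocks = blocks,
                              trials_per_block = tpb, model = model,
                              censor_misses = censor, seed = seed, ...))
}

quick_fit <- function(data, spec = "M1_start", n_iter = 800, burn_in = 400,
                      n_chains = 1, seed = 5, ...) {
  sample_posterior(build_model(spec, accuracy_code(data)),
                   n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                   seed = seed, ...)
}

# hand-built trial table for IO tests
toy_trials <- function() {
  data.frame(participant = rep(c("a", "b"), each = 3),
             block = 1L,
             condition = c("neutral", "valid", "invalid",
                           "neutral", "valid", "invalid"),
             correct = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
             rt = c(0.5, 0.4, 0.6, 0.55, 0.45, 0.65),
             stringsAsFactors = FALSE)
}

toy_covariates <- function() {
  data.frame(participant = c("a", "b"), aq = c(12L, 25L),
             stringsAsFactors = FALSE)
}
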