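# data model, IO, filtering, behavioural summaries

test_that("well-formed tables round-trip through files", {
  sd0 <- study_data(toy_trials(), toy_covariates())
  dir <- withr::local_tempdir()
  write_study(sd0, dir)
  sd1 <- read_trials(file.path(dir, "trials.csv"),
                     file.path(dir, "covariates.csv"))
  expect_equal(sd1$trials$rt, sd0$trials$rt)
  expect_equal(as.character(sd1$trials$condition),
               as.character(sd0$trials$condition))
  expect_equal(sd1$covariates, sd0$covariates)
})

test_that("millisecond input is converted to seconds via config", {
  tr <- toy_trials()
  tr$rt <- tr$rt * 1000
  dir <- withr::local_tempdir()
  write.csv(tr, file.path(dir, "t.csv"), row.names = FALSE)
  write.csv(toy_covariates(), file.path(dir, "c.csv"), row.names = FALSE)
  sd1 <- read_trials(file.path(dir, "t.csv"), file.path(dir, "c.csv"),
                     config = list(rt_unit = "ms"))
  expect_equal(sd1$trials$rt, toy_trials()$rt)
})

test_that("schema violations are reported with offending values", {
  tr <- toy_trials()
  tr$condition[2] <- "sideways"
  expect_error(study_data(tr, toy_covariates()), "sideways")
  tr2 <- toy_trials()[, -5]
  expect_error(study_data(tr2, toy_covariates()), "rt")
  tr3 <- toy_trials()
  tr3$rt[3] <- "fast"
  expect_error(study_data(tr3, toy_covariates()), "row")
  cv <- toy_covariates()
  cv$aq[1] <- 60
  expect_error(study_data(toy_trials(), cv), "AQ")
  expect_error(study_data(toy_trials(), toy_covariates()[1, ]),
               "missing from covariate")
})

test_that("integer condition codes map to the labelled levels", {
  tr <- toy_trials()
  tr$condition <- rep(c(1, 2, 3), 2)
  sd0 <- study_data(tr, toy_covariates())
  expect_equal(as.character(sd0$trials$condition),
               rep(c("neutral", "valid", "invalid"), 2))
  tr$condition <- rep(c(1, 2, 7), 2)
  expect_error(study_data(tr, toy_covariates()), "7")
})

test_that("RT filter applies the 0.2/1.5 s bounds inclusively", {
  tr <- toy_trials()[rep(1, 3), ]
  tr$rt <- c(0.15, 0.50, 1.55)
  sd0 <- study_data(tr, toy_covariates())
  flt <- filter_rts(sd0)
  expect_equal(flt$data$trials$rt, 0.50)
  expect_equal(flt$retention$pct[flt$retention$participant == "a"],
               100 / 3, tolerance = 1e-10)

  tr$rt <- c(0.2, 1.5, 0.8)  # bounds are retained
  flt2 <- filter_rts(study_data(tr, toy_covariates()))
  expect_equal(flt2$mean_pct, 100)
  expect_equal(nrow(flt2$data$trials), 3)
})

test_that("filtering is idempotent and conserves trial counts", {
  st <- small_study(seed = 3, P = 5, censor = TRUE)
  f1 <- filter_rts(st$data)
  f2 <- filter_rts(f1$data)
  expect_equal(f2$data$trials, f1$data$trials)
  expect_equal(f2$mean_pct, 100)
  expect_equal(f1$retention$n_total,
               f1$retention$n_retained +
                 (f1$retention$n_total - f1$retention$n_retained))
  # per participant: total before = retained + removed
  tot_before <- table(st$data$trials$participant)
  expect_equal(as.integer(tot_before[f1$retention$participant]),
               f1$retention$n_total)
})

test_that("a participant losing every trial is excluded with a warning", {
  tr <- toy_trials()
  tr$rt[tr$participant == "b"] <- 0.05
  expect_warning(flt <- filter_rts(study_data(tr, toy_covariates())),
                 "no retained trials")
  expect_false("b" %in% flt$data$trials$participant)
  expect_equal(flt$retention$n_retained[flt$retention$participant == "b"], 0)
})

test_that("accuracy coding conserves condition-by-correctness counts", {
  st <- small_study(seed = 9, P = 6)
  coded <- accuracy_code(st$data)
  expect_true(attr(coded, "accuracy_coded"))
  expect_equal(table(coded$trials$condition, coded$trials$correct),
               table(st$data$trials$condition, st$data$trials$correct))
  expect_equal(coded$trials$boundary,
               ifelse(coded$trials$correct, "upper", "lower"))
})

test_that("direction labels do not change the likelihood contribution", {
  # identical (condition, correct, rt) with opposite stimulus directions
  ll <- function(stim) wiener_loglik(0.6, TRUE, 1, 1.4, 0.25, 0.55)
  expect_equal(ll("left"), ll("right"))
})

test_that("behavioural summary computes medians, accuracies and AQ correlations", {
  st <- small_study(seed = 13, P = 20, blocks = 5, tpb = 40)
  s <- summarize_behavior(st$data)
  expect_equal(s$by_condition$condition,
               c("neutral", "valid", "invalid"))
  expect_true(all(s$by_condition$accuracy_mean >= 0 &
                    s$by_condition$accuracy_mean <= 100))
  ok <- !is.na(s$correlations$r)
  expect_true(all(s$correlations$ci_lower[ok] <= s$correlations$r[ok] &
                    s$correlations$r[ok] <= s$correlations$ci_upper[ok]))
})

test_that("degenerate summaries: identical participants and perfect correlation", {
  tr <- toy_trials()
  tr2 <- rbind(tr, tr)
  tr2$participant <- rep(c("a", "b"), each = 6)  # identical data per person
  cv <- toy_covariates()
  w <- capture_warnings(s <- summarize_behavior(study_data(tr2, cv)))
  expect_true(any(grepl("undefined", w)))
  expect_equal(s$by_condition$median_rt_sd, rep(0, 3))
  expect_true(all(is.na(s$correlations$r)))

  # trait a positive affine image of the median RT -> r = 1 exactly
  st <- small_study(seed = 17, P = 8)
  sel <- st$data$trials$correct & st$data$trials$condition == "neutral"
  med <- tapply(st$data$trials$rt[sel], st$data$trials$participant[sel],
                median)
  st$data$covariates$aq <-
    50 * (med[st$data$covariates$participant] - min(med)) /
    diff(range(med))
  s2 <- summarize_behavior(st$data)
  r_pkg <- s2$correlations$r[s2$correlations$measure == "median_rt" &
                               s2$correlations$condition == "neutral"]
  expect_equal(r_pkg, 1, tolerance = 1e-12)
})

test_that("Fisher-z interval is symmetric on the z scale and contains r", {
  ci <- cueddm:::.fisher_ci(0.3, 50)
  expect_lt(ci[1], 0.3)
  expect_gt(ci[2], 0.3)
  expect_equal(atanh(0.3) - atanh(ci[1]), atanh(ci[2]) - atanh(0.3),
               tolerance = 1e-12)
  expect_equal(atanh(ci[2]) - atanh(0.3), qnorm(0.975) / sqrt(50 - 3),
               tolerance = 1e-12)
})
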