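# Study data model: trial table + trait covariates, response-time filtering,
# accuracy coding, and behavioural summaries.

CONDITION_LEVELS <- c("neutral", "valid", "invalid")

#' Construct a study-data object
#'
#' Bundles a trial table with a per-participant covariate table and validates
#' both. Trials carry participant id, block, cue condition (neutral / valid /
#' invalid), correctness and response time in seconds; covariates carry the
#' trait score (AQ total, 0-50) and optionally the motion-coherence level.
#'
#' @param trials data.frame with columns `participant`, `block`, `condition`,
#'   `correct`, `rt` and optionally `stimulus_direction`, `cue_direction`.
#'   `condition` may be the labels `"neutral"/"valid"/"invalid"` or the integer
#'   codes 1/2/3.
#' @param covariates data.frame with columns `participant`, `aq` and optionally
#'   `coherence`.
#' @return object of class `study_data`.
#' @export
study_data <- function(trials, covariates) {
  req <- c("participant", "block", "condition", "correct", "rt")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(c("participant", "aq") %in% names(covariates)))
    stop("covariate table must have columns `participant` and `aq`")

  trials$participant <- as.character(trials$participant)
  covariates$participant <- as.character(covariates$participant)

  cond <- trials$condition
  if (is.numeric(cond)) {
    bad <- which(!(cond %in% 1:3))
    if (length(bad))
      stop("unknown condition code(s) ",
           paste(unique(cond[bad]), collapse = ", "),
           " in trial row(s) ", paste(head(bad, 10), collapse = ", "))
    cond <- CONDITION_LEVELS[cond]
  } else {
    cond <- tolower(as.character(cond))
    bad <- which(!(cond %in% CONDITION_LEVELS))
    if (length(bad))
      stop("unknown condition label(s): ",
           paste(unique(cond[bad]), collapse = ", "),
           " in trial row(s) ", paste(head(bad, 10), collapse = ", "))
  }
  trials$condition <- factor(cond, levels = CONDITION_LEVELS)

  rt <- suppressWarnings(as.numeric(trials$rt))
  bad <- which(is.na(rt) | rt <= 0)
  if (length(bad))
    stop("unparseable or non-positive rt in trial row(s): ",
         paste(head(bad, 10), collapse = ", "))
  trials$rt <- rt
  trials$correct <- as.logical(trials$correct)
  if (anyNA(trials$correct)) stop("`correct` must be logical or 0/1")
  trials$block <- as.integer(trials$block)
  if (any(trials$block < 1L, na.rm = TRUE)) stop("`block` must be >= 1")

  orphan <- setdiff(unique(trials$participant), covariates$participant)
  if (length(orphan))
    stop("participant(s) missing from covariate table: ",
         paste(head(orphan, 5), collapse = ", "))
  aq <- covariates$aq
  if (any(!is.na(aq) & (aq < 0 | aq > 50)))
    stop("AQ scores must lie in [0, 50]")

  structure(list(trials = trials, covariates = covariates),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat("study_data:", nrow(x$trials), "trials,",
      length(unique(x$trials$participant)), "participants\n")
  print(table(x$trials$condition))
  invisible(x)
}

#' Read trial-level data and covariates from delimited text
#'
#' Reads the trial table (CSV or TSV, auto-detected from the header line or
#' set via `config$delimiter`) and the covariate table, validates the schema
#' and returns a [study_data] object. Response times are converted to seconds
#' when `config$rt_unit = "ms"`.
#'
#' @param path trial table file; header columns `participant`, `block`,
#'   `condition`, `correct`, `rt` (optional `stimulus_direction`,
#'   `cue_direction`).
#' @param covariates_path covariate file with columns `participant`, `aq`
#'   (optional `coherence`).
#' @param config list with optional entries `rt_unit` (`"s"`, default, or
#'   `"ms"`) and `delimiter` (`","` or `"\t"`).
#' @return a [study_data] object.
#' @export
read_trials <- function(path, covariates_path, config = list()) {
  for (p in c(path, covariates_path))
    if (!file.exists(p)) stop("file not found: ", p)
  delim <- config$delimiter
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  trials <- read.csv(path, sep = delim, stringsAsFactors = FALSE)
  covariates <- read.csv(covariates_path, sep = delim,
                         stringsAsFactors = FALSE)
  unit <- config$rt_unit %||% "s"
  if (!unit %in% c("s", "ms")) stop("rt_unit must be 's' or 'ms'")
  if (unit == "ms" && "rt" %in% names(trials))
    trials$rt <- suppressWarnings(as.numeric(trials$rt)) / 1000
  study_data(trials, covariates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove implausibly fast and slow response times
#'
#' Removes trials with response times below `lower` (default 0.2 s) or above
#' `upper` (default 1.5 s); times exactly at a bound are retained. Reports the
#' retained fraction per participant and overall. Participants left without
#' any trials are dropped from the trial table with a warning (they remain in
#' the covariate table).
#'
#' @param data a [study_data] object.
#' @param lower,upper retention bounds in seconds (inclusive).
#' @return list with elements `data` (filtered [study_data]) and `retention`
#'   (data.frame `participant`, `n_total`, `n_retained`, `pct`), plus
#'   attribute-style element `mean_pct` (mean per-participant retention, %).
#' @export
filter_rts <- function(data, lower = 0.2, upper = 1.5) {
  stopifnot(inherits(data, "study_data"))
  tr <- data$trials
  keep <- tr$rt >= lower & tr$rt <= upper
  n_tot <- tapply(rep(1L, nrow(tr)), tr$participant, sum)
  n_ret <- tapply(as.integer(keep), tr$participant, sum)
  ret <- data.frame(participant = names(n_tot),
                    n_total = as.integer(n_tot),
                    n_retained = as.integer(n_ret),
                    pct = 100 * as.integer(n_ret) / as.integer(n_tot),
                    row.names = NULL, stringsAsFactors = FALSE)
  empty <- ret$participant[ret$n_retained == 0L]
  if (length(empty))
    warning("participant(s) with no retained trials excluded from fitting: ",
            paste(empty, collapse = ", "))
  out <- data
  out$trials <- tr[keep & !(tr$participant %in% empty), , drop = FALSE]
  rownames(out$trials) <- NULL
  list(data = out, retention = ret, mean_pct = mean(ret$pct))
}

#' Apply accuracy coding
#'
#' Marks the data as accuracy-coded: trials are classified only by cue
#' condition and correctness, collapsing across leftward and rightward
#' stimuli. The upper diffusion boundary is identified with the correct
#' response; stimulus and cue directions are retained as metadata but play no
#' role in the likelihood.
#'
#' @param data a [study_data] object.
#' @return the same object with the `boundary` column (`"upper"`/`"lower"`)
#'   added and attribute `accuracy_coded = TRUE`.
#' @export
accuracy_code <- function(data) {
  stopifnot(inherits(data, "study_data"))
  data$trials$boundary <- ifelse(data$trials$correct, "upper", "lower")
  attr(data, "accuracy_coded") <- TRUE
  data
}

.fisher_ci <- function(r, n, level = 0.95) {
  if (is.na(r) || n < 4) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Behavioural summary by cue condition
#'
#' For each cue condition, computes each participant's median correct-response
#' time and percentage accuracy, then the mean and SD of these across
#' participants, and the Pearson correlation of each per-participant measure
#' with the trait score (AQ), with a 95% confidence interval from the Fisher
#' z transform (variance 1/(n-3)).
#'
#' @param data a (typically filtered) [study_data] object.
#' @return object of class `behavioral_summary`: list with `by_condition`
#'   (data.frame: condition, median RT mean/SD, accuracy mean/SD, n) and
#'   `correlations` (data.frame: measure, condition, r, ci_lower, ci_upper, n).
#' @export
summarize_behavior <- function(data) {
  stopifnot(inherits(data, "study_data"))
  tr <- data$trials
  aq <- setNames(data$covariates$aq, data$covariates$participant)
  pts <- sort(unique(tr$participant))

  cell_stats <- expand.grid(participant = pts, condition = CONDITION_LEVELS,
                            stringsAsFactors = FALSE)
  cell_stats$med_rt <- NA_real_
  cell_stats$acc <- NA_real_
  for (i in seq_len(nrow(cell_stats))) {
    sel <- tr$participant == cell_stats$participant[i] &
      tr$condition == cell_stats$condition[i]
    if (!any(sel)) next
    cell_stats$acc[i] <- 100 * mean(tr$correct[sel])
    cr <- tr$rt[sel & tr$correct]
    if (length(cr)) cell_stats$med_rt[i] <- median(cr)
  }
  n_no_correct <- sum(is.na(cell_stats$med_rt))
  if (n_no_correct)
    warning(n_no_correct,
            " participant-condition cell(s) without correct trials excluded",
            " from the RT summary")

  by_cond <- do.call(rbind, lapply(CONDITION_LEVELS, function(cc) {
    s <- cell_stats[cell_stats$condition == cc, ]
    data.frame(condition = cc,
               median_rt_mean = mean(s$med_rt, na.rm = TRUE),
               median_rt_sd = sd(s$med_rt[!is.na(s$med_rt)]),
               accuracy_mean = mean(s$acc, na.rm = TRUE),
               accuracy_sd = sd(s$acc[!is.na(s$acc)]),
               n = sum(!is.na(s$acc)), stringsAsFactors = FALSE)
  }))

  cors <- do.call(rbind, lapply(CONDITION_LEVELS, function(cc) {
    s <- cell_stats[cell_stats$condition == cc, ]
    do.call(rbind, lapply(c("med_rt", "acc"), function(m) {
      ok <- !is.na(s[[m]]) & !is.na(aq[s$participant])
      x <- s[[m]][ok]; y <- aq[s$participant][ok]
      r <- if (sum(ok) >= 4 && sd(x) > 0 && sd(y) > 0) cor(x, y) else {
        warning("correlation with AQ undefined for ", m, " / ", cc)
        NA_real_
      }
      ci <- .fisher_ci(r, sum(ok))
      data.frame(measure = if (m == "med_rt") "median_rt" else "accuracy",
                 condition = cc, r = r, ci_lower = ci[1], ci_upper = ci[2],
                 n = sum(ok), stringsAsFactors = FALSE)
    }))
  }))
  rownames(cors) <- NULL

  structure(list(by_condition = by_cond, correlations = cors),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat("Behavioural summary (per-participant medians / accuracies):\n")
  print(x$by_condition, digits = 3)
  cat("\nCorrelations with trait score (Fisher-z 95% CI):\n")
  print(x$correlations, digits = 2)
  invisible(x)
}

#' Write a study to delimited text files
#'
#' Writes `trials.csv` and `covariates.csv` (the schema [read_trials()]
#' accepts) into `dir`.
#'
#' @param data a [study_data] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_study <- function(data, dir) {
  stopifnot(inherits(data, "study_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- file.path(dir, "trials.csv")
  cp <- file.path(dir, "covariates.csv")
  tr <- data$trials
  tr$condition <- as.character(tr$condition)
  tr$boundary <- NULL
  write.csv(tr, tp, row.names = FALSE, quote = FALSE)
  write.csv(data$covariates, cp, row.names = FALSE, quote = FALSE)
  invisible(c(trials = tp, covariates = cp))
}
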