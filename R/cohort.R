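#' Specification of a synthetic survival cohort
#'
#' Describes a cohort whose event times follow a proportional-hazards model:
#' covariates are drawn from the stated distributions, 17-segment scores are
#' drawn per segment from a categorical distribution (rest thallium scores by
#' binomial thinning of stress scores, so no segment reverses; BMIPP scores
#' share each stress segment score with probability `bmipp_corr`, otherwise
#' drawn independently), and the event time is exponential with rate
#' `baseline_rate * exp(sum(beta * x))`, administratively censored at
#' `censor_days`. Given an event, it is hard with probability `hard_prob`,
#' otherwise soft.
#'
#' The defaults emulate a cohort of patients with suspected or known coronary
#' disease and no prior infarction: n = 151, diabetes prevalence 14%,
#' LVEF 69 +/- 8 %, age 65 +/- 10 years, hazard ratios 6.1 for diabetes and
#' 1.18 per SSS point, hard fraction 0.25 of events, administrative censoring
#' at 2500 days. They reproduce the qualitative structure of such a cohort,
#' not any particular dataset.
#'
#' @param n number of patients (>= 2).
#' @param dm_prev diabetes prevalence.
#' @param lvef_mean,lvef_sd LVEF distribution (%; truncated to (10, 90)).
#' @param age_mean,age_sd age distribution (years).
#' @param male_frac fraction of male patients.
#' @param seg_probs length-5 probabilities of per-segment stress scores 0-4.
#' @param rest_thinning per-point probability that a stress score point
#'   persists at rest (binomial thinning).
#' @param bmipp_corr probability a BMIPP segment copies the stress score.
#' @param beta named log-hazard-ratio vector; names among `dm`, `sss`,
#'   `srs`, `sds`, `sbs`, `lvef`, `age`, `sex_male`.
#' @param baseline_rate baseline exponential hazard per day (> 0).
#' @param censor_days administrative censoring time (> 0).
#' @param hard_prob probability an event is hard.
#' @param seed integer seed; same spec and seed give an identical cohort.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n = 151L, dm_prev = 0.14,
                        lvef_mean = 69, lvef_sd = 8,
                        age_mean = 65, age_sd = 10,
                        male_frac = 0.55,
                        seg_probs = c(0.93, 0.035, 0.015, 0.012, 0.008),
                        rest_thinning = 0.5,
                        bmipp_corr = 0.6,
                        beta = c(dm = log(6.1), sss = log(1.18)),
                        baseline_rate = 3e-5,
                        censor_days = 2500,
                        hard_prob = 0.25,
                        seed = 1L) {
  if (n < 2L) stop("`n` must be at least 2")
  if (baseline_rate <= 0) stop("`baseline_rate` must be positive")
  if (censor_days <= 0) stop("`censor_days` must be positive")
  if (length(seg_probs) != 5L || any(seg_probs < 0) ||
      abs(sum(seg_probs) - 1) > 1e-8)
    stop("`seg_probs` must be 5 probabilities summing to 1")
  allowed <- c("dm", "sss", "srs", "sds", "sbs", "lvef", "age", "sex_male")
  if (length(beta) && !all(names(beta) %in% allowed))
    stop("`beta` names must be among: ", paste(allowed, collapse = ", "))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a survival cohort
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` in the cohort CSV schema (see
#'   [validate_cohort()]): one row per patient with covariates, summed
#'   scores, `followup_days` and `event` in `none`/`soft`/`hard`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  dm <- stats::rbinom(n, 1, spec$dm_prev)
  sex_male <- stats::rbinom(n, 1, spec$male_frac)
  age <- round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1)
  lvef <- round(pmin(pmax(stats::rnorm(n, spec$lvef_mean, spec$lvef_sd),
                          10), 90), 1)
  htn <- stats::rbinom(n, 1, 0.5)
  dys <- stats::rbinom(n, 1, 0.3)
  smo <- stats::rbinom(n, 1, 0.32)
  uap <- stats::rbinom(n, 1, 0.1)
  ace <- stats::rbinom(n, 1, 0.13)
  bb <- stats::rbinom(n, 1, 0.15)
  ccb <- stats::rbinom(n, 1, 0.49)
  stress <- matrix(sample(0:4, n * 17, TRUE, spec$seg_probs), n, 17)
  rest <- matrix(stats::rbinom(n * 17, as.vector(stress),
                               spec$rest_thinning), n, 17)
  copy <- matrix(stats::rbinom(n * 17, 1, spec$bmipp_corr), n, 17)
  indep <- matrix(sample(0:4, n * 17, TRUE, spec$seg_probs), n, 17)
  bmipp <- copy * stress + (1 - copy) * indep
  sss <- rowSums(stress)
  srs <- rowSums(rest)
  sds <- rowSums(pmax(stress - rest, 0))
  sbs <- rowSums(bmipp)
  x <- cbind(dm = dm, sss = sss, srs = srs, sds = sds, sbs = sbs,
             lvef = lvef, age = age, sex_male = sex_male)
  lp <- if (length(spec$beta))
    drop(x[, names(spec$beta), drop = FALSE] %*% spec$beta) else rep(0, n)
  rate <- spec$baseline_rate * exp(lp)
  if (all(1 - exp(-rate * spec$censor_days) < 1 / n))
    warning("hazard implies fewer than one expected event before censoring")
  t_event <- stats::rexp(n, rate)
  observed <- t_event <= spec$censor_days
  followup <- round(pmin(t_event, spec$censor_days), 1)
  hard <- stats::rbinom(n, 1, spec$hard_prob) == 1
  event <- ifelse(observed, ifelse(hard, "hard", "soft"), "none")
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = age, sex = ifelse(sex_male == 1, "male", "female"),
    dm = dm, lvef = lvef, htn = htn, dyslipidemia = dys, smoking = smo,
    uap = uap, ace = ace, bb = bb, ccb = ccb,
    sss = sss, srs = srs, sds = sds, sbs = sbs,
    followup_days = followup, event = event,
    stringsAsFactors = FALSE)
}

cohort_columns <- c("id", "age", "sex", "dm", "lvef", "htn", "dyslipidemia",
                    "smoking", "uap", "ace", "bb", "ccb",
                    "sss", "srs", "sds", "sbs", "followup_days", "event")

#' Validate a cohort table against the CSV schema
#'
#' Required columns: id, age, sex, dm, lvef, htn, dyslipidemia, smoking,
#' uap, ace, bb, ccb, sss, srs, sds, sbs, followup_days, event.
#' `event` must be one of `none`, `soft`, `hard`; `followup_days` must be
#' non-negative; LVEF in (0, 100]; summed scores in `[0, 68]`.
#'
#' @param cohort a data frame.
#' @return The validated data frame (invisibly unchanged), or an error
#'   listing every offending column.
#' @export
validate_cohort <- function(cohort) {
  problems <- character(0)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    problems <- c(problems, paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    if (!all(cohort$event %in% c("none", "soft", "hard")))
      problems <- c(problems, "event: values outside none/soft/hard")
    if (any(is.na(cohort$followup_days)) || any(cohort$followup_days < 0))
      problems <- c(problems, "followup_days: negative or missing")
    if (any(is.na(cohort$lvef)) || any(cohort$lvef <= 0 | cohort$lvef > 100))
      problems <- c(problems, "lvef: outside (0, 100]")
    for (sc in c("sss", "srs", "sds", "sbs"))
      if (any(is.na(cohort[[sc]])) || any(cohort[[sc]] < 0 | cohort[[sc]] > 68))
        problems <- c(problems, paste0(sc, ": outside [0, 68]"))
  }
  if (length(problems))
    stop("cohort schema violation:\n  ", paste(problems, collapse = "\n  "))
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' @param cohort validated cohort data frame.
#' @param path output path.
#' @param header_comment optional provenance lines written as `#`-comments.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, header_comment = NULL) {
  validate_cohort(cohort)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' @param path CSV path.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_cohort(df)
  df
}

#' Event indicator for an event class
#'
#' `ALL` counts soft and hard events; `HARD` counts hard events only, with
#' soft events treated according to `soft_policy`: `"censor"` (default)
#' censors them at their event time, `"exclude"` drops those patients.
#'
#' @param cohort cohort data frame.
#' @param event_class `"ALL"` or `"HARD"`.
#' @param soft_policy `"censor"` or `"exclude"` (HARD analysis only).
#' @return List with `time`, `event` (logical) and `keep` (row filter used).
#' @export
event_indicator <- function(cohort, event_class = c("ALL", "HARD"),
                            soft_policy = c("censor", "exclude")) {
  event_class <- match.arg(event_class)
  soft_policy <- match.arg(soft_policy)
  keep <- rep(TRUE, nrow(cohort))
  if (event_class == "ALL") {
    ev <- cohort$event %in% c("soft", "hard")
  } else {
    if (soft_policy == "exclude") keep <- cohort$event != "soft"
    ev <- cohort$event == "hard"
  }
  list(time = cohort$followup_days[keep], event = ev[keep], keep = keep)
}
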