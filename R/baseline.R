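#' Baseline comparison table between event and non-event groups
#'
#' Compares each covariate between patients with and without events of the
#' requested class: continuous variables as mean +/- SD with a Welch
#' unpaired t-test, categorical variables as counts and percent with a
#' Pearson chi-square test (no continuity correction). Abnormal-score rows
#' (summed score >= cutoff) are included as categorical variables.
#'
#' @param cohort cohort data frame (see [validate_cohort()]).
#' @param event_class `"ALL"` or `"HARD"`.
#' @param cutoff abnormality cutoff for the score rows (default 4).
#' @return Data frame with columns `variable`, `type`, `event_summary`,
#'   `noevent_summary`, `p`, plus `event_n` / `noevent_n` group sizes in the
#'   attribute `group_n`.
#' @export
baseline_table <- function(cohort, event_class = c("ALL", "HARD"),
                           cutoff = 4L) {
  validate_cohort(cohort)
  event_class <- match.arg(event_class)
  ev <- if (event_class == "ALL") cohort$event %in% c("soft", "hard")
        else cohort$event == "hard"
  if (sum(ev) < 2L || sum(!ev) < 2L)
    stop("need at least 2 patients in each group")
  continuous <- c(age = "age", lvef = "lvef", SSS = "sss", SRS = "srs",
                  SDS = "sds", SBS = "sbs")
  categorical <- c(`male sex` = NA, `unstable angina` = "uap",
                   smoking = "smoking", diabetes = "dm",
                   hypertension = "htn", dyslipidemia = "dyslipidemia",
                   `ACE inhibitors` = "ace", `beta blockers` = "bb",
                   `calcium channel blockers` = "ccb")
  rows <- list()
  fmt_cont <- function(v, g) sprintf("%.1f ± %.1f", mean(v[g]),
                                     stats::sd(v[g]))
  fmt_cat <- function(v, g) sprintf("%d/%d (%.1f %%)", sum(v[g]), sum(g),
                                    100 * sum(v[g]) / sum(g))
  add_cat <- function(label, v) {
    tab <- matrix(c(sum(v[ev]), sum(!v[ev]), sum(v[!ev]), sum(!v[!ev])),
                  2, byrow = TRUE)
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    if (is.nan(p)) p <- NA_real_ # a margin of zeros
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = label, type = "categorical",
      event_summary = fmt_cat(v, ev), noevent_summary = fmt_cat(v, !ev),
      p = p)
  }
  for (nm in names(continuous)) {
    v <- cohort[[continuous[nm]]]
    p <- tryCatch(stats::t.test(v[ev], v[!ev])$p.value,
                  error = function(e) NA_real_) # constant data
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, type = "continuous",
      event_summary = fmt_cont(v, ev), noevent_summary = fmt_cont(v, !ev),
      p = p)
  }
  add_cat("male sex", cohort$sex == "male")
  for (nm in setdiff(names(categorical), "male sex"))
    add_cat(nm, cohort[[categorical[nm]]] == 1)
  for (sc in c("sss", "srs", "sds", "sbs"))
    add_cat(paste0(toupper(sc), " >= ", cutoff),
            classify_abnormal(cohort[[sc]], cutoff))
  out <- do.call(rbind, rows)
  attr(out, "group_n") <- c(event_n = sum(ev), noevent_n = sum(!ev))
  out
}
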