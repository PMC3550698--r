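#' Build a 2x2 contingency table of score flag against events
#'
#' Positive = abnormal score; outcome = cardiac event. `TP` = abnormal with
#' event, `FN` = normal with event, `FP` = abnormal without event, `TN` =
#' normal without event.
#'
#' @param cohort cohort data frame (see [validate_cohort()]).
#' @param score_flag logical per-patient abnormality flag, aligned with rows.
#' @param event_class `"ALL"` (soft + hard) or `"HARD"` (hard only).
#' @return A `contingency_table`: list with `TP`, `FP`, `FN`, `TN`.
#' @export
make_contingency <- function(cohort, score_flag,
                             event_class = c("ALL", "HARD")) {
  event_class <- match.arg(event_class)
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (length(score_flag) != nrow(cohort))
    stop("`score_flag` must align with cohort rows")
  ev <- if (event_class == "ALL") cohort$event %in% c("soft", "hard")
        else cohort$event == "hard"
  contingency_table(TP = sum(score_flag & ev), FP = sum(score_flag & !ev),
                    FN = sum(!score_flag & ev), TN = sum(!score_flag & !ev))
}

#' Construct a contingency table from its four cells
#'
#' @param TP,FP,FN,TN non-negative integer cell counts.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(TP, FP, FN, TN) {
  cells <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative")
  if (sum(cells) == 0) stop("contingency table is empty")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> TP %d  FP %d  FN %d  TN %d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Positive and negative predictive values
#'
#' PPV = TP / (TP + FP) x 100; NPV = TN / (TN + FN) x 100. Values are
#' reported both unrounded and rounded to the nearest integer percent. An
#' empty denominator leaves that value `NA` (undefined), never zero.
#'
#' @param table a `contingency_table`.
#' @return List with `ppv`, `npv` (percent, unrounded), `ppv_rounded`,
#'   `npv_rounded`, and logical `ppv_defined`, `npv_defined`.
#' @export
predictive_values <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  ppv_den <- table$TP + table$FP
  npv_den <- table$TN + table$FN
  ppv <- if (ppv_den > 0) table$TP / ppv_den * 100 else NA_real_
  npv <- if (npv_den > 0) table$TN / npv_den * 100 else NA_real_
  list(ppv = ppv, npv = npv,
       ppv_rounded = if (is.na(ppv)) NA_real_ else round(ppv),
       npv_rounded = if (is.na(npv)) NA_real_ else round(npv),
       ppv_defined = ppv_den > 0, npv_defined = npv_den > 0)
}

#' Combine two abnormality flags
#'
#' `AND`: abnormal only if both scores are abnormal; `OR`: abnormal if
#' either is. Used to build combined contingency tables (e.g. SSS and/or
#' SBS).
#'
#' @param a,b logical flags (vectorized).
#' @param mode `"AND"` or `"OR"`.
#' @return Logical combined flag.
#' @export
combine_flags <- function(a, b, mode = c("AND", "OR")) {
  mode <- match.arg(mode)
  if (mode == "AND") a & b else a | b
}

#' Predictive-value table over scores, combinations and event classes
#'
#' For each of SSS, SBS, SSS AND SBS, SSS OR SBS, and each event class
#' (ALL, HARD), builds the contingency table at the given cutoff and reports
#' predictive values: 8 rows in total.
#'
#' @param cohort cohort data frame.
#' @param cutoff abnormality cutoff (default 4).
#' @return Data frame with columns `score`, `event_class`, `TP`, `FP`, `FN`,
#'   `TN`, `ppv`, `npv`, `ppv_rounded`, `npv_rounded`.
#' @export
predictive_value_table <- function(cohort, cutoff = 4L) {
  validate_cohort(cohort)
  f_sss <- classify_abnormal(cohort$sss, cutoff)
  f_sbs <- classify_abnormal(cohort$sbs, cutoff)
  flags <- list(SSS = f_sss, SBS = f_sbs,
                `SSS_AND_SBS` = combine_flags(f_sss, f_sbs, "AND"),
                `SSS_OR_SBS` = combine_flags(f_sss, f_sbs, "OR"))
  rows <- list()
  for (ec in c("ALL", "HARD")) {
    for (nm in names(flags)) {
      tab <- make_contingency(cohort, flags[[nm]], ec)
      pv <- predictive_values(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        score = nm, event_class = ec,
        TP = tab$TP, FP = tab$FP, FN = tab$FN, TN = tab$TN,
        ppv = pv$ppv, npv = pv$npv,
        ppv_rounded = pv$ppv_rounded, npv_rounded = pv$npv_rounded)
    }
  }
  do.call(rbind, rows)
}
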