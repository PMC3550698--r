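#' ROC AUC of a score against event labels
#'
#' AUC as the normalized Mann-Whitney U statistic (ties count one half),
#' with higher scores taken as more abnormal. Backed by [pROC::roc()].
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) event labels; both classes must be present.
#' @return A `roc_result`: list with `auc` and the underlying `roc` object.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute an AUC")
  r <- pROC::roc(response = labels, predictor = scores,
                 direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(r)), roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f\n", x$auc))
  invisible(x)
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired comparison of two ROC curves computed on the same patients, using
#' the DeLong variance of the difference of the two U-statistics.
#'
#' @param a,b `roc_result` objects built on the same labels.
#' @return List with `auc_a`, `auc_b` and `p`.
#' @export
delong_compare <- function(a, b) {
  stopifnot(inherits(a, "roc_result"), inherits(b, "roc_result"))
  tst <- pROC::roc.test(a$roc, b$roc, method = "delong", paired = TRUE)
  list(auc_a = a$auc, auc_b = b$auc, p = tst$p.value)
}
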