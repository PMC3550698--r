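#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the event-free survival function; patients
#' without an event are censored at the end of their follow-up. Backed by
#' [survival::survfit()].
#'
#' @param times follow-up times in days (>= 0).
#' @param events logical event indicators.
#' @return Data frame `(time, n_risk, n_event, surv)`: the step function
#'   S(t) evaluated at each distinct event/censoring time.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(is.na(times)) || any(times < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Evaluate a KM step function at arbitrary times
#'
#' @param km data frame from [km_estimate()].
#' @param t times at which to evaluate S(t).
#' @return Survival probabilities (1 before the first event time).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    below <- km$time <= tt & km$n_event > 0
    if (!any(below)) 1 else min(km$surv[km$time <= tt])
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank comparison of event-free survival between two
#' groups, via [survival::survdiff()]. With no events in either group the
#' statistic is 0 and p = 1.
#'
#' @param times_a,events_a follow-up times and event indicators, group A.
#' @param times_b,events_b follow-up times and event indicators, group B.
#' @return List with `chisq` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must contain at least one subject")
  if (sum(events_a) + sum(events_b) == 0)
    return(list(chisq = 0, p = 1))
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron approximation for ties. Reports per
#' covariate the hazard ratio, Wald 95% CI and p-value, plus the model
#' log-likelihood and the global chi-square (likelihood ratio against the
#' null model).
#'
#' @param cohort cohort data frame (see [validate_cohort()]).
#' @param covariates character vector of cohort column names (numeric or
#'   0/1 coded).
#' @param event_class `"ALL"` or `"HARD"`.
#' @param soft_policy soft-event handling for HARD analysis
#'   (see [event_indicator()]).
#' @return A `survival_fit`: list with `table` (term, hr, ci_lower,
#'   ci_upper, p), `loglik`, `loglik_null`, `global_chisq`, `global_p`,
#'   `n_events`, `covariates`, and the underlying `coxph` object as `fit`.
#' @export
cox_fit <- function(cohort, covariates, event_class = c("ALL", "HARD"),
                    soft_policy = c("censor", "exclude")) {
  ind <- event_indicator(cohort, match.arg(event_class),
                         match.arg(soft_policy))
  dat <- cohort[ind$keep, , drop = FALSE]
  missing_cov <- setdiff(covariates, names(dat))
  if (length(missing_cov))
    stop("covariates not in cohort: ", paste(missing_cov, collapse = ", "))
  if (sum(ind$event) < 1L) stop("no events of the requested class; Cox model refused")
  X <- as.matrix(dat[, covariates, drop = FALSE])
  if (any(apply(X, 2, function(v) length(unique(v)) == 1L)))
    stop("constant covariate(s): ",
         paste(covariates[apply(X, 2, function(v)
           length(unique(v)) == 1L)], collapse = ", "))
  if (qr(scale(X, scale = FALSE))$rank < ncol(X))
    stop("collinear covariates: design matrix is rank-deficient")
  dat$.time <- ind$time
  dat$.event <- as.integer(ind$event)
  fml <- stats::reformulate(covariates, response = "survival::Surv(.time, .event)")
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations", conditionMessage(w)))
        stop("Cox fit failed to converge (possible complete separation): ",
             conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = dat, ties = "efron"))
    })
  if (any(is.na(stats::coef(fit))))
    stop("Cox fit produced undefined coefficients (collinearity)")
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    hr = unname(sm$coefficients[, "exp(coef)"]),
    ci_lower = unname(sm$conf.int[, "lower .95"]),
    ci_upper = unname(sm$conf.int[, "upper .95"]),
    p = unname(sm$coefficients[, "Pr(>|z|)"]))
  structure(
    list(table = tab,
         loglik = fit$loglik[2], loglik_null = fit$loglik[1],
         global_chisq = 2 * (fit$loglik[2] - fit$loglik[1]),
         global_p = stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]),
                                  df = length(covariates), lower.tail = FALSE),
         n_events = sum(ind$event), covariates = covariates, fit = fit),
    class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> %d events; global chi-square %.2f (p = %.3g)\n",
              x$n_events, x$global_chisq, x$global_p))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Global chi-square increment between nested Cox models
#'
#' Measures the added prognostic value of the covariates the extended model
#' adds to the base model: the difference of global (likelihood-ratio)
#' chi-squares, referred to a chi-square distribution with df = number of
#' added covariates.
#'
#' @param base_fit,extended_fit `survival_fit` objects; the extended model's
#'   covariates must strictly contain the base model's.
#' @return List with `delta_chisq`, `df` and `p`.
#' @export
chi2_increment <- function(base_fit, extended_fit) {
  stopifnot(inherits(base_fit, "survival_fit"),
            inherits(extended_fit, "survival_fit"))
  if (!all(base_fit$covariates %in% extended_fit$covariates))
    stop("models are not nested: base covariates must be a subset of extended")
  added <- setdiff(extended_fit$covariates, base_fit$covariates)
  d <- extended_fit$global_chisq - base_fit$global_chisq
  df <- length(added)
  list(delta_chisq = d, df = df,
       p = if (df > 0) stats::pchisq(max(d, 0), df, lower.tail = FALSE)
           else NA_real_)
}
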