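#' Median split of a cohort by expression
#'
#' Samples with expression strictly above the sample median are labelled
#' `high`; samples at or below the median are labelled `low` (the declared
#' tie rule, so the two halves differ in size by at most the number of
#' median ties).
#'
#' @param cohort data.frame with at least an `expression` column (the
#'   shape returned by [gen_survival_cohort()]).
#' @return factor of `"low"` / `"high"` labels, one per sample.
#' @export
median_split <- function(cohort) {
  x <- cohort$expression
  if (length(x) < 2) stop("need >= 2 samples to split")
  med <- stats::median(x)
  if (all(x == x[1])) stop("all expression values equal: no split possible")
  factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Estimates `S(t)` as the product over event times up to `t` of
#' `(1 - d_i / n_i)`; censored times reduce the risk set without steps.
#' Median survival is the smallest time with `S(t) <= 0.5`, `NA` when the
#' curve never reaches 0.5.
#'
#' @param time non-negative follow-up times (months).
#' @param event 1 = event observed, 0 = censored.
#' @return A `km_curve` list: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (the step values at each distinct time) and `median`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need >= 1 sample")
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  surv <- fit$surv
  hit <- which(surv <= 0.5)
  med <- if (length(hit)) fit$time[min(hit)] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = surv, median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d distinct times, %d events, median %s\n",
              length(x$time), sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct event time a 2x2 table contributes observed and
#' expected events and a hypergeometric variance; the statistic is
#' `(O_A - E_A)^2 / V`, referred to a chi-square distribution with 1
#' degree of freedom.  When no event time is comparable (zero total
#' variance) the test returns `p = 1` with a warning.
#'
#' @param time,event follow-up times and 0/1 event flags.
#' @param group two-level grouping (e.g. the [median_split()] labels).
#' @return A `logrank_result` list: per-group `observed` and `expected`
#'   event counts, `var` (the variance of `O - E`), `chisq`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) stop("log-rank test needs exactly 2 non-empty groups")
  if (sum(event) < 1) stop("need >= 1 event")
  sd_fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group),
    error = function(e) NULL)
  if (is.null(sd_fit) || !is.finite(sd_fit$chisq) || sd_fit$var[1, 1] == 0) {
    warning("no comparable event times: zero log-rank variance, p = 1")
    obs <- tapply(event, group, sum)
    return(structure(list(observed = obs, expected = obs, var = 0,
                          chisq = 0, p_value = 1),
                     class = "logrank_result"))
  }
  v <- sd_fit$var[1, 1]
  chisq <- sd_fit$chisq
  structure(list(observed = stats::setNames(sd_fit$obs, levels(group)),
                 expected = stats::setNames(sd_fit$exp, levels(group)),
                 var = v, chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test\n")
  print(data.frame(observed = x$observed, expected = x$expected))
  cat(sprintf("chisq = %.4g (1 df), p = %.4g\n", x$chisq, x$p_value))
  invisible(x)
}

#' Median-split survival analysis of a cohort
#'
#' Convenience wrapper composing [median_split()], per-group
#' [km_estimate()] and [logrank_test()], mirroring the overall-survival
#' comparison of the top and bottom expression halves of a cohort.
#'
#' @param cohort data.frame with `time_months`, `event`, `expression`.
#' @param alpha significance level for the reported decision.
#' @return list with `groups`, `km` (named list of `km_curve`s for `low`
#'   and `high`), `logrank`, `medians` (named numeric) and `significant`.
#' @export
survival_stratification <- function(cohort, alpha = 0.05) {
  g <- median_split(cohort)
  km <- lapply(split(seq_len(nrow(cohort)), g), function(idx)
    km_estimate(cohort$time_months[idx], cohort$event[idx]))
  lr <- logrank_test(cohort$time_months, cohort$event, g)
  list(groups = g, km = km, logrank = lr,
       medians = vapply(km, `[[`, numeric(1), "median"),
       significant = lr$p_value < alpha)
}
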