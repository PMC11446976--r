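#' @include AllClasses.R
NULL

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates via \code{survival::survfit}; without censoring
#' the estimate equals the empirical survivor function.
#'
#' @param times follow-up times (months).
#' @param events event indicators (1 = death, 0 = censored).
#' @param groups group labels (a single group when omitted).
#' @return data.frame: group, time, n_risk, n_event, n_censor, surv.
#' @export
kmFit <- function(times, events, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(times))
  df <- data.frame(time = times, event = events, group = factor(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(levels(df$group)[1], length(smry$time))
    else sub("^group=", "", as.character(smry$strata))
  data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
             n_event = smry$n.event, n_censor = smry$n.censor,
             surv = smry$surv, stringsAsFactors = FALSE)
}

#' Multi-group log-rank test
#'
#' \code{survival::survdiff} chi-squared test on k groups
#' (df = k - 1); invariant under relabeling of group names.
#'
#' @inheritParams kmFit
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
logrankTest <- function(times, events, groups) {
  df <- data.frame(time = times, event = events, group = factor(groups))
  if (nlevels(df$group) < 2L) stop("need at least 2 groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd_$n) - 1L
  list(chi2 = unname(sd_$chisq), df = dfree,
       p = stats::pchisq(sd_$chisq, dfree, lower.tail = FALSE))
}

#' Multivariate Cox proportional hazards for subgroup prognosis
#'
#' Partial-likelihood Cox regression (Efron tie handling) of overall
#' survival on sex, age, pathological stage and molecular subgroup, with
#' the immune-high subgroup as the reference level so subtype hazard
#' ratios read as HR versus I.  Stage is coded ordinally I < II < III by
#' default (\code{stageCoding = "factor"} dummy-codes it instead).  A
#' subtype stratum with zero events among those compared is an error naming
#' the stratum, as the partial likelihood cannot identify its coefficient.
#'
#' @param clinical clinical data.frame (sample, sex, age, stage,
#'   os_time_months, os_event).
#' @param labels named subgroup labels; merged onto the clinical table by
#'   sample id.
#' @param covariates subset of \code{c("sex", "age", "stage", "subtype")}.
#' @param reference reference subtype level (default \code{"I"}).
#' @param stageCoding \code{"ordinal"} (1/2/3) or \code{"factor"}.
#' @return list with \code{fit} (the \code{coxph} object) and \code{table}
#'   (data.frame: term, beta, hr, ci_lower, ci_upper, p).
#' @export
coxphFit <- function(clinical, labels,
                     covariates = c("sex", "age", "stage", "subtype"),
                     reference = "I",
                     stageCoding = c("ordinal", "factor")) {
  stageCoding <- match.arg(stageCoding)
  df <- clinical
  if ("subtype" %in% covariates) {
    df$subtype <- labels[df$sample]
    if (anyNA(df$subtype)) stop("labels do not cover every clinical sample")
    events <- tapply(df$os_event, df$subtype, sum)
    zero <- names(events)[events == 0]
    if (length(zero))
      stop("zero-event subtype stratum: ", paste(zero, collapse = ", "))
    df$subtype <- stats::relevel(factor(df$subtype), ref = reference)
  }
  if ("stage" %in% covariates)
    df$stage <- if (stageCoding == "ordinal")
      as.numeric(factor(df$stage, levels = c("I", "II", "III")))
    else factor(df$stage, levels = c("I", "II", "III"))
  if ("sex" %in% covariates) df$sex <- factor(df$sex, levels = c("F", "M"))
  fml <- stats::as.formula(paste("survival::Surv(os_time_months, os_event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
      if (any(!is.finite(sqrt(diag(f$var)))) ||
          any(abs(stats::coef(f)) > 15))
        stop("Cox fit numerically unstable (possible separation): ",
             conditionMessage(w))
      f
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    beta = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  list(fit = fit, table = tab)
}
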