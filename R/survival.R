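# Median-split stratification, Kaplan-Meier curves, log-rank testing and Cox
# proportional-hazards fitting for anchor-gene prognosis. Estimation is
# delegated to the survival package (Efron tie handling); this module fixes
# the stratification and reporting conventions.

#' Median-split stratification
#'
#' Samples above the median are labelled `high`, samples below `low`; ties at
#' the median are assigned to `low` deterministically.
#'
#' @param expr numeric vector of per-sample expression (>= 2 samples).
#' @return factor with levels `low`, `high`, aligned with `expr`.
#' @export
stratify_by_median <- function(expr) {
  if (length(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(expr)) == 1L)
    stop("all values identical: no median stratification possible", call. = FALSE)
  m <- median(expr)
  factor(ifelse(expr > m, "high", "low"), levels = c("low", "high"))
}

validate_survival_table <- function(table) {
  need <- c("time", "event", "group")
  if (!all(need %in% names(table)))
    stop("survival table needs columns time, event, group", call. = FALSE)
  if (any(table$time < 0)) stop("negative survival times", call. = FALSE)
  if (!all(table$event %in% c(0, 1)))
    stop("event indicator must be 0/1", call. = FALSE)
  invisible(table)
}

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimator for the samples of `table` belonging to `group`.
#' Censored times reduce the risk set without dropping the curve.
#'
#' @param table survival data.frame (time, event, group, ...).
#' @param group group label to estimate (default: all samples).
#' @return data.frame (time, n_risk, n_event, n_censor, survival); survival
#'   starts at 1 and is non-increasing.
#' @export
km_curve <- function(table, group = NULL) {
  validate_survival_table(table)
  if (!is.null(group)) {
    table <- table[table$group == group, , drop = FALSE]
    if (!nrow(table)) stop(sprintf("group '%s' is empty", group), call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank test of the high/low groups: observed minus expected
#' events summed over event times, chi-square with 1 df.
#'
#' @param table survival data.frame (time, event, group).
#' @return list (chisq, p, obs, exp) where obs/exp are per-group event
#'   counts.
#' @export
logrank_test <- function(table) {
  validate_survival_table(table)
  if (length(unique(table$group)) < 2L)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(table$event) == 0L) stop("no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = table)
  list(chisq = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Cox proportional-hazards fit on the group indicator
#'
#' Fits a single-covariate Cox model (high vs low) by partial-likelihood
#' maximization with Efron handling of tied event times, and reports the
#' Wald test. Monotone likelihood (complete separation) is reported via
#' `converged = FALSE`.
#'
#' @param table survival data.frame (time, event, group).
#' @param conf_level confidence level for the reported HR interval.
#' @return one-row data.frame of class `cox_fit`: (beta, hr, se, z, p,
#'   ci_low, ci_high, converged).
#' @export
cox_hazard_ratio <- function(table, conf_level = 0.95) {
  validate_survival_table(table)
  if (length(unique(table$group)) < 2L)
    stop("both covariate levels must be present", call. = FALSE)
  if (sum(table$event) == 0L) stop("no events observed", call. = FALSE)
  table$g <- as.integer(table$group == "high")
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, data = table,
                    ties = "efron", control = survival::coxph.control(
                      eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit)); se <- sqrt(unname(fit$var[1, 1]))
  z <- beta / se
  converged <- !warned && is.finite(beta) && abs(beta) < 15
  q <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(beta = beta, hr = exp(beta), se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    ci_low = exp(beta - q * se), ci_high = exp(beta + q * se),
                    converged = converged)
  class(out) <- c("cox_fit", class(out))
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (high vs low): HR = %.3f [%.3f, %.3f], p = %.3g%s\n",
              x$hr, x$ci_low, x$ci_high, x$p,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' @importFrom stats coef
NULL
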