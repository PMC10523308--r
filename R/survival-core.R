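#' Multivariable Cox proportional hazards fit
#'
#' Thin wrapper around [survival::coxph()] returning the pieces the rest of
#' the pipeline consumes: log hazard ratios, standard errors from the
#' observed-information inverse, and per-feature Wald statistics on the
#' squared-z scale, `(beta/se)^2`, referred to chi-square with 1 df.
#'
#' @param x numeric covariate matrix, samples in rows.
#' @param time positive follow-up times in months.
#' @param event 0/1 indicator (1 = recurrence/progression).
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: `coefficients`, `se`, `wald`,
#'   `loglik` (at the MLE), `loglik_null`, `converged`, `n`, `n_events`.
#' @export
fit_cox <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  if (any(!is.finite(x))) stop("covariates must be finite")
  if (sum(event) == 0) stop("no events: Cox model undefined")
  varying <- apply(x, 2, function(v) length(unique(v)) > 1)
  p <- ncol(x)
  beta <- se <- wald <- rep(0, p)
  se[!varying] <- Inf
  if (!any(varying)) {
    # no covariate variation: the score at beta = 0 vanishes
    ll <- cox_univariate_batch(matrix(0, nrow(x), 1), time, event,
                               max_iter = 1)$loglik_null
    return(structure(list(coefficients = stats::setNames(beta, colnames(x)),
                          se = stats::setNames(se, colnames(x)),
                          wald = stats::setNames(wald, colnames(x)),
                          loglik = ll, loglik_null = ll, converged = TRUE,
                          n = nrow(x), n_events = sum(event), ties = ties),
                     class = "cox_fit"))
  }
  if (sum(event) < 2) stop("need at least 2 events")
  xv <- x[, varying, drop = FALSE]
  fit <- survival::coxph(survival::Surv(time, event) ~ xv, ties = ties)
  b <- unname(coef(fit))
  b[is.na(b)] <- 0
  beta[varying] <- b
  se[varying] <- sqrt(diag(fit$var))
  wald[varying] <- ifelse(se[varying] > 0, (beta[varying] / se[varying])^2, 0)
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 wald = stats::setNames(wald, colnames(x)),
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 converged = is.null(fit$info) || fit$iter < fit$control$iter.max,
                 n = nrow(x), n_events = sum(event), ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties), ",
      x$n, " samples, ", x$n_events, " events\n", sep = "")
  print(data.frame(coef = x$coefficients, HR = exp(x$coefficients),
                   se = x$se, wald = x$wald,
                   p = stats::pchisq(x$wald, 1, lower.tail = FALSE)))
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' @inheritParams fit_cox
#' @return object of class `km_curve` with steps only at observed event
#'   times: `times`, `survival`, `at_risk`, `n_events_at`, plus totals.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (length(time) == 0) stop("empty cohort")
  if (any(time <= 0)) stop("times must be strictly positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n_events_at = fit$n.event[keep],
                 n = length(time), n_events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "samples,", x$n_events, "events\n")
  print(data.frame(time = x$times, at_risk = x$at_risk,
                   events = x$n_events_at, survival = x$survival))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival", ...) {
  tt <- c(0, rep(x$times, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * length(x$survival))])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function lookup of the survival estimate.
#'
#' @param km [kaplan_meier()] result.
#' @param t times (months).
#' @return survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    below <- km$times <= ti
    if (!any(below)) 1 else km$survival[max(which(below))]
  }, numeric(1))
}

#' Log-rank test for group differences in survival
#'
#' @inheritParams fit_cox
#' @param group group labels (>= 2 distinct values).
#' @return object of class `ptc_test`: `statistic`, `df`, `p_value`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least 2 groups")
  if (sum(event) == 0) stop("need at least 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 method = "log-rank"),
            class = "ptc_test")
}

#' @export
print.ptc_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' @param table matrix of non-negative integer counts, >= 2 rows and
#'   columns, all margins positive.
#' @return object of class `ptc_test`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (nrow(table) < 2 || ncol(table) < 2) stop("need >= 2 rows and columns")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row/column margin")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(res$statistic), df = unname(res$parameter),
                 p_value = res$p.value, method = "Pearson chi-square"),
            class = "ptc_test")
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by summing hypergeometric point probabilities no
#' larger than the observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return object of class `ptc_test` (`df` is `NA`).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) == 2)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  res <- stats::fisher.test(table)
  structure(list(statistic = unname(table[1, 1]), df = NA_integer_,
                 p_value = res$p.value, method = "Fisher exact"),
            class = "ptc_test")
}

#' Kruskal-Wallis rank-sum test
#'
#' @param values numeric vector, or a list of per-group numeric vectors
#'   (in which case `group` is ignored).
#' @param group group labels aligned with `values`.
#' @return object of class `ptc_test`. All-identical values give
#'   statistic 0 and p = 1 rather than an error.
#' @export
kruskal_wallis <- function(values, group = NULL) {
  if (is.list(values)) {
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least 2 groups")
  if (length(unique(values)) < 2) {
    return(structure(list(statistic = 0,
                          df = nlevels(droplevels(group)) - 1L,
                          p_value = 1, method = "Kruskal-Wallis"),
                     class = "ptc_test"))
  }
  res <- stats::kruskal.test(values, group)
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter), p_value = res$p.value,
                 method = "Kruskal-Wallis"),
            class = "ptc_test")
}

#' Time-dependent cumulative/dynamic AUROC with IPCW
#'
#' AUC at a fixed horizon for distinguishing cumulative cases (event by
#' the horizon) from dynamic controls (still event-free past it), with
#' inverse-probability-of-censoring weights from the Kaplan-Meier
#' estimate of the censoring distribution. Cases are weighted by
#' `1/G(T_i-)`, controls by `1/G(horizon)`; tied marker values count 1/2.
#' The estimate is invariant to strictly monotone transforms of the
#' marker.
#'
#' @param marker per-sample risk score, higher = higher presumed hazard.
#' @inheritParams fit_cox
#' @param horizon evaluation time in months (60 = the 5-year convention).
#' @return object of class `td_auc`: `horizon`, `auc`, `n_cases`,
#'   `n_controls`.
#' @export
cumulative_dynamic_auc <- function(marker, time, event, horizon) {
  stopifnot(length(marker) == length(time), length(time) == length(event))
  if (any(!is.finite(marker))) stop("marker must be finite")
  is_case <- time <= horizon & event == 1
  is_control <- time > horizon
  if (!any(is_case)) stop("no cases by the horizon")
  if (!any(is_control)) stop("no controls past the horizon")
  # censoring KM: G(t) = P(censoring time > t)
  cens_km <- kaplan_meier(time, 1 - event)
  g_at <- function(t) km_surv_at(cens_km, t)
  g_minus <- function(t) {            # left limit G(t-)
    vapply(t, function(ti) {
      below <- cens_km$times < ti
      if (!any(below)) 1 else cens_km$survival[max(which(below))]
    }, numeric(1))
  }
  w_case <- 1 / g_minus(time[is_case])
  w_ctrl <- rep(1 / g_at(horizon), sum(is_control))
  m_case <- marker[is_case]
  m_ctrl <- marker[is_control]
  # weighted probability that a case outranks a control
  gt <- outer(m_case, m_ctrl, `>`)
  eq <- outer(m_case, m_ctrl, `==`)
  wmat <- outer(w_case, w_ctrl)
  auc <- sum(wmat * (gt + 0.5 * eq)) / sum(wmat)
  structure(list(horizon = horizon, auc = auc,
                 n_cases = sum(is_case), n_controls = sum(is_control)),
            class = "td_auc")
}

#' @export
print.td_auc <- function(x, ...) {
  cat(sprintf("IPCW cumulative/dynamic AUC at %g months: %.3f (%d cases, %d controls)\n",
              x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}
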