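#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and repackages the curve with Greenwood
#' standard errors and the step-function median (earliest time at which the
#' survival estimate drops to 0.5 or below; undefined when never reached).
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return a `ctb_km` object: `time`, `at_risk`, `events`, `censored`,
#'   `survival`, `greenwood_se`, `median`, `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L) stop_ctb("km_estimate: empty input")
  if (any(times < 0)) stop_ctb("km_estimate: negative times")
  fit <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1,
                           conf.type = "none")
  d <- fit$n.event; n <- fit$n.risk
  # Greenwood: se(S) = S * sqrt( sum d / (n (n - d)) ); 0/0 at S = 0 -> NA
  gterm <- ifelse(n > d, d / (n * (n - d)), NA_real_)
  se <- fit$surv * sqrt(cumsum(ifelse(is.na(gterm), 0, gterm)))
  se[cumsum(is.na(gterm)) > 0 & fit$surv == 0] <- NA_real_
  structure(
    list(time = fit$time, at_risk = fit$n.risk, events = fit$n.event,
         censored = fit$n.censor, survival = fit$surv, greenwood_se = se,
         median = median_from_curve(fit$time, fit$surv), n = length(times)),
    class = "ctb_km"
  )
}

median_from_curve <- function(time, surv) {
  hit <- which(surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) NA_real_ else time[min(hit)]
}

#' Median survival from a Kaplan-Meier curve
#'
#' Step-function convention: the first observed time at which the estimated
#' survival is at or below one half; `NA` if the curve never reaches it.
#'
#' @param curve a `ctb_km` object.
#' @return months, or `NA` when undefined.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "ctb_km"))
  curve$median
}

#' @export
print.ctb_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median = %s\n",
              x$n, sum(x$events),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance, via
#' [survival::survdiff()]; p-value from the chi-square distribution with
#' (groups - 1) df.
#'
#' @param times,events as in [km_estimate()].
#' @param group grouping vector with >= 2 nonempty levels.
#' @return a `ctb_test_result` (method `"logrank"`).
#' @export
logrank_test <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) < 2L || any(table(g) == 0L))
    stop_ctb("logrank_test: need >= 2 nonempty groups")
  sd <- survival::survdiff(survival::Surv(times, as.numeric(events)) ~ g)
  df <- nlevels(g) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  new_test_result("logrank", sd$chisq, p, n = as.integer(table(g)),
                  notes = sprintf("df=%d", df))
}

#' Cox proportional-hazards fit
#'
#' Wraps [survival::coxph()] (Efron tie handling by default, Breslow
#' available for cross-checks) and returns a flat inference object with
#' hazard ratios, 95% Wald confidence intervals and per-coefficient Wald
#' tests. Monotone partial likelihoods (perfect separation: a coefficient
#' running away) and rank-deficient design matrices are reported as errors
#' rather than silently returned.
#'
#' @param x covariate data frame or matrix (column names kept as term names).
#' @param times,events survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a `ctb_cox` object: `terms`, `coef`, `se`, `hazard_ratio`,
#'   `ci_lower`, `ci_upper`, `wald_z`, `wald_p`, `loglik`, `score_stat`,
#'   `n`, `n_events`, `ties`, `vcov`, `fit` (the underlying coxph fit).
#' @export
cox_fit <- function(x, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.data.frame(x)
  if (sum(events) < 1) stop_ctb("cox_fit: no events")
  dat <- cbind(data.frame(.time = times, .event = as.numeric(events)), x)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(x)), collapse = " + ")))
  warned <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_ctb("cox_fit: rank-deficient design; collinear column(s): %s",
             paste(names(cf)[is.na(cf)], collapse = ", "),
             class = "ctb_degenerate_error")
  if (any(grepl("infinite|did not converge|out of iterations", warned,
                ignore.case = TRUE)) || any(abs(cf) > 15))
    stop_ctb(paste("cox_fit: monotone partial likelihood (coefficient",
                   "diverging); stratify or merge sparse cells: %s"),
             paste(names(cf)[abs(cf) == max(abs(cf))], collapse = ", "),
             class = "ctb_divergence_error")
  se <- sqrt(diag(stats::vcov(fit)))
  z <- cf / se
  structure(
    list(terms = names(cf), coef = unname(cf), se = unname(se),
         hazard_ratio = unname(exp(cf)),
         ci_lower = unname(exp(cf - 1.959963984540054 * se)),
         ci_upper = unname(exp(cf + 1.959963984540054 * se)),
         wald_z = unname(z), wald_p = unname(2 * stats::pnorm(-abs(z))),
         loglik = fit$loglik[2], score_stat = unname(fit$score),
         n = fit$n, n_events = fit$nevent, ties = ties,
         vcov = stats::vcov(fit), fit = fit),
    class = "ctb_cox"
  )
}

#' @export
print.ctb_cox <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d\n", x$ties, x$n, x$n_events))
  tab <- data.frame(term = x$terms, HR = round(x$hazard_ratio, 3),
                    lo95 = round(x$ci_lower, 3), hi95 = round(x$ci_upper, 3),
                    p = signif(x$wald_p, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Treatment-by-biomarker interaction analysis
#'
#' Fits a Cox model with treatment, biomarker-group and their product on the
#' chosen endpoint and reports the Wald p-value of the product term - the
#' test of whether the biomarker is predictive (modifies the treatment
#' effect) rather than merely prognostic. Also returns the within-stratum
#' treatment hazard ratios (biomarker-high and biomarker-low subsets) for
#' forest-style reporting.
#'
#' @param clinical clinical data frame with `arm`, `os_months`/`os_event`,
#'   `pfs_months`/`pfs_event`.
#' @param biomarker_group logical/0-1 vector aligned with `clinical` rows
#'   (TRUE = biomarker-high). Rows with `NA` are dropped.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param ties passed to [cox_fit()].
#' @return list: `fit` (ctb_cox), `interaction_p`, `interaction_coef`,
#'   `stratum_hr` (data frame: stratum, HR, ci, p, n, events), `endpoint`.
#' @export
interaction_analysis <- function(clinical, biomarker_group,
                                 endpoint = c("OS", "PFS"),
                                 ties = "efron") {
  endpoint <- match.arg(endpoint)
  marker <- as.logical(biomarker_group)
  keep <- !is.na(marker)
  cl <- clinical[keep, , drop = FALSE]
  marker <- marker[keep]
  treat <- cl$arm == "ICI"
  tm <- if (endpoint == "OS") cl$os_months else cl$pfs_months
  ev <- if (endpoint == "OS") cl$os_event else cl$pfs_event
  cells <- table(treat, marker)
  if (length(cells) < 4L || any(cells == 0L))
    stop_ctb("interaction_analysis: empty treatment x marker cell(s): %s",
             paste(c("comparator/low", "ICI/low", "comparator/high",
                     "ICI/high")[as.vector(cells) == 0], collapse = ", "),
             class = "ctb_degenerate_error")
  x <- data.frame(treatment = as.numeric(treat),
                  marker = as.numeric(marker),
                  treatment_x_marker = as.numeric(treat) * as.numeric(marker))
  fit <- cox_fit(x, tm, ev, ties = ties)
  k <- match("treatment_x_marker", fit$terms)

  stratum_hr <- do.call(rbind, lapply(c(TRUE, FALSE), function(hi) {
    sel <- marker == hi
    sf <- cox_fit(data.frame(treatment = as.numeric(treat[sel])),
                  tm[sel], ev[sel], ties = ties)
    data.frame(stratum = if (hi) "marker_high" else "marker_low",
               hr = sf$hazard_ratio[1], ci_lower = sf$ci_lower[1],
               ci_upper = sf$ci_upper[1], p = sf$wald_p[1],
               n = sf$n, events = sf$n_events, stringsAsFactors = FALSE)
  }))
  list(fit = fit, interaction_p = fit$wald_p[k],
       interaction_coef = fit$coef[k], stratum_hr = stratum_hr,
       endpoint = endpoint)
}
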