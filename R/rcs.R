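#' Restricted cubic spline basis (truncated-power construction)
#'
#' Builds the classical restricted cubic spline design: a linear column in
#' `x` followed by `k - 2` cubic columns that are identically zero at and
#' below the first knot and exactly linear at and above the last knot
#' (second derivatives vanish outside the knot span). Column `j + 1` is
#'
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'        + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#'
#' The division by the squared knot range keeps the nonlinear columns on
#' the scale of `x`, so Cox coefficients on this basis are comparable to
#' the linear slope.
#'
#' @param x numeric vector of covariate values.
#' @param knots ascending vector of >= 3 distinct knot locations.
#' @return matrix with `length(x)` rows and `k - 1` columns (`x`,
#'   `rcs1` ... `rcs(k-2)`).
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L || any(diff(knots) <= 0))
    stop_ctb("rcs_basis: need >= 3 distinct ascending knots",
             class = "ctb_config_error")
  k <- length(knots)
  t1 <- knots[1]; tkm1 <- knots[k - 1]; tk <- knots[k]
  norm <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  nl <- vapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pos3(x - tj) -
       pos3(x - tkm1) * (tk - tj) / (tk - tkm1) +
       pos3(x - tk) * (tkm1 - tj) / (tk - tkm1)) / norm
  }, numeric(length(x)))
  nl <- matrix(nl, nrow = length(x))
  out <- cbind(x, nl)
  colnames(out) <- c("x", paste0("rcs", seq_len(k - 2)))
  out
}

#' Default knot locations for a restricted cubic spline
#'
#' Quantile placements following the usual practice: 10/50/90 for 3 knots,
#' 5/35/65/95 for 4 (the default), 5/27.5/50/72.5/95 for 5.
#'
#' @param x covariate values.
#' @param k number of knots (3-5).
#' @return numeric vector of knot locations (sample quantiles, type 7).
#' @export
rcs_default_knots <- function(x, k = 4) {
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop_ctb("rcs_default_knots: k must be 3, 4 or 5",
                           class = "ctb_config_error"))
  kn <- unname(stats::quantile(x, probs, na.rm = TRUE))
  if (any(diff(kn) <= 0))
    stop_ctb(paste("rcs_basis: knot quantiles are not distinct;",
                   "too few unique values - use fewer knots"),
             class = "ctb_degenerate_error")
  kn
}

#' Restricted-cubic-spline Cox hazard-ratio curve
#'
#' Fits a Cox model on the RCS basis of a continuous biomarker and returns
#' the hazard-ratio curve `HR(x) = exp(f(x) - f(ref))` against a reference
#' value (the sample median by default), with delta-method 95% confidence
#' bands, plus a Wald test that all nonlinear coefficients are zero - the
#' probe for a non-linear biomarker-outcome relationship (e.g. the
#' upside-down-U shape reported for raw bTMB against OS).
#'
#' @param scores continuous biomarker values.
#' @param times,events survival outcome.
#' @param k_knots number of knots (default 4, quantiles 5/35/65/95).
#' @param knots explicit knot locations (overrides `k_knots`).
#' @param reference score value at which HR = 1 (default: median of
#'   `scores`).
#' @param grid_n number of curve evaluation points.
#' @param ties passed to [cox_fit()].
#' @return a `ctb_rcs` object: `knots`, `reference`, `coef`, `vcov`,
#'   `curve` (data frame x/hr/ci_lower/ci_upper), `nonlinearity_chisq`,
#'   `nonlinearity_df`, `nonlinearity_p`, `cox` (the underlying `ctb_cox`).
#' @export
rcs_cox_curve <- function(scores, times, events, k_knots = 4, knots = NULL,
                          reference = NULL, grid_n = 100, ties = "efron") {
  ok <- !is.na(scores) & !is.na(times) & !is.na(events)
  scores <- scores[ok]; times <- times[ok]; events <- events[ok]
  if (is.null(knots)) knots <- rcs_default_knots(scores, k_knots)
  if (is.null(reference)) reference <- stats::median(scores)
  basis <- rcs_basis(scores, knots)
  cox <- cox_fit(as.data.frame(basis), times, events, ties = ties)

  nl_idx <- seq(2, ncol(basis))
  b_nl <- cox$coef[nl_idx]
  v_nl <- cox$vcov[nl_idx, nl_idx, drop = FALSE]
  chisq <- as.numeric(t(b_nl) %*% solve(v_nl, b_nl))
  df <- length(nl_idx)
  nonlin_p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)

  grid <- seq(stats::quantile(scores, 0.025), stats::quantile(scores, 0.975),
              length.out = grid_n)
  bg <- rcs_basis(grid, knots)
  bref <- rcs_basis(reference, knots)
  dmat <- sweep(bg, 2, as.numeric(bref))       # basis(x) - basis(ref)
  eta <- as.numeric(dmat %*% cox$coef)
  se <- sqrt(pmax(0, rowSums((dmat %*% cox$vcov) * dmat)))
  zc <- 1.959963984540054
  curve <- data.frame(x = grid, hr = exp(eta),
                      ci_lower = exp(eta - zc * se),
                      ci_upper = exp(eta + zc * se))

  structure(
    list(knots = knots, reference = reference, coef = cox$coef,
         vcov = cox$vcov, curve = curve, nonlinearity_chisq = chisq,
         nonlinearity_df = df, nonlinearity_p = nonlin_p, cox = cox),
    class = "ctb_rcs"
  )
}

#' Evaluate the fitted spline hazard ratio at arbitrary score values
#'
#' @param fit a `ctb_rcs` object.
#' @param x score values.
#' @return hazard ratios relative to the fit's reference value.
#' @export
rcs_hr_at <- function(fit, x) {
  stopifnot(inherits(fit, "ctb_rcs"))
  d <- sweep(rcs_basis(x, fit$knots), 2,
             as.numeric(rcs_basis(fit$reference, fit$knots)))
  exp(as.numeric(d %*% fit$coef))
}

#' @export
print.ctb_rcs <- function(x, ...) {
  cat(sprintf(
    "RCS Cox curve: %d knots at [%s], reference = %g\n  nonlinearity: chi2(%d) = %.3f, p = %.4g\n",
    length(x$knots), paste(signif(x$knots, 4), collapse = ", "),
    x$reference, x$nonlinearity_df, x$nonlinearity_chisq, x$nonlinearity_p))
  invisible(x)
}
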