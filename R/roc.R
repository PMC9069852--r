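#' ROC curve for a biomarker score against a binary benefit label
#'
#' Builds the empirical ROC ladder for the classification rule
#' `score >= threshold  =>  predicted positive` (high score predicts durable
#' clinical benefit). One operating point is produced per unique attained
#' score value, plus the trivial `+Inf` endpoint (sensitivity 0, specificity
#' 1). The AUC is the trapezoidal area under the polygon, which equals the
#' tie-corrected Mann-Whitney concordance `P(S_pos > S_neg) + P(S_pos =
#' S_neg)/2` exactly.
#'
#' @param scores finite numeric biomarker scores.
#' @param labels binary labels (0/1, logical, or a 2-level factor whose
#'   second level is the positive class).
#' @return a `ctb_roc` object: `thresholds` (descending, first `Inf`),
#'   `sensitivity`, `specificity`, `auc`, `optimal_cutoff`, `youden_j`,
#'   `n_pos`, `n_neg`.
#' @seealso [youden_optimal_cutoff()], [compare_auc_paired()]
#' @export
roc_curve <- function(scores, labels) {
  lb <- normalize_labels(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(lb))
    stop_ctb("roc_curve: scores and labels differ in length")
  ok <- !is.na(scores) & !is.na(lb)
  scores <- scores[ok]; lb <- lb[ok]
  if (any(!is.finite(scores))) stop_ctb("roc_curve: scores must be finite")
  n_pos <- sum(lb == 1L); n_neg <- sum(lb == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_ctb("roc_curve: need at least one positive and one negative label",
             class = "ctb_degenerate_error")

  thr <- sort(unique(scores), decreasing = TRUE)
  # counts with score >= t, per unique threshold, by cumulative tabulation
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]; l_sorted <- lb[ord]
  idx <- findInterval(-thr, -s_sorted)     # last index with score >= thr
  cum_pos <- cumsum(l_sorted == 1L)
  cum_neg <- cumsum(l_sorted == 0L)
  sens <- cum_pos[idx] / n_pos
  spec <- (n_neg - cum_neg[idx]) / n_neg

  thresholds <- c(Inf, thr)
  sensitivity <- c(0, sens)
  specificity <- c(1, spec)

  fpr <- 1 - specificity
  # close the polygon at (1, 1)
  auc <- sum(diff(c(fpr, 1)) * (c(sensitivity, 1)[-1] + sensitivity) / 2)

  res <- structure(
    list(thresholds = thresholds, sensitivity = sensitivity,
         specificity = specificity, auc = auc,
         optimal_cutoff = NA_real_, youden_j = NA_real_,
         n_pos = n_pos, n_neg = n_neg),
    class = "ctb_roc"
  )
  yj <- youden_optimal_cutoff(res)
  res$optimal_cutoff <- yj$cutoff
  res$youden_j <- yj$j
  res
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L)
      stop_ctb("labels must be binary")
    as.integer(labels == levels(labels)[2L])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    lb <- as.integer(labels)
    if (!all(lb %in% c(0L, 1L, NA)))
      stop_ctb("labels must be 0/1")
    lb
  }
}

#' @export
print.ctb_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d pos / %d neg); Youden cutoff = %g (J = %.4f)\n",
              x$auc, x$n_pos, x$n_neg, x$optimal_cutoff, x$youden_j))
  invisible(x)
}

#' Tie-corrected Mann-Whitney concordance (rank formula)
#'
#' Independent computation of the probability that a positive outranks a
#' negative (ties counted 1/2) via midranks; used to cross-check the
#' trapezoidal AUC, to which it is identical.
#'
#' @inheritParams roc_curve
#' @return concordance in `[0, 1]`.
#' @export
auc_concordance <- function(scores, labels) {
  lb <- normalize_labels(labels)
  n_pos <- sum(lb == 1L); n_neg <- sum(lb == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_ctb("auc_concordance: degenerate labels", class = "ctb_degenerate_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[lb == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal cutoff from a ROC ladder
#'
#' Maximises J = sensitivity + specificity - 1 over the attained score
#' thresholds. Ties in J are broken toward the cutoff with the higher
#' sensitivity, i.e. the smallest score value attaining the maximum.
#'
#' @param roc a `ctb_roc` object.
#' @return list with `cutoff` (an attained score value) and `j`.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ctb_roc"))
  finite <- is.finite(roc$thresholds)
  j <- roc$sensitivity[finite] + roc$specificity[finite] - 1
  thr <- roc$thresholds[finite]
  jmax <- max(j)
  list(cutoff = min(thr[j == jmax]), j = jmax)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both scores are measured on the same patients against the same labels.
#' The AUC difference is tested with the DeLong placement-value variance
#' (covariance between the two scores' placement values enters the paired
#' variance), giving a two-sided normal-approximation p-value.
#'
#' @param scores_a,scores_b numeric scores on the same patients.
#' @param labels binary labels as in [roc_curve()].
#' @return list: `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  lb <- normalize_labels(labels)
  if (length(scores_a) != length(lb) || length(scores_b) != length(lb))
    stop_ctb("compare_auc_paired: inputs differ in length")
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(lb)
  scores_a <- as.numeric(scores_a)[ok]
  scores_b <- as.numeric(scores_b)[ok]
  lb <- lb[ok]
  n_pos <- sum(lb == 1L); n_neg <- sum(lb == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_ctb("compare_auc_paired: degenerate labels", class = "ctb_degenerate_error")

  placements <- function(s) {
    sp <- s[lb == 1L]; sn <- s[lb == 0L]
    # V10_i: fraction of negatives below positive i (ties 1/2); V01 analogous
    v10 <- vapply(sp, function(z) (sum(z > sn) + 0.5 * sum(z == sn)) / n_neg,
                  numeric(1))
    v01 <- vapply(sn, function(z) (sum(sp > z) + 0.5 * sum(sp == z)) / n_pos,
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vard <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
          (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  diff <- pa$auc - pb$auc
  if (vard <= .Machine$double.eps) {
    z <- 0; p <- if (abs(diff) < 1e-15) 1 else NA_real_
  } else {
    z <- diff / sqrt(vard)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
       se = sqrt(max(0, vard)), z = z, p_value = p)
}
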