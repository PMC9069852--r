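#!/usr/bin/env Rscript
# Stage 3: ROC against durable clinical benefit and Youden cutoff.
#
# DCB (PFS >= 6 months) is the label; the ROC is built on ICI-arm patients
# with a defined adjusted score and a determinate DCB status. The adjusted
# score's discrimination is compared against raw bTMB with the paired
# DeLong test.

suppressPackageStartupMessages(library(ctbTMB))

clinical <- suppressWarnings(read_clinical("results/cohort/clinical.tsv"))
profiles <- utils::read.delim("results/scoring/biomarker_profiles.tsv",
                              na.strings = c("", "NA"))

pol <- eligibility_policy()
dcb <- classify_dcb(clinical$pfs_months, clinical$pfs_event, pol)
lab <- ifelse(dcb == "DCB", 1L, ifelse(dcb == "NDB", 0L, NA_integer_))
sel <- clinical$arm == "ICI" & !is.na(lab) & !is.na(profiles$adjusted_btmb)
cat(sprintf("ROC cohort: %d ICI-arm patients (%d DCB, %d NDB; %d indeterminate excluded)\n",
            sum(sel), sum(lab[sel] == 1), sum(lab[sel] == 0),
            sum(clinical$arm == "ICI" & dcb == "indeterminate")))

roc_adj <- roc_curve(profiles$adjusted_btmb[sel], lab[sel])
roc_raw <- roc_curve(profiles$btmb[sel], lab[sel])
cmp <- compare_auc_paired(profiles$adjusted_btmb[sel], profiles$btmb[sel],
                          lab[sel])
cat(sprintf("AUC: adjusted %.3f vs raw bTMB %.3f; paired DeLong p = %.3g\n",
            roc_adj$auc, roc_raw$auc, cmp$p_value))
cat(sprintf("Youden-optimal cutoff: %.3f muts/Mb x ng (J = %.3f)\n",
            roc_adj$optimal_cutoff, roc_adj$youden_j))

ladder <- data.frame(threshold = roc_adj$thresholds,
                     sensitivity = roc_adj$sensitivity,
                     specificity = roc_adj$specificity,
                     youden_j = roc_adj$sensitivity + roc_adj$specificity - 1)
write_results(list(
  roc_adjusted = ladder,
  cutoff = list(cutoff = roc_adj$optimal_cutoff, youden_j = roc_adj$youden_j,
                auc_adjusted = roc_adj$auc, auc_btmb = roc_raw$auc,
                delong_p = cmp$p_value, n = sum(sel))),
  "results/cutoff")
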