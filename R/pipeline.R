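#' Run the end-to-end biomarker evaluation pipeline
#'
#' Orchestrates the whole analysis: score the cohort, derive (Youden on DCB
#' in the ICI arm, by default) or apply a fixed adjusted-bTMB cutoff,
#' compare the adjusted score's ROC against raw bTMB (paired DeLong),
#' test the burden associations (Spearman), contrast DCB/ORR between score
#' groups per arm (Fisher or chi-square as appropriate), estimate per-arm
#' Kaplan-Meier curves, stratified treatment hazard ratios and the
#' treatment-by-biomarker interaction for OS and PFS, fit
#' restricted-cubic-spline hazard curves for both the raw and the adjusted
#' score, and repeat the interaction analysis in configured subgroups.
#' Patients with an undefined adjusted score, and patients indeterminate
#' for DCB, are excluded where the respective quantity is needed; every
#' exclusion is counted in the report's log.
#'
#' @param run_config a `ctb_run_config` (see [read_run_config()]), a path
#'   to a YAML run configuration, or a plain named list with the same keys.
#' @param data optional list with elements `clinical`, `variants`, `plasma`
#'   (data frames); when supplied, the config's input paths are ignored.
#' @return an `analysis_report` (nested list; see [generate_report()]).
#' @export
run_pipeline <- function(run_config, data = NULL) {
  if (is.character(run_config)) run_config <- read_run_config(run_config)
  defaults <- list(variant_format = "maf_tsv", panel_size_mb = 1.0,
                   cutoff = "derive", cutoff_arm = "ici",
                   ties_method = "efron", rcs_knots = 4, seed = 1,
                   subgroups = list())
  cfg <- utils::modifyList(defaults, as.list(run_config))
  policy <- eligibility_policy(
    af_floor = cfg$af_floor %||% 0.005,
    include_indels = cfg$include_indels %||% TRUE,
    exclude_germline = cfg$exclude_germline %||% TRUE,
    exclude_drivers_from_btmb = cfg$exclude_drivers_from_btmb %||% FALSE,
    mean_af_variant_set = cfg$mean_af_variant_set %||% "all_somatic",
    zero_mass_policy = cfg$zero_mass_policy %||% "exclude",
    epsilon_mass_ng = cfg$epsilon_mass_ng %||% 0.01,
    dcb_indeterminate = cfg$dcb_indeterminate %||% "exclude")

  log <- list()
  note <- function(stage, msg) log[[length(log) + 1L]] <<-
    list(stage = stage, message = msg)

  if (is.null(data)) {
    clinical <- read_clinical(cfg$clinical)
    variants <- read_variants(cfg$variants, cfg$variant_format)
    plasma <- read_plasma(cfg$plasma)
  } else {
    clinical <- data$clinical; variants <- data$variants; plasma <- data$plasma
  }
  note("input", sprintf("clinical rows in: %d; variant calls in: %d; plasma rows in: %d",
                        nrow(clinical), nrow(variants), nrow(plasma)))

  profiles <- score_cohort(clinical, variants, plasma, policy,
                           cfg$panel_size_mb)
  defined <- !is.na(profiles$adjusted_btmb)
  note("scoring", sprintf(
    "profiles: %d; adjusted score defined: %d; undefined: %s",
    nrow(profiles), sum(defined),
    paste(sprintf("%s=%d", names(table(profiles$undefined_reason)),
                  table(profiles$undefined_reason)), collapse = ", ")))

  dcb <- classify_dcb(clinical$pfs_months, clinical$pfs_event, policy)
  dcb_bin <- ifelse(dcb == "DCB", 1L, ifelse(dcb == "NDB", 0L, NA_integer_))
  note("dcb", sprintf("DCB=%d NDB=%d indeterminate=%d",
                      sum(dcb == "DCB"), sum(dcb == "NDB"),
                      sum(dcb == "indeterminate")))

  # --- association with tumor burden -------------------------------------
  association <- list()
  if ("sum_longest_diameters_mm" %in% names(clinical)) {
    burden <- clinical$sum_longest_diameters_mm
    association$spearman_btmb_burden <-
      flatten_test(spearman_corr(profiles$btmb, burden))
    association$spearman_adjusted_burden <-
      flatten_test(spearman_corr(profiles$adjusted_btmb[defined],
                                 burden[defined]))
  }

  # --- cutoff block -------------------------------------------------------
  in_roc_arm <- if (cfg$cutoff_arm == "ici") clinical$arm == "ICI"
                else rep(TRUE, nrow(clinical))
  roc_rows <- defined & !is.na(dcb_bin) & in_roc_arm
  roc_adj <- roc_curve(profiles$adjusted_btmb[roc_rows], dcb_bin[roc_rows])
  roc_raw <- roc_curve(profiles$btmb[roc_rows], dcb_bin[roc_rows])
  cmp <- compare_auc_paired(profiles$adjusted_btmb[roc_rows],
                            profiles$btmb[roc_rows], dcb_bin[roc_rows])
  cutoff <- if (identical(cfg$cutoff, "derive")) roc_adj$optimal_cutoff
            else as.numeric(cfg$cutoff)
  note("cutoff", sprintf(
    "ROC on %d patients (%s arm%s); cutoff %s = %g",
    sum(roc_rows), cfg$cutoff_arm,
    if (identical(cfg$cutoff, "derive"))
      "; derived and evaluated on the same cohort (optimism not corrected)"
    else "",
    if (identical(cfg$cutoff, "derive")) "derived" else "fixed", cutoff))
  cutoff_block <- list(
    cutoff = cutoff,
    cutoff_source = if (identical(cfg$cutoff, "derive")) "derive" else "fixed",
    cutoff_arm = cfg$cutoff_arm,
    youden_j = roc_adj$youden_j,
    auc_adjusted = roc_adj$auc, auc_btmb = roc_raw$auc,
    auc_comparison_p = cmp$p_value, n_roc = sum(roc_rows))

  group_high <- ifelse(defined, profiles$adjusted_btmb >= cutoff, NA)

  # --- DCB / ORR contrasts by arm ----------------------------------------
  orr_bin <- if ("best_response" %in% names(clinical))
    as.integer(clinical$best_response %in% c("CR", "PR")) else NULL
  benefit <- list()
  for (a in c("ICI", "comparator")) {
    sel <- clinical$arm == a & !is.na(group_high)
    benefit[[a]] <- list(
      dcb = contrast_2x2(dcb_bin[sel], group_high[sel]),
      orr = if (!is.null(orr_bin)) contrast_2x2(orr_bin[sel], group_high[sel]))
  }

  # --- survival block -----------------------------------------------------
  surv_block <- list()
  for (ep in c("OS", "PFS")) {
    tm <- if (ep == "OS") clinical$os_months else clinical$pfs_months
    ev <- if (ep == "OS") clinical$os_event else clinical$pfs_event
    ia <- interaction_analysis(clinical, group_high, endpoint = ep,
                               ties = cfg$ties_method)
    km <- lapply(list(high = TRUE, low = FALSE), function(hi) {
      lapply(list(ICI = "ICI", comparator = "comparator"), function(a) {
        sel <- !is.na(group_high) & group_high == hi & clinical$arm == a
        if (!any(sel)) return(NULL)
        k <- km_estimate(tm[sel], ev[sel])
        list(n = k$n, events = sum(k$events), median = k$median)
      })
    })
    lr <- tryCatch({
      sel <- !is.na(group_high) & clinical$arm == "ICI"
      flatten_test(logrank_test(tm[sel], ev[sel], group_high[sel]))
    }, error = function(e) NULL)
    surv_block[[ep]] <- list(
      interaction_p = ia$interaction_p,
      interaction_hr = exp(ia$interaction_coef),
      cox_terms = cox_to_list(ia$fit),
      stratified_hr = ia$stratum_hr,
      km_medians = km,
      logrank_ici_by_group = lr)
  }

  # --- RCS block ----------------------------------------------------------
  rcs_block <- list()
  for (score_name in c("btmb", "adjusted_btmb")) {
    sc <- profiles[[score_name]]
    ok <- if (score_name == "adjusted_btmb") defined else rep(TRUE, length(sc))
    for (ep in c("OS", "PFS")) {
      tm <- if (ep == "OS") clinical$os_months else clinical$pfs_months
      ev <- if (ep == "OS") clinical$os_event else clinical$pfs_event
      fit <- tryCatch(
        rcs_cox_curve(sc[ok], tm[ok], ev[ok], k_knots = cfg$rcs_knots,
                      ties = cfg$ties_method),
        error = function(e) NULL)
      if (!is.null(fit))
        rcs_block[[paste(score_name, ep, sep = "_")]] <- list(
          knots = fit$knots, reference = fit$reference,
          nonlinearity_p = fit$nonlinearity_p, curve = fit$curve)
    }
  }

  # --- subgroups ----------------------------------------------------------
  subgroup_block <- list()
  for (nm in names(cfg$subgroups)) {
    expr <- cfg$subgroups[[nm]]
    sel <- eval(parse(text = expr), envir = clinical, enclos = baseenv())
    sel <- !is.na(sel) & sel
    note("subgroup", sprintf("%s ('%s'): %d patients", nm, expr, sum(sel)))
    sub <- lapply(c(OS = "OS", PFS = "PFS"), function(ep) {
      tryCatch({
        ia <- interaction_analysis(clinical[sel, , drop = FALSE],
                                   group_high[sel], endpoint = ep,
                                   ties = cfg$ties_method)
        list(interaction_p = ia$interaction_p,
             interaction_hr = exp(ia$interaction_coef),
             stratified_hr = ia$stratum_hr, n = sum(sel))
      }, error = function(e) list(error = conditionMessage(e), n = sum(sel)))
    })
    subgroup_block[[nm]] <- sub
  }

  report <- list(
    meta = list(
      package_version = as.character(utils::packageVersion("ctbTMB")),
      config = cfg[setdiff(names(cfg), c("out_dir"))],
      config_hash = config_hash(cfg),
      seed = cfg$seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    biomarker_summary = list(
      n_patients = nrow(profiles),
      n_defined = sum(defined),
      median_btmb = stats::median(profiles$btmb),
      median_adjusted = stats::median(profiles$adjusted_btmb, na.rm = TRUE),
      median_mean_af = stats::median(profiles$mean_af)),
    cutoff = cutoff_block,
    association = association,
    benefit = benefit,
    survival = surv_block,
    rcs = rcs_block,
    subgroups = subgroup_block,
    log = log)
  attr(report, "profiles") <- profiles
  class(report) <- "analysis_report"
  report
}

flatten_test <- function(tr) {
  list(method = tr$method, statistic = tr$statistic, p_value = tr$p_value,
       n = tr$n, notes = tr$notes)
}

cox_to_list <- function(fit) {
  lapply(seq_along(fit$terms), function(k) list(
    term = fit$terms[k], hr = fit$hazard_ratio[k],
    ci_lower = fit$ci_lower[k], ci_upper = fit$ci_upper[k],
    p = fit$wald_p[k]))
}

# 2x2 contrast of a binary outcome by biomarker group; Fisher when any
# expected cell < 5, chi-square otherwise ("as appropriate").
contrast_2x2 <- function(outcome, group) {
  ok <- !is.na(outcome) & !is.na(group)
  outcome <- outcome[ok]; group <- group[ok]
  if (!length(outcome) || length(unique(group)) < 2L)
    return(list(note = "degenerate: missing stratum"))
  tab <- table(factor(group, levels = c(FALSE, TRUE)),
               factor(outcome, levels = c(0, 1)))
  rate_high <- mean(outcome[group]); rate_low <- mean(outcome[!group])
  res <- tryCatch({
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) fisher_exact_2x2(tab) else chi_square_test(tab)
  }, error = function(e) NULL)
  list(rate_high = rate_high, rate_low = rate_low,
       n_high = sum(group), n_low = sum(!group),
       test = if (!is.null(res)) flatten_test(res))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  keep <- cfg[sort(setdiff(names(cfg), c("out_dir")))]
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Structural validation of an analysis report
#'
#' Checks the report against the package's report schema: required
#' top-level blocks, required fields within them, and numeric ranges for
#' the headline quantities. Used by [generate_report()] before anything is
#' written, so a malformed report never reaches disk.
#'
#' @param report an `analysis_report`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_report <- function(report) {
  required <- c("meta", "biomarker_summary", "cutoff", "association",
                "benefit", "survival", "rcs", "subgroups", "log")
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop_ctb("report missing block(s): %s", paste(missing, collapse = ", "),
             class = "ctb_schema_error")
  cb <- report$cutoff
  for (f in c("cutoff", "auc_adjusted", "auc_btmb", "n_roc"))
    if (is.null(cb[[f]]))
      stop_ctb("report cutoff block missing '%s'", f, class = "ctb_schema_error")
  for (f in c("auc_adjusted", "auc_btmb"))
    if (!is.na(cb[[f]]) && (cb[[f]] < 0 || cb[[f]] > 1))
      stop_ctb("report: %s out of [0,1]", f, class = "ctb_schema_error")
  for (ep in c("OS", "PFS")) {
    sv <- report$survival[[ep]]
    if (is.null(sv) || is.null(sv$interaction_p))
      stop_ctb("report survival block incomplete for %s", ep,
               class = "ctb_schema_error")
    if (sv$interaction_p < 0 || sv$interaction_p > 1)
      stop_ctb("report: interaction_p out of [0,1]", class = "ctb_schema_error")
  }
  invisible(TRUE)
}

#' Write an analysis report to disk
#'
#' Validates the report, then writes `report.json`, a human-readable
#' `summary.txt`, the biomarker profile table and every curve grid as TSV,
#' plus a checksum manifest. The JSON is stable across reruns with the same
#' inputs and configuration, apart from the timestamp field.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the manifest data frame from [write_results()].
#' @export
generate_report <- function(report, out_dir) {
  validate_report(report)
  artifacts <- list("report.json" = unclass(report),
                    "summary.txt" = report_summary_lines(report))
  profiles <- attr(report, "profiles")
  if (!is.null(profiles))
    artifacts[["biomarker_profiles.tsv"]] <- as.data.frame(profiles)
  for (nm in names(report$rcs))
    artifacts[[paste0("rcs_", nm, ".tsv")]] <- report$rcs[[nm]]$curve
  write_results(artifacts, out_dir)
}

report_summary_lines <- function(r) {
  cb <- r$cutoff
  fmtp <- function(p) ifelse(is.na(p), "NA",
                             ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  lines <- c(
    sprintf("ctDNA-adjusted bTMB analysis (ctbTMB %s)", r$meta$package_version),
    sprintf("Patients: %d (%d with defined adjusted score)",
            r$biomarker_summary$n_patients, r$biomarker_summary$n_defined),
    sprintf("Cutoff: %.4g muts/Mb x ng (%s, %s arm); Youden J = %.3f",
            cb$cutoff, cb$cutoff_source, cb$cutoff_arm, cb$youden_j %||% NA),
    sprintf("AUC (DCB): adjusted %.3f vs bTMB %.3f, DeLong p = %s",
            cb$auc_adjusted, cb$auc_btmb, fmtp(cb$auc_comparison_p)))
  if (!is.null(r$association$spearman_btmb_burden)) {
    lines <- c(lines, sprintf(
      "Spearman vs burden: bTMB rho = %.3f (p = %s); adjusted rho = %.3f (p = %s)",
      r$association$spearman_btmb_burden$statistic,
      fmtp(r$association$spearman_btmb_burden$p_value),
      r$association$spearman_adjusted_burden$statistic,
      fmtp(r$association$spearman_adjusted_burden$p_value)))
  }
  for (ep in names(r$survival)) {
    sv <- r$survival[[ep]]
    hrw <- sv$stratified_hr
    lines <- c(lines, sprintf(
      "%s: interaction p = %s; treatment HR high = %.2f (%.2f-%.2f), low = %.2f (%.2f-%.2f)",
      ep, fmtp(sv$interaction_p),
      hrw$hr[hrw$stratum == "marker_high"],
      hrw$ci_lower[hrw$stratum == "marker_high"],
      hrw$ci_upper[hrw$stratum == "marker_high"],
      hrw$hr[hrw$stratum == "marker_low"],
      hrw$ci_lower[hrw$stratum == "marker_low"],
      hrw$ci_upper[hrw$stratum == "marker_low"]))
  }
  for (nm in names(r$rcs))
    lines <- c(lines, sprintf("RCS %s: nonlinearity p = %s", nm,
                              fmtp(r$rcs[[nm]]$nonlinearity_p)))
  lines
}
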