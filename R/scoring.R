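#' Variant-eligibility policy for bTMB and mean-AF computation
#'
#' The counting rules behind plasma TMB differ between assays and are rarely
#' spelled out; this object makes every knob explicit. Defaults: somatic SNVs
#' and indels with allele fraction >= 0.5%, germline-flagged calls excluded,
#' driver mutations included in the count; the mean allele fraction is taken
#' over all somatic calls (not just the bTMB-eligible subset), since the
#' ctDNA mass estimate reflects total tumor shedding, not panel eligibility.
#'
#' @param af_floor minimum allele fraction for bTMB eligibility, in `[0, 1)`.
#' @param include_indels count insertions/deletions toward bTMB.
#' @param exclude_germline drop germline-flagged calls everywhere.
#' @param exclude_drivers_from_btmb drop driver-flagged calls from the bTMB
#'   count only (they always remain in the all-somatic mean-AF set).
#' @param mean_af_variant_set `"all_somatic"` (default) or `"btmb_eligible"`.
#' @param zero_mass_policy what [adjust_btmb()] does when the estimated ctDNA
#'   mass is zero: `"exclude"` (score undefined, default) or `"epsilon_floor"`.
#' @param epsilon_mass_ng floor mass (ng) used under `"epsilon_floor"`.
#' @param dcb_indeterminate `"exclude"` (default) or `"ndb"`: how patients
#'   censored before 6 months enter DCB-based labelling.
#' @return an `eligibility_policy` list.
#' @export
eligibility_policy <- function(af_floor = 0.005,
                               include_indels = TRUE,
                               exclude_germline = TRUE,
                               exclude_drivers_from_btmb = FALSE,
                               mean_af_variant_set = c("all_somatic", "btmb_eligible"),
                               zero_mass_policy = c("exclude", "epsilon_floor"),
                               epsilon_mass_ng = 0.01,
                               dcb_indeterminate = c("exclude", "ndb")) {
  assert_scalar_number(af_floor, "af_floor", 0, 1 - 1e-9)
  assert_scalar_number(epsilon_mass_ng, "epsilon_mass_ng", 1e-12, Inf)
  structure(
    list(af_floor = af_floor,
         include_indels = isTRUE(include_indels),
         exclude_germline = isTRUE(exclude_germline),
         exclude_drivers_from_btmb = isTRUE(exclude_drivers_from_btmb),
         mean_af_variant_set = match.arg(mean_af_variant_set),
         zero_mass_policy = match.arg(zero_mass_policy),
         epsilon_mass_ng = epsilon_mass_ng,
         dcb_indeterminate = match.arg(dcb_indeterminate)),
    class = "eligibility_policy"
  )
}

#' Split one patient's calls into the bTMB set and the mean-AF set
#'
#' @param calls data frame of variant calls for a single patient (columns
#'   `allele_fraction`, `variant_class`, `germline_flag`, `driver_flag`).
#' @param policy an [eligibility_policy()].
#' @return list of two data frames, `btmb_set` and `mean_af_set` (either may
#'   be empty).
#' @export
filter_eligible_variants <- function(calls, policy = eligibility_policy()) {
  stopifnot(inherits(policy, "eligibility_policy"))
  if (is.null(calls) || nrow(calls) == 0L) {
    empty <- calls[0, , drop = FALSE]
    return(list(btmb_set = empty, mean_af_set = empty))
  }
  somatic <- if (policy$exclude_germline) !isTRUE_vec(calls$germline_flag)
             else rep(TRUE, nrow(calls))
  keep_class <- calls$variant_class %in%
    c("SNV", if (policy$include_indels) c("insertion", "deletion"))
  eligible <- somatic & keep_class & calls$allele_fraction >= policy$af_floor
  if (policy$exclude_drivers_from_btmb)
    eligible <- eligible & !isTRUE_vec(calls$driver_flag)
  af_set <- switch(policy$mean_af_variant_set,
                   all_somatic = somatic,
                   btmb_eligible = eligible)
  list(btmb_set = calls[eligible, , drop = FALSE],
       mean_af_set = calls[af_set, , drop = FALSE])
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Blood tumor mutational burden from an eligible variant set
#'
#' @param btmb_set data frame of eligible calls (only its row count is used),
#'   or an integer count.
#' @param panel_size_mb sequenced panel territory in megabases, > 0.
#' @return bTMB in mutations per megabase.
#' @export
compute_btmb <- function(btmb_set, panel_size_mb) {
  if (!is.numeric(panel_size_mb) || length(panel_size_mb) != 1L ||
      !is.finite(panel_size_mb) || panel_size_mb <= 0)
    stop_ctb("panel_size_mb must be a single positive number",
             class = "ctb_config_error")
  n <- if (is.data.frame(btmb_set)) nrow(btmb_set) else as.integer(btmb_set)
  n / panel_size_mb
}

#' Mean somatic allele fraction
#'
#' Arithmetic mean over the mean-AF variant set; 0 for an empty set (the
#' profile then records `undefined_reason = "no_variants"` downstream).
#'
#' @param mean_af_set data frame with column `allele_fraction`, or a numeric
#'   vector of allele fractions.
#' @return mean allele fraction in `[0, 1]`.
#' @export
compute_mean_af <- function(mean_af_set) {
  af <- if (is.data.frame(mean_af_set)) mean_af_set$allele_fraction
        else as.numeric(mean_af_set)
  if (length(af) == 0L) return(0)
  mean(af)
}

#' Estimated ctDNA input mass
#'
#' The tumor-derived fraction of cell-free DNA cannot be massed directly;
#' it is estimated as cfDNA input mass times the mean somatic allele
#' fraction.
#'
#' @param cfdna_input_mass_ng cfDNA input mass in ng, > 0.
#' @param mean_af mean somatic allele fraction in `[0, 1]`.
#' @return estimated ctDNA input mass in ng.
#' @export
estimate_ctdna_mass <- function(cfdna_input_mass_ng, mean_af) {
  if (any(!is.finite(cfdna_input_mass_ng)) || any(cfdna_input_mass_ng < 0))
    stop_ctb("cfdna_input_mass_ng must be nonnegative and finite",
             class = "ctb_validation_error")
  if (any(!is.finite(mean_af)) || any(mean_af < 0) || any(mean_af > 1))
    stop_ctb("mean_af must lie in [0, 1]", class = "ctb_validation_error")
  cfdna_input_mass_ng * mean_af
}

#' ctDNA-adjusted bTMB
#'
#' The biomarker at the centre of the package:
#' `adjusted bTMB = bTMB / (cfDNA input mass x mean AF)`, in
#' mutations/(Mb.ng). Dividing by the estimated ctDNA mass removes the
#' tumor-burden dependence that raw bTMB inherits from shedding. When the
#' estimated mass is zero the score is undefined under the default policy
#' (`NA` returned; the patient is excluded downstream); the
#' `"epsilon_floor"` policy divides by a configured floor mass instead, for
#' sensitivity analyses.
#'
#' @param btmb bTMB in muts/Mb, >= 0.
#' @param ctdna_input_mass_ng estimated ctDNA mass in ng, >= 0.
#' @param policy an [eligibility_policy()] (only the zero-mass fields are
#'   used).
#' @return adjusted score in muts/(Mb.ng), or `NA` when undefined.
#' @export
adjust_btmb <- function(btmb, ctdna_input_mass_ng,
                        policy = eligibility_policy()) {
  if (any(btmb < 0, na.rm = TRUE) || any(ctdna_input_mass_ng < 0, na.rm = TRUE))
    stop_ctb("btmb and ctdna_input_mass_ng must be nonnegative",
             class = "ctb_validation_error")
  out <- ifelse(ctdna_input_mass_ng > 0, btmb / ctdna_input_mass_ng, NA_real_)
  if (policy$zero_mass_policy == "epsilon_floor") {
    zero <- !is.na(ctdna_input_mass_ng) & ctdna_input_mass_ng == 0
    out[zero] <- btmb[zero] / policy$epsilon_mass_ng
  }
  out
}

#' Durable clinical benefit classification
#'
#' DCB is progression-free survival of 6 months or more (boundary
#' inclusive), regardless of whether the 6-month mark is reached with an
#' event or under censoring; NDB is progression or death before 6 months.
#' A patient censored before 6 months is indeterminate: by default such
#' patients are excluded from DCB-based labelling, optionally counted as NDB.
#'
#' @param pfs_months nonnegative PFS time(s) in months.
#' @param pfs_event event indicator(s) (1 = progression or death).
#' @param policy an [eligibility_policy()] (field `dcb_indeterminate`).
#' @return factor with levels `DCB`, `NDB`, `indeterminate`.
#' @export
classify_dcb <- function(pfs_months, pfs_event, policy = eligibility_policy()) {
  if (any(pfs_months < 0, na.rm = TRUE))
    stop_ctb("pfs_months must be nonnegative", class = "ctb_validation_error")
  ev <- as.logical(pfs_event)
  out <- ifelse(pfs_months >= 6, "DCB",
                ifelse(ev, "NDB", "indeterminate"))
  if (policy$dcb_indeterminate == "ndb") out[out == "indeterminate"] <- "NDB"
  factor(out, levels = c("DCB", "NDB", "indeterminate"))
}

#' Score a whole cohort
#'
#' Composes the per-patient pipeline: eligibility filtering, bTMB, mean AF,
#' ctDNA mass and the adjusted score, one row per clinical record. Patients
#' without variant calls get bTMB 0 (`undefined_reason = "no_variants"`);
#' patients without a plasma record get `"missing_plasma"`; patients whose
#' mean AF is zero get `"zero_mean_af"`. Variant or plasma rows whose
#' patient_id does not appear in the clinical table are a reconciliation
#' error.
#'
#' @param clinical data frame of clinical records (see [read_clinical()]).
#' @param variants data frame of variant calls (see [read_variants()]).
#' @param plasma data frame of plasma samples (see [read_plasma()]).
#' @param policy an [eligibility_policy()].
#' @param panel_size_mb panel territory in Mb.
#' @return data frame (class `biomarker_profile`) with columns `patient_id`,
#'   `n_eligible_mutations`, `btmb`, `mean_af`, `cfdna_input_mass_ng`,
#'   `ctdna_input_mass_ng`, `adjusted_btmb`, `undefined_reason`.
#' @export
score_cohort <- function(clinical, variants, plasma,
                         policy = eligibility_policy(), panel_size_mb = 1.0) {
  ids <- clinical$patient_id
  orphans_v <- setdiff(unique(variants$patient_id), ids)
  orphans_p <- setdiff(unique(plasma$patient_id), ids)
  if (length(orphans_v) || length(orphans_p))
    stop_ctb("patient_id reconciliation failed; orphans: %s",
             paste(unique(c(orphans_v, orphans_p)), collapse = ", "),
             class = "ctb_reconciliation_error")
  if (anyDuplicated(plasma$patient_id))
    stop_ctb("duplicate patient_id in plasma table",
             class = "ctb_validation_error")

  var_split <- split(variants, factor(variants$patient_id, levels = ids))
  mass_of <- stats::setNames(plasma$cfdna_input_mass_ng, plasma$patient_id)

  rows <- lapply(ids, function(id) {
    calls <- var_split[[id]]
    sets <- filter_eligible_variants(calls, policy)
    n_elig <- nrow(sets$btmb_set)
    btmb <- compute_btmb(sets$btmb_set, panel_size_mb)
    mean_af <- compute_mean_af(sets$mean_af_set)
    cfdna <- unname(mass_of[id])
    reason <- "none"
    if (is.na(cfdna)) {
      ctdna <- NA_real_; adj <- NA_real_; reason <- "missing_plasma"
    } else {
      ctdna <- estimate_ctdna_mass(cfdna, mean_af)
      adj <- adjust_btmb(btmb, ctdna, policy)
      if (nrow(sets$mean_af_set) == 0L) reason <- "no_variants"
      else if (mean_af == 0) reason <- "zero_mean_af"
      if (reason != "none" && policy$zero_mass_policy == "epsilon_floor")
        reason <- "none"   # score defined via the floor
    }
    data.frame(patient_id = id, n_eligible_mutations = n_elig, btmb = btmb,
               mean_af = mean_af, cfdna_input_mass_ng = cfdna,
               ctdna_input_mass_ng = ctdna, adjusted_btmb = adj,
               undefined_reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("biomarker_profile", "data.frame")
  out
}
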