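#' Configuration of the synthetic two-arm cohort generator
#'
#' Encodes the generative model the evaluation pipeline assumes: tumor
#' burden (sum of longest diameters) drives the mean plasma allele fraction
#' of shed ctDNA, which drives per-mutation detectability -- so raw bTMB is
#' confounded with burden while the ctDNA-adjusted score is not -- and
#' survival follows exponential hazards with a treatment-by-biomarker
#' interaction on the latent high-score group.
#'
#' @param n_patients cohort size (>= 0).
#' @param seed integer master seed; each patient draws from its own
#'   substream derived from `(seed, patient index)`, so increasing
#'   `n_patients` never reshuffles earlier patients.
#' @param panel_size_mb sequenced panel territory, Mb (> 0).
#' @param burden_logmean,burden_logsd lognormal parameters of the sum of
#'   longest diameters, mm.
#' @param mutload_mean,mutload_dispersion negative-binomial mean and size of
#'   the true panel mutation count.
#' @param cfdna_logmean,cfdna_logsd lognormal parameters of cfDNA input
#'   mass, ng.
#' @param shedding_slope mean allele fraction per mm of tumor diameter.
#' @param shedding_noise_sd log-sd of the multiplicative shedding noise.
#' @param af_cap ceiling on the mean allele fraction.
#' @param af_spread_sd log-sd of per-variant allele-fraction scatter around
#'   the patient mean (mean-matched lognormal, truncated below at `af_lod`).
#' @param af_lod assay limit of detection: reported variant allele
#'   fractions are drawn from the lognormal conditioned on exceeding this
#'   value, since a caller does not report sub-LOD variants. Matches the
#'   default bTMB eligibility floor.
#' @param detection_slope per-mutation detection probability per unit mean
#'   allele fraction (probability capped at 1).
#' @param arm_prob randomization probability of the ICI arm.
#' @param true_cutoff adjusted-score threshold, muts/(Mb.ng), defining the
#'   latent biomarker-high group on the *expected* adjusted score.
#' @param baseline_median_os,baseline_median_pfs months, reference stratum
#'   (comparator arm, biomarker-low, average log-burden).
#' @param beta_treat,beta_marker,beta_interaction_os,beta_interaction_pfs,beta_burden
#'   log-hazard coefficients; `beta_burden` is per SD of log-burden.
#' @param censoring apply administrative censoring (TRUE) or follow every
#'   patient to the event (FALSE).
#' @param censor_lo,censor_hi administrative censoring window, months.
#' @param orr_logit_base,orr_logit_interaction logistic response-model
#'   intercept and coefficient on (ICI arm x latent-high).
#' @param btmb_high_cutoff muts/Mb threshold behind the
#'   `original_btmb_high` clinical flag.
#' @param germline_rate Poisson mean of incidentally reported
#'   germline-flagged calls per patient (exercises the somatic filter).
#' @param prob_pdl1_negative,prob_pdl1_unknown PD-L1 status frequencies
#'   (remainder positive).
#' @param stk11_keap1_rate frequency of the STK11/KEAP1 mutation flag.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 400,
                       seed = 1,
                       panel_size_mb = 1.0,
                       burden_logmean = 4.0, burden_logsd = 0.5,
                       mutload_mean = 10, mutload_dispersion = 5,
                       cfdna_logmean = 3.2, cfdna_logsd = 0.4,
                       shedding_slope = 2e-4, shedding_noise_sd = 0.25,
                       af_cap = 0.30, af_spread_sd = 0.45, af_lod = 0.005,
                       detection_slope = 30,
                       arm_prob = 0.5,
                       true_cutoff = 8,
                       baseline_median_os = 12, baseline_median_pfs = 4,
                       beta_treat = log(0.85), beta_marker = 0,
                       beta_interaction_os = log(0.5),
                       beta_interaction_pfs = log(0.45),
                       beta_burden = log(1.3),
                       censoring = TRUE, censor_lo = 12, censor_hi = 36,
                       orr_logit_base = -1.5, orr_logit_interaction = 1.2,
                       btmb_high_cutoff = 6,
                       germline_rate = 0.5,
                       prob_pdl1_negative = 0.45, prob_pdl1_unknown = 0.05,
                       stk11_keap1_rate = 0.15) {
  cfg <- as.list(environment())
  assert_scalar_number(n_patients, "n_patients", 0, Inf)
  if (n_patients != round(n_patients))
    stop_ctb("'n_patients' must be an integer", class = "ctb_config_error")
  assert_scalar_number(seed, "seed", -2^31 + 1, 2^31 - 1)
  assert_scalar_number(panel_size_mb, "panel_size_mb", 1e-9, Inf)
  assert_scalar_number(burden_logsd, "burden_logsd", 0, Inf)
  assert_scalar_number(burden_logmean, "burden_logmean")
  assert_scalar_number(mutload_mean, "mutload_mean", 0, Inf)
  assert_scalar_number(mutload_dispersion, "mutload_dispersion", 1e-9, Inf)
  assert_scalar_number(cfdna_logmean, "cfdna_logmean")
  assert_scalar_number(cfdna_logsd, "cfdna_logsd", 0, Inf)
  assert_scalar_number(shedding_slope, "shedding_slope", 0, Inf)
  assert_scalar_number(shedding_noise_sd, "shedding_noise_sd", 0, Inf)
  assert_scalar_number(af_cap, "af_cap", 1e-9, 1)
  assert_scalar_number(af_spread_sd, "af_spread_sd", 0, Inf)
  assert_scalar_number(af_lod, "af_lod", 0, 1)
  assert_scalar_number(detection_slope, "detection_slope", 0, Inf)
  assert_scalar_number(arm_prob, "arm_prob", 0, 1)
  assert_scalar_number(true_cutoff, "true_cutoff", 0, Inf)
  assert_scalar_number(baseline_median_os, "baseline_median_os", 1e-9, Inf)
  assert_scalar_number(baseline_median_pfs, "baseline_median_pfs", 1e-9, Inf)
  for (b in c("beta_treat", "beta_marker", "beta_interaction_os",
              "beta_interaction_pfs", "beta_burden",
              "orr_logit_base", "orr_logit_interaction"))
    assert_scalar_number(cfg[[b]], b)
  if (!is.logical(censoring) || length(censoring) != 1L || is.na(censoring))
    stop_ctb("'censoring' must be TRUE or FALSE", class = "ctb_config_error")
  if (censoring) {
    assert_scalar_number(censor_lo, "censor_lo", 0, Inf)
    assert_scalar_number(censor_hi, "censor_hi", 0, Inf)
    if (censor_lo >= censor_hi)
      stop_ctb("'censor_lo' must be < 'censor_hi'", class = "ctb_config_error")
  }
  assert_scalar_number(btmb_high_cutoff, "btmb_high_cutoff", 0, Inf)
  assert_scalar_number(germline_rate, "germline_rate", 0, Inf)
  assert_scalar_number(prob_pdl1_negative, "prob_pdl1_negative", 0, 1)
  assert_scalar_number(prob_pdl1_unknown, "prob_pdl1_unknown", 0, 1)
  if (prob_pdl1_negative + prob_pdl1_unknown > 1)
    stop_ctb("PD-L1 status probabilities exceed 1", class = "ctb_config_error")
  assert_scalar_number(stk11_keap1_rate, "stk11_keap1_rate", 0, 1)
  structure(cfg, class = "sim_config")
}

# Deterministic per-(patient, part) substream seed (31-bit). Part 0 holds
# the clinical draws, part 1 the variant-annotation draws, so generating a
# cohort without its variant table leaves clinical outcomes identical.
patient_substream_seed <- function(seed, i, part = 0L) {
  s <- (abs(seed) * 48271) %% 2147483629
  ((s + 2 * i + part) * 16807) %% 2147483629 + 1
}

with_preserved_rng <- function(expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  expr
}

#' Simulate a randomized two-arm cohort
#'
#' Per patient: burden `B ~ lognormal`; true mutation count
#' `M ~ negative binomial`; cfDNA mass `C ~ lognormal`; mean shed allele
#' fraction `a = min(af_cap, shedding_slope * B * eps)` with lognormal
#' noise `eps`; each of the `M` mutations is detected independently with
#' probability `min(1, detection_slope * a)` and detected variants receive
#' individual allele fractions drawn mean-matched lognormally around `a`,
#' conditioned on exceeding the assay limit of detection `af_lod` (a caller
#' reports no sub-LOD variants).
#' The latent biomarker-high indicator is `E[adjusted score | M, C, a] =
#' M * min(1, kappa*a) / (panel * C * a) >= true_cutoff`. OS and PFS are
#' exponential with log-hazard `beta_treat*T + beta_marker*X +
#' beta_interaction*T*X + beta_burden*z(log B)` (z standardized by the
#' configured lognormal parameters), administratively censored uniformly on
#' the censoring window. Best response follows a logistic model in `T*X`;
#' responders' progression times are floored at 2 months so response and
#' PFS cannot contradict each other.
#'
#' Identical `(config, seed)` reproduce identical tables; patients are
#' generated from index-keyed substreams, so extending `n_patients` leaves
#' earlier patients untouched, and the variant table can be skipped
#' (`include_variants = FALSE`, for survival-only simulation studies)
#' without changing any clinical outcome.
#'
#' @param config a [sim_config()].
#' @param include_variants generate the per-variant table (default TRUE).
#' @return list of four data frames: `clinical`, `variants`, `plasma`,
#'   `truth` (class `ctb_cohort`). `truth` carries the generating config as
#'   attribute `"config"`.
#' @export
simulate_cohort <- function(config = sim_config(), include_variants = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- as.integer(cfg$n_patients)

  with_preserved_rng({
    arm_ici <- logical(n)
    B <- M <- C <- a <- p_det <- D <- numeric(n)
    t_os <- t_pfs <- cens <- u_resp <- u_cat <- u_pdl1 <- u_stk <- numeric(n)
    n_met <- integer(n)

    for (i in seq_len(n)) {
      set.seed(patient_substream_seed(cfg$seed, i, 0L))
      arm_ici[i] <- stats::runif(1) < cfg$arm_prob
      B[i] <- stats::rlnorm(1, cfg$burden_logmean, cfg$burden_logsd)
      M[i] <- stats::rnbinom(1, size = cfg$mutload_dispersion,
                             mu = cfg$mutload_mean)
      C[i] <- stats::rlnorm(1, cfg$cfdna_logmean, cfg$cfdna_logsd)
      eps <- stats::rlnorm(1, 0, cfg$shedding_noise_sd)
      a[i] <- min(cfg$af_cap, cfg$shedding_slope * B[i] * eps)
      p_det[i] <- min(1, cfg$detection_slope * a[i])
      D[i] <- stats::rbinom(1, M[i], p_det[i])
      t_os[i] <- stats::rexp(1)       # unit exponentials, scaled below
      t_pfs[i] <- stats::rexp(1)
      cens[i] <- stats::runif(1)
      u_resp[i] <- stats::runif(1)
      u_cat[i] <- stats::runif(1)
      u_pdl1[i] <- stats::runif(1)
      u_stk[i] <- stats::runif(1)
      n_met[i] <- 1L + stats::rpois(1, lambda = B[i] / 50)
    }

    pid <- sprintf("P%05d", seq_len(n))
    treat <- as.numeric(arm_ici)
    arm <- ifelse(arm_ici, "ICI", "comparator")
    expected_adj <- ifelse(a > 0, M * p_det / (cfg$panel_size_mb * C * a), 0)
    X <- as.integer(expected_adj >= cfg$true_cutoff)
    z <- (log(B) - cfg$burden_logmean) /
      (if (cfg$burden_logsd > 0) cfg$burden_logsd else 1)

    lp_os <- cfg$beta_treat * treat + cfg$beta_marker * X +
      cfg$beta_interaction_os * treat * X + cfg$beta_burden * z
    lp_pfs <- cfg$beta_treat * treat + cfg$beta_marker * X +
      cfg$beta_interaction_pfs * treat * X + cfg$beta_burden * z
    t_os <- t_os / (log(2) / cfg$baseline_median_os * exp(lp_os))
    t_pfs <- t_pfs / (log(2) / cfg$baseline_median_pfs * exp(lp_pfs))

    p_resp <- stats::plogis(cfg$orr_logit_base +
                              cfg$orr_logit_interaction * treat * X)
    responder <- u_resp < p_resp
    t_pfs[responder] <- pmax(t_pfs[responder], 2)  # response-PFS coherence
    best_response <- ifelse(responder,
                            ifelse(u_cat < 0.15, "CR", "PR"),
                            ifelse(u_cat < 0.40, "SD",
                                   ifelse(u_cat < 0.95, "PD", "NE")))

    if (cfg$censoring && n > 0) {
      ctime <- cfg$censor_lo + cens * (cfg$censor_hi - cfg$censor_lo)
      os_months <- pmin(t_os, ctime)
      os_event <- as.integer(t_os <= ctime)
      pfs_months <- pmin(t_pfs, ctime)
      pfs_event <- as.integer(t_pfs <= ctime)
    } else {
      os_months <- t_os; os_event <- rep(1L, n)
      pfs_months <- t_pfs; pfs_event <- rep(1L, n)
    }

    pdl1 <- ifelse(u_pdl1 < cfg$prob_pdl1_negative, "negative",
                   ifelse(u_pdl1 < cfg$prob_pdl1_negative +
                            cfg$prob_pdl1_unknown, "unknown", "positive"))

    clinical <- data.frame(
      patient_id = pid, arm = arm,
      os_months = os_months, os_event = os_event,
      pfs_months = pfs_months, pfs_event = pfs_event,
      best_response = best_response, pdl1_status = pdl1,
      sum_longest_diameters_mm = B, n_metastatic_sites = n_met,
      stk11_keap1_mut = u_stk < cfg$stk11_keap1_rate,
      original_btmb_high = D / cfg$panel_size_mb >= cfg$btmb_high_cutoff,
      stringsAsFactors = FALSE)
    plasma <- data.frame(patient_id = pid, cfdna_input_mass_ng = C,
                         stringsAsFactors = FALSE)
    truth <- data.frame(
      patient_id = pid, arm = arm, burden_mm = B, true_mut_count = M,
      mean_shed_af = a, detect_prob = p_det, n_detected = D,
      cfdna_mass_ng = C, expected_adjusted = expected_adj,
      latent_high = X, z_log_burden = z, stringsAsFactors = FALSE)

    variants <- if (include_variants)
      simulate_variant_table(pid, D, a, cfg) else empty_variant_table()

    cohort <- list(clinical = clinical, variants = variants,
                   plasma = plasma, truth = truth)
    attr(cohort$truth, "config") <- unclass(cfg)
    class(cohort) <- "ctb_cohort"
    cohort
  })
}

empty_variant_table <- function() {
  data.frame(
    patient_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), allele_fraction = numeric(),
    depth = integer(), variant_class = character(), driver_flag = logical(),
    germline_flag = logical(), stringsAsFactors = FALSE)
}

# Detected somatic variants plus incidental germline-flagged calls;
# each patient's draws come from its part-1 substream.
simulate_variant_table <- function(pid, D, a, cfg) {
  bases <- c("A", "C", "G", "T")
  acc <- vector("list", length(pid))
  for (i in seq_along(pid)) {
    set.seed(patient_substream_seed(cfg$seed, i, 1L))
    n_som <- D[i]
    n_germ <- stats::rpois(1, cfg$germline_rate)
    total <- n_som + n_germ
    if (total == 0L) next
    af_som <- if (n_som > 0) {
      mu <- log(a[i]) - cfg$af_spread_sd^2 / 2
      if (cfg$af_spread_sd > 0) {
        p0 <- stats::plnorm(cfg$af_lod, mu, cfg$af_spread_sd)
        pmin(0.999, stats::qlnorm(stats::runif(n_som, p0, 1), mu,
                                  cfg$af_spread_sd))
      } else pmin(0.999, pmax(cfg$af_lod, rep(exp(mu), n_som)))
    } else numeric(0)
    af_germ <- if (n_germ > 0) stats::runif(n_germ, 0.40, 0.60) else numeric(0)

    u_class <- stats::runif(total)
    cls <- ifelse(u_class < 0.85, "SNV",
                  ifelse(u_class < 0.91, "insertion",
                         ifelse(u_class < 0.99, "deletion", "other")))
    cls[seq_len(total) > n_som] <- "SNV"   # germline calls kept simple
    ref <- bases[1L + floor(stats::runif(total) * 4)]
    alt_off <- 1L + floor(stats::runif(total) * 3)
    alt <- vapply(seq_len(total), function(j)
      setdiff(bases, ref[j])[alt_off[j]], character(1))
    ins <- cls == "insertion"; del <- cls == "deletion"
    alt[ins] <- paste0(ref[ins], alt[ins])
    refdel <- paste0(ref[del], bases[1L + floor(stats::runif(sum(del)) * 4)])
    alt[del] <- ref[del]; ref[del] <- refdel
    acc[[i]] <- list(
      patient_id = rep(pid[i], total),
      chrom = as.character(1L + floor(stats::runif(total) * 22)),
      pos = as.integer(1L + floor(stats::runif(total) * 1e8)),
      ref = ref, alt = alt,
      allele_fraction = c(af_som, af_germ),
      depth = as.integer(round(stats::rlnorm(total, log(800), 0.3))),
      variant_class = cls,
      driver_flag = stats::runif(total) < 0.10,
      germline_flag = seq_len(total) > n_som)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) return(empty_variant_table())
  cols <- names(acc[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(acc, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Bookkeeping summary of a simulation truth table
#'
#' @param truth the `truth` data frame from [simulate_cohort()].
#' @return list: `n`, `n_per_arm`, `prevalence_latent_high`,
#'   `mean_burden_mm`, `mean_true_mutload`.
#' @export
truth_summary <- function(truth) {
  if (is.null(truth) || nrow(truth) == 0L)
    stop_ctb("truth_summary: empty truth table", class = "ctb_validation_error")
  list(n = nrow(truth),
       n_per_arm = as.list(table(truth$arm)),
       prevalence_latent_high = mean(truth$latent_high),
       mean_burden_mm = mean(truth$burden_mm),
       mean_true_mutload = mean(truth$true_mut_count))
}

#' Write a simulated cohort to a directory as TSV tables
#'
#' Emits `clinical.tsv`, `variants.tsv`, `plasma.tsv`, `truth.tsv` and a
#' JSON sidecar `dictionary.json` describing every column and carrying the
#' generating configuration.
#'
#' @param cohort a `ctb_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ctb_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("clinical.tsv", "variants.tsv",
                                "plasma.tsv", "truth.tsv"))
  write_tsv_full(cohort$clinical, paths[1])
  write_tsv_full(cohort$variants, paths[2])
  write_tsv_full(cohort$plasma, paths[3])
  write_tsv_full(cohort$truth, paths[4])
  dict <- list(
    tables = list(
      clinical = names(cohort$clinical), variants = names(cohort$variants),
      plasma = names(cohort$plasma), truth = names(cohort$truth)),
    units = list(os_months = "months", pfs_months = "months",
                 sum_longest_diameters_mm = "mm",
                 cfdna_input_mass_ng = "ng", allele_fraction = "fraction",
                 burden_mm = "mm", expected_adjusted = "muts/(Mb.ng)"),
    config = attr(cohort$truth, "config"))
  side <- file.path(out_dir, "dictionary.json")
  jsonlite::write_json(dict, side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, side))
}
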