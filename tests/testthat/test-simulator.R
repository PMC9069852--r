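test_that("an empty cohort yields empty tables with the full column sets", {
  co <- simulate_cohort(sim_config(n_patients = 0, seed = 1))
  expect_equal(nrow(co$clinical), 0)
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$plasma), 0)
  expect_true(all(c("patient_id", "arm", "os_months", "os_event",
                    "pfs_months", "pfs_event", "best_response",
                    "pdl1_status") %in% names(co$clinical)))
  expect_true(all(c("patient_id", "chrom", "pos", "ref", "alt",
                    "allele_fraction", "depth", "variant_class",
                    "driver_flag", "germline_flag") %in% names(co$variants)))
})

test_that("identical (config, seed) reproduce identical tables; seeds differ otherwise", {
  a <- simulate_cohort(sim_config(n_patients = 150, seed = 8))
  b <- simulate_cohort(sim_config(n_patients = 150, seed = 8))
  expect_identical(a, b)
  c <- simulate_cohort(sim_config(n_patients = 150, seed = 9))
  expect_false(identical(a$clinical, c$clinical))
})

test_that("extending the cohort preserves earlier patients (per-patient substreams)", {
  small <- simulate_cohort(sim_config(n_patients = 40, seed = 12))
  big <- simulate_cohort(sim_config(n_patients = 90, seed = 12))
  expect_identical(small$clinical, big$clinical[1:40, ])
  expect_identical(small$truth, big$truth[1:40, ],
                   ignore_attr = TRUE)
})

test_that("skipping the variant table leaves clinical outcomes untouched", {
  a <- simulate_cohort(sim_config(n_patients = 60, seed = 4))
  b <- simulate_cohort(sim_config(n_patients = 60, seed = 4),
                       include_variants = FALSE)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(b$variants), 0)
})

test_that("out-of-range configuration values are rejected naming the field", {
  expect_error(sim_config(arm_prob = 1.5), "arm_prob")
  expect_error(sim_config(censor_lo = 40, censor_hi = 20), "censor_lo")
  expect_error(sim_config(panel_size_mb = 0), "panel_size_mb")
  expect_error(sim_config(n_patients = 2.5), "n_patients")
  expect_error(sim_config(shedding_slope = NaN), "shedding_slope")
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(stats::runif(1))
  invisible(simulate_cohort(sim_config(n_patients = 10, seed = 1)))
  after <- stats::runif(2)
  expect_identical(before[2:3], after)
})

test_that("truth_summary reports prevalence and errors on empty input", {
  co <- simulate_cohort(sim_config(n_patients = 100, seed = 3),
                        include_variants = FALSE)
  s1 <- truth_summary(co$truth)
  s2 <- truth_summary(simulate_cohort(sim_config(n_patients = 100, seed = 3),
                                      include_variants = FALSE)$truth)
  expect_identical(s1, s2)
  expect_equal(s1$n, 100)

  allhigh <- co$truth
  allhigh$latent_high <- 1L
  expect_equal(truth_summary(allhigh)$prevalence_latent_high, 1.0)
  expect_error(truth_summary(co$truth[0, ]), "empty")
})

test_that("latent-group prevalence matches numerical integration of the generative model", {
  cfg <- sim_config(n_patients = 2000, seed = 101)
  co <- simulate_cohort(cfg, include_variants = FALSE)
  p_hat <- truth_summary(co$truth)$prevalence_latent_high
  p_true <- oracle_latent_high_prob(cfg)
  half_width <- stats::qnorm(0.995) * sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(p_hat - p_true), half_width)
})

test_that("median OS of the reference stratum is near the configured baseline", {
  cfg <- sim_config(n_patients = 5000, seed = 55, censoring = FALSE)
  co <- simulate_cohort(cfg, include_variants = FALSE)
  ref <- co$clinical$arm == "comparator" & co$truth$latent_high == 0
  km <- km_estimate(co$clinical$os_months[ref], co$clinical$os_event[ref])
  expect_lt(abs(km$median - 12) / 12, 0.10)
})

test_that("responders never progress before the 2-month coherence floor", {
  co <- simulate_cohort(sim_config(n_patients = 800, seed = 21),
                        include_variants = FALSE)
  resp <- co$clinical$best_response %in% c("CR", "PR")
  prog <- co$clinical$pfs_event == 1
  expect_true(all(co$clinical$pfs_months[resp & prog] >= 2))
})

test_that("variant AFs respect the detection floor and the germline band", {
  co <- simulate_cohort(sim_config(n_patients = 300, seed = 33))
  som <- co$variants[!co$variants$germline_flag, ]
  expect_true(all(som$allele_fraction >= 0.005))
  germ <- co$variants[co$variants$germline_flag, ]
  expect_true(all(germ$allele_fraction >= 0.40 & germ$allele_fraction <= 0.60))
  # detected counts in the truth table equal somatic rows per patient
  cnt <- table(factor(som$patient_id, levels = co$truth$patient_id))
  expect_equal(as.integer(cnt), co$truth$n_detected)
})

test_that("with censoring disabled the Cox fit on the truth grouping recovers the interaction", {
  # moderate replication; the full parameter-recovery study runs in the
  # acceptance suite
  set.seed(61)
  reps <- 60
  est <- replicate(reps, {
    cfg <- sim_config(n_patients = 600,
                      seed = sample.int(2^31 - 1, 1), censoring = FALSE)
    co <- simulate_cohort(cfg, include_variants = FALSE)
    ia <- interaction_analysis(co$clinical, co$truth$latent_high, "OS")
    ia$interaction_coef
  })
  expect_lt(abs(mean(est) - log(0.5)), 0.1)
})
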