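make_calls <- function(af, class = "SNV", germline = FALSE, driver = FALSE) {
  n <- length(af)
  data.frame(patient_id = rep("P1", n), chrom = rep("1", n), pos = seq_len(n),
             ref = rep("A", n), alt = rep("T", n), allele_fraction = af,
             depth = rep(500L, n),
             variant_class = rep_len(class, n),
             driver_flag = rep_len(driver, n),
             germline_flag = rep_len(germline, n), stringsAsFactors = FALSE)
}

test_that("eligibility filter applies the AF floor, class and flag rules", {
  calls <- rbind(make_calls(c(0.002, 0.01, 0.05, 0.20, 0.30)),
                 make_calls(0.50, germline = TRUE))
  sets <- filter_eligible_variants(calls, eligibility_policy())
  expect_equal(nrow(sets$btmb_set), 4)           # 0.002 below floor, germline out
  expect_equal(nrow(sets$mean_af_set), 5)        # all somatic, no floor
  expect_false(any(sets$mean_af_set$germline_flag))

  empty <- filter_eligible_variants(calls[0, ], eligibility_policy())
  expect_equal(nrow(empty$btmb_set), 0)
  expect_equal(nrow(empty$mean_af_set), 0)
})

test_that("driver exclusion removes drivers from the bTMB set only", {
  calls <- rbind(make_calls(c(0.02, 0.03), driver = TRUE),
                 make_calls(c(0.04, 0.05, 0.06, 0.07)))
  pol <- eligibility_policy(exclude_drivers_from_btmb = TRUE)
  sets <- filter_eligible_variants(calls, pol)
  expect_equal(nrow(sets$btmb_set), 4)
  expect_equal(nrow(sets$mean_af_set), 6)
})

test_that("indel inclusion is a policy knob", {
  calls <- make_calls(c(0.02, 0.03, 0.04), class = c("SNV", "insertion", "deletion"))
  on <- filter_eligible_variants(calls, eligibility_policy())
  off <- filter_eligible_variants(calls, eligibility_policy(include_indels = FALSE))
  expect_equal(nrow(on$btmb_set), 3)
  expect_equal(nrow(off$btmb_set), 1)
})

test_that("bTMB is the eligible count per megabase", {
  expect_equal(compute_btmb(make_calls(rep(0.05, 12)), 1.0), 12.0)
  expect_equal(compute_btmb(make_calls(rep(0.05, 11)), 1.1), 10.0)
  expect_equal(compute_btmb(make_calls(numeric(0)), 1.0), 0.0)
  expect_error(compute_btmb(make_calls(0.05), 0), "positive")
})

test_that("mean AF is the arithmetic mean, zero on empty sets", {
  expect_equal(compute_mean_af(c(0.05, 0.15)), 0.10)
  expect_equal(compute_mean_af(0.08), 0.08)
  expect_equal(compute_mean_af(numeric(0)), 0.0)
})

test_that("ctDNA mass is cfDNA mass times mean AF", {
  expect_equal(estimate_ctdna_mass(25, 0.08), 2.0)
  expect_equal(estimate_ctdna_mass(30, 0.0), 0.0)
  expect_equal(estimate_ctdna_mass(10, 0.5), 5.0)
  expect_error(estimate_ctdna_mass(-1, 0.1), "nonnegative")
  expect_error(estimate_ctdna_mass(10, 1.2), "\\[0, 1\\]")
})

test_that("adjusted bTMB divides by ctDNA mass; zero mass follows policy", {
  expect_equal(adjust_btmb(16, 2.0), 8.0)
  expect_equal(adjust_btmb(0, 1.5), 0.0)
  expect_true(is.na(adjust_btmb(10, 0)))
  pol <- eligibility_policy(zero_mass_policy = "epsilon_floor",
                            epsilon_mass_ng = 0.5)
  expect_equal(adjust_btmb(10, 0, pol), 20)
})

test_that("DCB classification is boundary-inclusive at 6 months", {
  pol <- eligibility_policy()
  expect_equal(as.character(classify_dcb(7.2, 1, pol)), "DCB")
  expect_equal(as.character(classify_dcb(6.0, 1, pol)), "DCB")
  expect_equal(as.character(classify_dcb(6.0, 0, pol)), "DCB")
  expect_equal(as.character(classify_dcb(4.0, 1, pol)), "NDB")
  expect_equal(as.character(classify_dcb(4.0, 0, pol)), "indeterminate")
  pol2 <- eligibility_policy(dcb_indeterminate = "ndb")
  expect_equal(as.character(classify_dcb(4.0, 0, pol2)), "NDB")
  expect_error(classify_dcb(-1, 1), "nonnegative")
})

test_that("score_cohort composes per-patient quantities and records reasons", {
  clinical <- data.frame(patient_id = c("A", "B", "C"),
                         arm = c("ICI", "ICI", "comparator"),
                         stringsAsFactors = FALSE)
  variants <- data.frame(
    patient_id = c("A", "A", "B"), chrom = "1", pos = 1:3, ref = "A",
    alt = "T", allele_fraction = c(0.10, 0.30, 0.05), depth = 100L,
    variant_class = "SNV", driver_flag = FALSE, germline_flag = FALSE,
    stringsAsFactors = FALSE)
  plasma <- data.frame(patient_id = c("A", "B"),
                       cfdna_input_mass_ng = c(20, 10),
                       stringsAsFactors = FALSE)
  pr <- score_cohort(clinical, variants, plasma, panel_size_mb = 1)
  expect_equal(nrow(pr), 3)
  a <- pr[pr$patient_id == "A", ]
  expect_equal(a$btmb, 2); expect_equal(a$mean_af, 0.20)
  expect_equal(a$ctdna_input_mass_ng, 4)
  expect_equal(a$adjusted_btmb, 0.5)
  # defining identity: adjusted x ctDNA mass = bTMB
  def <- !is.na(pr$adjusted_btmb)
  expect_equal(pr$adjusted_btmb[def] * pr$ctdna_input_mass_ng[def],
               pr$btmb[def], tolerance = 1e-12)
  expect_equal(pr$undefined_reason, c("none", "none", "missing_plasma"))

  # orphan variant rows are a reconciliation error naming the id
  bad <- rbind(variants,
               within(variants[1, ], patient_id <- "GHOST"))
  expect_error(score_cohort(clinical, bad, plasma), "GHOST")
})

test_that("patients without variant rows score bTMB 0 with reason no_variants", {
  clinical <- data.frame(patient_id = "Z", arm = "ICI", stringsAsFactors = FALSE)
  variants <- make_calls(numeric(0))
  plasma <- data.frame(patient_id = "Z", cfdna_input_mass_ng = 15,
                       stringsAsFactors = FALSE)
  pr <- score_cohort(clinical, variants, plasma)
  expect_equal(pr$btmb, 0)
  expect_equal(pr$mean_af, 0)
  expect_true(is.na(pr$adjusted_btmb))
  expect_equal(pr$undefined_reason, "no_variants")
})

test_that("simulated cohort profiles match independent row-by-row recomputation", {
  co <- simulate_cohort(sim_config(n_patients = 200, seed = 42))
  pol <- eligibility_policy()
  pr <- score_cohort(co$clinical, co$variants, co$plasma, pol, 1.0)
  for (i in sample(nrow(co$clinical), 40)) {
    id <- co$clinical$patient_id[i]
    vc <- co$variants[co$variants$patient_id == id, ]
    som <- vc[!vc$germline_flag, ]
    elig <- som[som$allele_fraction >= 0.005 &
                  som$variant_class %in% c("SNV", "insertion", "deletion"), ]
    mass <- co$plasma$cfdna_input_mass_ng[co$plasma$patient_id == id]
    btmb <- nrow(elig) / 1.0
    maf <- if (nrow(som)) mean(som$allele_fraction) else 0
    row <- pr[pr$patient_id == id, ]
    expect_equal(row$btmb, btmb)
    expect_equal(row$mean_af, maf)
    expect_equal(row$ctdna_input_mass_ng, mass * maf)
    if (maf > 0) expect_equal(row$adjusted_btmb, btmb / (mass * maf))
    else expect_true(is.na(row$adjusted_btmb))
  }
})

test_that("rescaling every AF by c scales mean AF and divides the adjusted score by c", {
  af <- c(0.02, 0.08, 0.11, 0.27)
  cc <- 0.5   # keeps every AF above the floor
  p1 <- score_cohort(
    data.frame(patient_id = "P1", arm = "ICI", stringsAsFactors = FALSE),
    make_calls(af),
    data.frame(patient_id = "P1", cfdna_input_mass_ng = 30,
               stringsAsFactors = FALSE))
  p2 <- score_cohort(
    data.frame(patient_id = "P1", arm = "ICI", stringsAsFactors = FALSE),
    make_calls(af * cc),
    data.frame(patient_id = "P1", cfdna_input_mass_ng = 30,
               stringsAsFactors = FALSE))
  expect_equal(p2$btmb, p1$btmb)
  expect_equal(p2$mean_af, p1$mean_af * cc)
  expect_equal(p2$adjusted_btmb, p1$adjusted_btmb / cc, tolerance = 1e-12)
})

test_that("adding an eligible variant never decreases bTMB", {
  set.seed(31)
  for (trial in 1:20) {
    af <- stats::runif(sample(1:10, 1), 0.01, 0.4)
    b0 <- compute_btmb(filter_eligible_variants(make_calls(af))$btmb_set, 1)
    b1 <- compute_btmb(filter_eligible_variants(
      make_calls(c(af, stats::runif(1, 0.01, 0.4))))$btmb_set, 1)
    expect_gte(b1, b0)
  }
})
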