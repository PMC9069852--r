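test_that("Kaplan-Meier product-limit values match hand computation", {
  k1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$survival, c(2/3, 1/3, 0))
  expect_equal(k1$median, 2)

  # censoring at t=2 leaves a risk set of 1 at t=3
  k2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k2$survival[k2$time == 1], 2/3)
  expect_equal(k2$survival[k2$time == 3], 0)

  k3 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(k3$survival == 1))
  expect_true(is.na(k3$median))
  expect_true(is.na(median_survival(k3)))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(41)
  t <- stats::rexp(40)
  k <- km_estimate(t, rep(1, 40))
  expect_equal(k$survival, 1 - stats::ecdf(t)(k$time), tolerance = 1e-12)
})

test_that("Greenwood standard errors match the explicit formula on a toy curve", {
  k <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  # at t=2: S = 1/2, var = S^2 (1/(4*3) + 1/(3*2))
  expect_equal(k$greenwood_se[k$time == 2],
               0.5 * sqrt(1/12 + 1/6), tolerance = 1e-12)
})

test_that("median survival uses the first time the curve drops to one half", {
  k <- km_estimate(c(5, 10, 15, 20), c(1, 1, 1, 1))
  # S(10) = 0.5 exactly -> median 10 under the step convention
  expect_equal(median_survival(k), 10)
})

test_that("log-rank on identical groups is null; hand-computed instance matches", {
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 0)
  r <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  # 6-patient instance, hand O-E/V computation
  times <- c(1, 2, 3, 4, 5, 6); events <- rep(1, 6)
  grp <- c(0, 1, 0, 1, 0, 1)
  o_minus_e <- 0; v <- 0
  for (j in seq_along(times)) {
    risk <- times >= times[j]
    n1 <- sum(risk & grp == 0); ntot <- sum(risk)
    o_minus_e <- o_minus_e + (grp[j] == 0) - n1 / ntot
    v <- v + (n1 / ntot) * (1 - n1 / ntot)
  }
  r2 <- logrank_test(times, events, grp)
  expect_equal(r2$statistic, o_minus_e^2 / v, tolerance = 1e-10)
  expect_error(logrank_test(times, events, rep(1, 6)), "groups")
})

test_that("log-rank rejects at about the nominal rate under a permuted null", {
  set.seed(42)
  rej <- mean(replicate(500, {
    t <- stats::rexp(40); e <- stats::rbinom(40, 1, 0.8)
    g <- sample(rep(0:1, each = 20))
    logrank_test(t, e, g)$p_value < 0.05
  }))
  expect_gt(rej, 0.025); expect_lt(rej, 0.085)
})

test_that("Cox coefficient matches golden-section maximization of the exact partial likelihood", {
  set.seed(43)
  for (trial in 1:12) {
    d <- random_survival_data(8)
    fit <- cox_fit(data.frame(x = d$x), d$times, d$events, ties = "breslow")
    opt <- stats::optimize(function(b)
      -oracle_cox_loglik_breslow(b, d$x, d$times, d$events),
      interval = c(-8, 8), tol = 1e-7)
    expect_equal(fit$coef, opt$minimum, tolerance = 1e-3)
    # Efron route against its own oracle
    fe <- cox_fit(data.frame(x = d$x), d$times, d$events, ties = "efron")
    oe <- stats::optimize(function(b)
      -oracle_cox_loglik_efron(b, d$x, d$times, d$events),
      interval = c(-8, 8), tol = 1e-7)
    expect_equal(fe$coef, oe$minimum, tolerance = 1e-3)
  }
})

test_that("log-rank chi-square equals the squared Cox score statistic (Breslow, untied times)", {
  set.seed(44)
  for (trial in 1:10) {
    d <- random_survival_data(30)
    lr <- logrank_test(d$times, d$events, d$x)
    cf <- cox_fit(data.frame(x = d$x), d$times, d$events, ties = "breslow")
    expect_equal(lr$statistic, cf$score_stat, tolerance = 1e-8)
  }
})

test_that("a covariate unrelated to survival estimates near zero at large n", {
  co <- simulate_cohort(sim_config(n_patients = 5000, seed = 77),
                        include_variants = FALSE)
  set.seed(77)
  noise <- stats::rnorm(5000)
  fit <- cox_fit(data.frame(noise = noise), co$clinical$os_months,
                 co$clinical$os_event)
  expect_lt(abs(fit$coef), 0.07)
})

test_that("Cox estimates are invariant to affine covariate shifts and to subject duplication", {
  set.seed(45)
  d <- random_survival_data(40)
  x2 <- stats::rnorm(40)
  f1 <- cox_fit(data.frame(a = d$x, b = x2), d$times, d$events)
  f2 <- cox_fit(data.frame(a = d$x + 100, b = x2 - 3), d$times, d$events)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)

  fd <- cox_fit(data.frame(a = rep(d$x, 2)), rep(d$times, 2),
                rep(d$events, 2), ties = "breslow")
  f0 <- cox_fit(data.frame(a = d$x), d$times, d$events, ties = "breslow")
  expect_equal(fd$hazard_ratio, f0$hazard_ratio, tolerance = 1e-6)
})

test_that("rank-deficient designs and monotone likelihoods raise diagnostic errors", {
  set.seed(46)
  d <- random_survival_data(20)
  expect_error(cox_fit(data.frame(a = d$x, b = 2 * d$x), d$times, d$events),
               "collinear")
  # perfect separation: all events in one covariate group, ordered times
  t <- c(1:5, 11:15); e <- rep(1, 10); x <- rep(c(1, 0), each = 5)
  expect_error(cox_fit(data.frame(x = x), t, e), "diverging|monotone")
})

test_that("interaction analysis reports the product-term Wald p and stratum HRs", {
  co <- simulate_cohort(sim_config(n_patients = 600, seed = 9),
                        include_variants = FALSE)
  ia <- interaction_analysis(co$clinical, co$truth$latent_high, "OS")
  expect_true(ia$interaction_p >= 0 && ia$interaction_p <= 1)
  expect_setequal(ia$stratum_hr$stratum, c("marker_high", "marker_low"))
  # relabeling symmetry: swapping the marker flips the coefficient sign
  ia2 <- interaction_analysis(co$clinical, 1 - co$truth$latent_high, "OS")
  expect_equal(ia2$interaction_coef, -ia$interaction_coef, tolerance = 1e-6)
  expect_equal(ia2$interaction_p, ia$interaction_p, tolerance = 1e-6)
  # empty cell detection
  expect_error(
    interaction_analysis(co$clinical, rep(TRUE, nrow(co$clinical)), "OS"),
    "empty")
})
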