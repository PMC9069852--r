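# Independent oracles used across the suite. These deliberately use
# brute-force enumeration / naive formulas, never the package's own code
# paths.

# All-pairs concordance (ties = 1/2) by explicit double loop.
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# Exhaustive Youden search over every attained threshold with the
# score >= t classification rule; ties to the smallest attaining score.
oracle_youden <- function(scores, labels) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  jmax <- max(j)
  list(cutoff = min(thr[j == jmax]), j = jmax)
}

# Exact Cox partial log-likelihood for one covariate, Breslow ties.
oracle_cox_loglik_breslow <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    dead <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + sum(beta * x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Exact Cox partial log-likelihood, Efron ties.
oracle_cox_loglik_efron <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    dead <- which(times == t & events == 1)
    risk <- which(times >= t)
    d <- length(dead)
    sr <- sum(exp(beta * x[risk])); sd_ <- sum(exp(beta * x[dead]))
    ll <- ll + sum(beta * x[dead]) -
      sum(log(sr - (seq_len(d) - 1) / d * sd_))
  }
  ll
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration with the point-probability rule.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  pobs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all label assignments.
oracle_mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, u_of)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Closed-form probability of the latent biomarker-high group under the
# generator: numerical integration over mutation count (discrete),
# shed AF (lognormal product with cap) and cfDNA mass (lognormal CDF).
oracle_latent_high_prob <- function(cfg) {
  g <- function(a) ifelse(cfg$detection_slope * a < 1,
                          cfg$detection_slope, 1 / a)
  w_meanlog <- cfg$burden_logmean + log(cfg$shedding_slope)
  w_sdlog <- sqrt(cfg$burden_logsd^2 + cfg$shedding_noise_sd^2)
  m_max <- stats::qnbinom(1 - 1e-10, size = cfg$mutload_dispersion,
                          mu = cfg$mutload_mean)
  p_cap <- stats::plnorm(cfg$af_cap, w_meanlog, w_sdlog, lower.tail = FALSE)
  total <- 0
  for (m in 0:m_max) {
    pm <- stats::dnbinom(m, size = cfg$mutload_dispersion,
                         mu = cfg$mutload_mean)
    if (m == 0) next  # expected score 0: never latent-high (cutoff > 0)
    f <- function(a)
      stats::dlnorm(a, w_meanlog, w_sdlog) *
        stats::plnorm(m * g(a) / (cfg$panel_size_mb * cfg$true_cutoff),
                      cfg$cfdna_logmean, cfg$cfdna_logsd)
    int <- stats::integrate(f, lower = 1e-8, upper = cfg$af_cap,
                            rel.tol = 1e-9, subdivisions = 500L)$value
    at_cap <- p_cap *
      stats::plnorm(m * g(cfg$af_cap) / (cfg$panel_size_mb * cfg$true_cutoff),
                    cfg$cfdna_logmean, cfg$cfdna_logsd)
    total <- total + pm * (int + at_cap)
  }
  total
}

# Small survival dataset with continuous (tie-free) times and a binary
# covariate, guaranteed to have events in both covariate groups and a
# finite partial-likelihood maximizer (screened with the oracle likelihood,
# independently of the code under test).
random_survival_data <- function(n, beta = 0.5) {
  repeat {
    x <- stats::rbinom(n, 1, 0.5)
    t <- stats::rexp(n, exp(beta * x))
    e <- stats::rbinom(n, 1, 0.8)
    if (!(sum(e) >= 2 && length(unique(x)) == 2 &&
          sum(e[x == 0]) >= 1 && sum(e[x == 1]) >= 1 &&
          !anyDuplicated(t))) next
    bhat <- stats::optimize(function(b)
      -oracle_cox_loglik_breslow(b, x, t, e), c(-12, 12), tol = 1e-8)$minimum
    if (abs(bhat) < 5) return(list(x = x, times = t, events = e))
  }
}

# All permutations of 1..n (tiny n only).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (p in combinat_perms(n - 1))
      out[[length(out) + 1L]] <- c(k, setdiff(1:n, k)[p])
  }
  out
}
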