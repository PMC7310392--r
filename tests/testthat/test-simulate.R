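test_that("simulate_subjects draws the right cohort size and covariances", {
  cfg <- sim_config(seed = 4)
  subj <- simulate_subjects(cfg)
  expect_equal(nrow(subj), 219L)
  expect_true(all(subj$age_group %in% c("18-20", "21-39", ">=40")))

  # degenerate covariance: all random effects exactly zero
  p0 <- default_true_params(); p0$D <- matrix(0, 2, 2)
  cfg0 <- sim_config(true_params = p0, seed = 4)
  subj0 <- simulate_subjects(cfg0)
  expect_true(all(subj0$u0 == 0) && all(subj0$u1 == 0))

  # large-sample covariance within 3 Monte-Carlo SEs of the target D
  D <- matrix(c(12.21, -0.36, -0.36, 0.02), 2)
  cfgN <- sim_config(n_subjects = 50000, seed = 8)
  sN <- simulate_subjects(cfgN)
  S <- cov(cbind(sN$u0, sN$u1))
  n <- 50000
  se_var <- function(v) v * sqrt(2 / n)
  se_cov <- sqrt((D[1, 1] * D[2, 2] + D[1, 2]^2) / n)
  expect_lt(abs(S[1, 1] - D[1, 1]), 3 * se_var(D[1, 1]))
  expect_lt(abs(S[2, 2] - D[2, 2]), 3 * se_var(D[2, 2]))
  expect_lt(abs(S[1, 2] - D[1, 2]), 3 * se_cov)

  # category frequencies match the configured probabilities in expectation
  p_hat <- mean(sN$sex_under_alcohol)
  p <- 22 / 219
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("invalid random-effects covariance is rejected", {
  bad <- default_true_params()
  bad$D <- matrix(c(1, 2, 2, 1), 2)   # not PSD
  expect_error(sim_config(true_params = bad), "positive semidefinite")
})

test_that("simulate_visits honors the visit process", {
  # zero follow-up: exactly the baseline visit
  cfg0 <- sim_config(n_subjects = 25, max_followup = 0, seed = 2)
  v0 <- simulate_visits(simulate_subjects(cfg0), cfg0)
  expect_equal(nrow(v0), 25L)
  expect_true(all(v0$time == 0))

  # default config: follow-up bounded by the configured maximum
  cfg <- sim_config(n_subjects = 300, seed = 6)
  v <- simulate_visits(simulate_subjects(cfg), cfg)
  expect_true(all(v$time >= 0 & v$time <= 13.13))
  expect_true(all(tapply(v$time, v$subject_id, min) == 0))

  # Poisson process: mean visits/subject = 1 + rate * horizon
  cfgP <- sim_config(n_subjects = 10000, max_followup = 10, visit_rate = 2,
                     followup = list(type = "fixed"), seed = 3)
  vP <- simulate_visits(simulate_subjects(cfgP), cfgP)
  mean_visits <- nrow(vP) / 10000
  expect_lt(abs(mean_visits - 21), 3 * sqrt(20 / 10000))
})

test_that("phases are assigned from time and treatment", {
  cfg <- sim_config(n_subjects = 150, seed = 13)
  coh <- simulate_cohort(cfg)
  pre <- coh[coh$on_cart == 0, ]
  expect_true(all(pre$phase[pre$time < 0.25] == "II"))
  expect_true(all(pre$phase[pre$time >= 0.25 & pre$time < 1] == "III"))
  expect_true(all(pre$phase[pre$time >= 1] == "IV"))
  expect_true(all(coh$phase[coh$on_cart == 1] == "V"))
})

test_that("ordinal outcomes follow the threshold-implied distribution", {
  # saturated threshold: P(Y <= 1) ~ 1 gives all-normal stages
  cfg <- recovery_config(n_subjects = 50, horizon = 2, D = matrix(0, 2, 2))
  sat <- param_vector(c(15, 16, 17), D = matrix(0, 2, 2))
  subj <- simulate_subjects(cfg, seed = 1)
  v <- simulate_visits(subj, cfg, seed = 1)
  out <- simulate_ordinal_outcomes(v, sat, seed = 1)
  expect_true(all(out$stage == 1L))

  # uniform quartile thresholds: equal long-run category frequencies
  unif <- param_vector(qlogis(c(0.25, 0.5, 0.75)), D = matrix(0, 2, 2))
  cfgU <- recovery_config(n_subjects = 3000, horizon = 3, rate = 1,
                          D = matrix(0, 2, 2))
  vU <- simulate_visits(simulate_subjects(cfgU, seed = 2), cfgU, seed = 2)
  outU <- simulate_ordinal_outcomes(vU, unif, seed = 2)
  freq <- tabulate(outU$stage, 4) / nrow(outU)
  se <- sqrt(0.25 * 0.75 / nrow(outU))
  expect_true(all(abs(freq - 0.25) < 3 * se))

  # reported-scale thresholds: P(stage = 1) = 0.02/1.02
  tab3 <- param_vector(log(c(0.02, 19.87, 24.51)), D = matrix(0, 2, 2))
  outT <- simulate_ordinal_outcomes(vU, tab3, seed = 3)
  p1 <- 0.02 / 1.02
  expect_lt(abs(mean(outT$stage == 1) - p1),
            3 * sqrt(p1 * (1 - p1) / nrow(outT)))
})

test_that("simulated CD4 counts round-trip staging and cART is absorbing", {
  cfg <- sim_config(n_subjects = 200, seed = 17)
  coh <- simulate_cohort(cfg)
  expect_equal(who_stage(coh$cd4), coh$stage)
  for (id in unique(coh$subject_id)) {
    oc <- coh$on_cart[coh$subject_id == id]
    expect_true(all(diff(oc) >= 0))
  }
})

test_that("cART starts at the visit after the triggering stage", {
  cfg <- sim_config(n_subjects = 120, seed = 23)
  coh <- simulate_cohort(cfg)
  for (id in unique(coh$subject_id)) {
    sub <- coh[coh$subject_id == id, ]
    sub <- sub[order(sub$time), ]
    expected <- c(0L, as.integer(cumsum(sub$stage >= 2) > 0))[seq_len(nrow(sub))]
    expect_equal(sub$on_cart, expected)
  }
})

test_that("non-monotone generating parameters abort with the offending row", {
  cfg <- recovery_config(n_subjects = 30, horizon = 3)
  bad <- param_vector(log(c(0.02, 19.87, 24.51)),
                      npo = cbind(log_vl = c(-2, 0, 2)),
                      D = matrix(0, 2, 2))
  subj <- simulate_subjects(cfg, seed = 5)
  v <- simulate_visits(subj, cfg, seed = 5)
  expect_error(simulate_ordinal_outcomes(v, bad, seed = 5),
               "non-monotone.*subject", )
})

test_that("same seed and config give byte-identical cohorts", {
  cfg <- sim_config(n_subjects = 60, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 32)
  expect_false(identical(a$stage, c2$stage))
})

test_that("simulate_clinical_panel reproduces the factor model", {
  # noiseless single factor: every column equals the factor
  one <- simulate_clinical_panel(matrix(1, 4, 1), n = 200, noise_sd = 0,
                                 seed = 3)
  expect_true(all(abs(one$X - one$factors[, 1]) < 1e-12))

  # two-factor block structure: within-block correlation 0.81/(0.81 + s2)
  L <- rbind(c(0.9, 0), c(0.9, 0), c(0, 0.9), c(0, 0.9))
  pan <- simulate_clinical_panel(L, n = 5000, noise_sd = 0.5, seed = 7)
  r <- cor(pan$X)
  target <- 0.81 / (0.81 + 0.25)
  expect_lt(abs(r[1, 2] - target), 0.04)
  expect_lt(abs(r[3, 4] - target), 0.04)
  expect_lt(abs(r[1, 3]), 0.05)
  expect_error(simulate_clinical_panel(matrix(1, 2, 3), 10), "more rows")
})
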