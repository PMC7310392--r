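# minimal fitted-model stand-ins for arithmetic-level checks of the
# comparison operations
mock_fit <- function(minus2loglik, npo_cols = character(),
                     shared_cols = c("time", "x"), K = 4,
                     est = NULL, se = NULL) {
  nms <- c(paste0("delta_", seq_len(K - 1)), shared_cols)
  est <- if (is.null(est)) setNames(rep(0, length(nms)), nms) else est
  se <- if (is.null(se)) setNames(rep(0.1, length(est)), names(est)) else se
  structure(list(minus2loglik = minus2loglik, K = K, n = 100,
                 npo_cols = npo_cols, shared_cols = shared_cols,
                 estimates = est, se = se,
                 ci = cbind(lower = est - 1.96 * se,
                            upper = est + 1.96 * se),
                 icc = 0.5, converged = TRUE,
                 spec = list(random = "intercept")),
            class = "ogm")
}

test_that("LR test arithmetic: statistic, df rule, and p-value", {
  po <- mock_fit(1000, shared_cols = c(paste0("x", 1:18)))
  npo <- mock_fit(1000, npo_cols = paste0("x", 1:18), shared_cols = character())
  out <- lr_proportionality_test(po, npo)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_false(out$reject)
  # 18 freed covariates with K = 4: (K-2) * m = 36 degrees of freedom
  expect_equal(out$df, 36L)

  npo2 <- mock_fit(840, npo_cols = paste0("x", 1:18),
                   shared_cols = character())
  out2 <- lr_proportionality_test(po, npo2)
  expect_equal(out2$statistic, 160)
  expect_equal(out2$p_value, pchisq(160, 36, lower.tail = FALSE))
  expect_true(out2$reject)

  # negative statistics beyond tolerance demand a refit
  npo3 <- mock_fit(1000.01, npo_cols = paste0("x", 1:18),
                   shared_cols = character())
  expect_error(lr_proportionality_test(po, npo3), "refit")
  # non-nested specifications are refused
  expect_error(lr_proportionality_test(po, mock_fit(900, npo_cols = "y")),
               "not nested")
  expect_error(lr_proportionality_test(po, mock_fit(900, npo_cols = character(),
                                                    shared_cols = c(paste0("x", 1:18)))),
               "no category-specific")
})

test_that("LR statistic is invariant to affine covariate rescaling", {
  cfg <- recovery_config(n_subjects = 70, horizon = 4, rate = 1,
                         D = matrix(c(2, 0, 0, 0), 2), random = "intercept")
  coh <- simulate_cohort(cfg, seed = 19)
  fit_pair <- function(d) {
    po <- ogm(d, recovery_spec("intercept"), quad_order = 5, se = FALSE,
              control = list(rel.tol = 1e-12))
    npo <- ogm(d, model_spec(shared = c("time", "log_vl"),
                             npo = "sex_under_alcohol", random = "intercept"),
               quad_order = 5, init = po, se = FALSE,
               control = list(rel.tol = 1e-12))
    lr_proportionality_test(po, npo)$statistic
  }
  s1 <- fit_pair(coh)
  coh2 <- coh
  coh2$log_vl <- 2 * coh2$log_vl
  coh2$sex_under_alcohol <- 3 * coh2$sex_under_alcohol
  s2 <- fit_pair(coh2)
  expect_lt(abs(s1 - s2), 1e-3)
})

test_that("DIC comparison prefers the lower-DIC model and respects pD = 0", {
  mk <- function(dbar, pD, converged = TRUE)
    structure(list(dbar = dbar, pD = pD, dic = dbar + pD,
                   converged = converged, warnings = if (converged) character(0)
                   else "acceptance rate 0.05 outside [0.1, 0.6]"),
              class = "ogm_mcmc")
  same <- compare_dic(mk(100, 5), mk(100, 5))
  expect_equal(same$delta_dic, 0)
  deg <- compare_dic(mk(100, 0), mk(90, 0))
  expect_equal(deg$table$dic, deg$table$dbar)
  expect_equal(deg$preferred, "non-proportional")
  nc <- compare_dic(mk(100, 5, converged = FALSE), mk(90, 5))
  expect_true(is.na(nc$preferred))
  expect_match(nc$warnings, "acceptance")
})

test_that("DIC prefers the NPO model under strong category-specific effects", {
  pars <- param_vector(log(c(0.05, 5, 9)),
                       shared = c(time = 0.2, log_vl = -0.3),
                       npo = cbind(sex_under_alcohol = c(-1.2, 0.2, 1.5)),
                       D = matrix(c(2, 0, 0, 0), 2))
  specs <- default_covariate_specs()
  specs$visit <- list(log_vl = list(type = "normal", mean = 0, sd = 0.85))
  specs$subject <- list(sex_under_alcohol = list(type = "binary", prob = 0.5))
  cfg <- sim_config(n_subjects = 150, max_followup = 4, visit_rate = 1,
                    followup = list(type = "fixed"), true_params = pars,
                    covariate_specs = specs, cart_rule = 99,
                    panel_loadings = NULL, seed = 27)
  coh <- simulate_cohort(cfg)
  sp_po <- model_spec(shared = c("time", "log_vl", "sex_under_alcohol"),
                      random = "intercept")
  sp_npo <- model_spec(shared = c("time", "log_vl"),
                       npo = "sex_under_alcohol", random = "intercept")
  po <- ogm(coh, sp_po, quad_order = 5, se = FALSE)
  npo <- ogm(coh, sp_npo, quad_order = 5, init = po, se = FALSE)
  mc_po <- ogm_mcmc(coh, sp_po, iters = 1200, burnin = 400, quad_order = 5,
                    seed = 1, init = po)
  mc_npo <- ogm_mcmc(coh, sp_npo, iters = 1200, burnin = 400, quad_order = 5,
                     seed = 2, init = npo)
  cmp <- compare_dic(mc_po, mc_npo)
  expect_equal(cmp$preferred, "non-proportional")
  expect_gt(cmp$delta_dic, 0)
})

test_that("odds-ratio table lays out estimates per cumulative logit", {
  est <- setNames(c(log(0.02), log(19.87), log(24.51), 0, 0.5),
                  c("delta_1", "delta_2", "delta_3", "x", "time"))
  se <- setNames(c(0.3, 0.3, 0.3, 0.1, 0.05), names(est))
  fit <- mock_fit(500, shared_cols = c("x", "time"), est = est, se = se)
  tab <- odds_ratio_table(fit)
  # thresholds exponentiate to the reported scale
  thr <- tab[tab$block == "threshold", ]
  expect_equal(thr$or, c(0.02, 19.87, 24.51), tolerance = 1e-12)
  # zero coefficient with SE 0.1: OR 1.00, CI exp(+-1.96 * 0.1)
  xr <- tab[tab$term == "x", ]
  expect_equal(nrow(xr), 3L)                 # repeated across the three logits
  expect_equal(unique(round(xr$or, 10)), 1)
  expect_equal(xr$ci_low, rep(exp(-0.196), 3), tolerance = 1e-10)
  expect_equal(xr$ci_high, rep(exp(0.196), 3), tolerance = 1e-10)
  # shared covariate repeats the identical OR in every logit column
  expect_equal(length(unique(xr$or)), 1L)
  # time classifies into the slope block; diagnostics carry ICC and -2logL
  expect_true(all(tab$block[tab$term == "time"] == "time_slope"))
  expect_true(all(c("icc_latent", "minus2loglik") %in%
                    tab$term[tab$block == "diagnosis"]))
  expect_output(print(tab), "logit 3")
})
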