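test_that("single-level fit matches the established cumulative-logit fitter", {
  cfg <- recovery_config(n_subjects = 250, horizon = 3, rate = 1,
                         D = matrix(0, 2, 2), random = "slope")
  coh <- simulate_cohort(cfg)
  sp <- model_spec(shared = c("time", "log_vl", "sex_under_alcohol"),
                   random = "none")
  fit <- ogm(coh, sp, quad_order = 1,
             control = list(rel.tol = 1e-12))
  ref <- MASS::polr(factor(stage) ~ time + log_vl + sex_under_alcohol,
                    data = coh, method = "logistic",
                    control = list(reltol = 1e-12))
  # identical model, opposite coefficient sign convention:
  # ours: logit P(Y<=k) = delta_k + x'beta; polr: zeta_k - x'beta
  expect_lt(max(abs(fit$params$thresholds - ref$zeta)), 1e-3)
  expect_lt(max(abs(fit$params$shared - (-coef(ref)))), 1e-3)
  expect_lt(abs(fit$minus2loglik - ref$deviance), 1e-3)
})

test_that("estimates recover generating parameters on one mid-size cohort", {
  cfg <- recovery_config(n_subjects = 300, horizon = 5, rate = 1)
  coh <- simulate_cohort(cfg, seed = 42)
  fit <- ogm(coh, recovery_spec(), quad_order = 5)
  expect_true(fit$converged)
  true <- c(log(c(0.02, 19.87, 24.51)), 0.3, -0.58, 0.35)
  est <- fit$estimates[1:6]
  z <- (est - true) / fit$se[1:6]
  expect_true(all(abs(z) < 3.5))
  expect_gt(fit$estimates["var_u0"], 5)
  expect_gt(fit$icc, 0.5)
})

test_that("the NPO model never fits worse than the nested PO model", {
  cfg <- recovery_config(n_subjects = 80, horizon = 4, rate = 1,
                         D = matrix(c(4, 0, 0, 0), 2), random = "intercept")
  coh <- simulate_cohort(cfg, seed = 7)
  po <- ogm(coh, recovery_spec("intercept"), quad_order = 5)
  npo <- ogm(coh, model_spec(shared = c("time", "log_vl"),
                             npo = "sex_under_alcohol",
                             random = "intercept"),
             quad_order = 5, init = po)
  expect_lte(npo$minus2loglik, po$minus2loglik + 1e-4)
})

test_that("fitted effect signs follow the data-generating direction", {
  cfg <- recovery_config(n_subjects = 150, horizon = 4, rate = 1,
                         D = matrix(c(2, 0, 0, 0), 2),
                         beta = c(time = 0, log_vl = 0,
                                  sex_under_alcohol = 1.5),
                         random = "intercept")
  coh <- simulate_cohort(cfg, seed = 8)
  fit <- ogm(coh, recovery_spec("intercept"), quad_order = 5)
  expect_gt(fit$params$shared[["sex_under_alcohol"]], 0)
  # and predicted P(normal) rises with the positively acting covariate
  nd <- coh[1:2, ]
  nd$sex_under_alcohol <- c(0, 1)
  nd$time <- 0; nd$log_vl <- 0
  P <- predict(fit, nd)
  expect_gt(P[2, 1], P[1, 1])
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
})

test_that("unobserved outcome categories are rejected with advice", {
  cfg <- recovery_config(n_subjects = 30, horizon = 2, D = matrix(0, 2, 2))
  coh <- simulate_cohort(cfg)
  coh$stage[coh$stage == 4] <- 3
  expect_error(ogm(coh, recovery_spec("intercept")), "merge")
})

test_that("fit accessors expose the standard modelling interface", {
  cfg <- recovery_config(n_subjects = 60, horizon = 3, rate = 1,
                         D = matrix(c(2, 0, 0, 0), 2),
                         thresholds = log(c(0.05, 5, 9)),
                         random = "intercept")
  coh <- simulate_cohort(cfg, seed = 3)
  fit <- ogm(coh, recovery_spec("intercept"), quad_order = 5)
  expect_named(coef(fit))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), -fit$minus2loglik / 2)
  expect_equal(attr(ll, "df"), fit$n_params)
  # Wald intervals contain the point estimates
  expect_true(all(fit$ci[, 1] <= fit$estimates & fit$estimates <= fit$ci[, 2]))
  expect_output(print(fit), "proportional odds")
  expect_output(print(summary(fit)), "ICC")
  # simulate() returns stages of the right shape, deterministically per seed
  s1 <- simulate(fit, nsim = 2, seed = 5, newdata = coh)
  s2 <- simulate(fit, nsim = 2, seed = 5, newdata = coh)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(nrow(coh), 2L))
  expect_true(all(unlist(s1) %in% 1:4))
})

test_that("design construction expands factors and interactions correctly", {
  cfg <- sim_config(n_subjects = 25, seed = 2)
  coh <- simulate_cohort(cfg)
  sp <- model_spec(shared = c("time", "education"), npo = "on_cart",
                   time_interactions = "on_cart", random = "slope")
  b <- build_design(coh, sp,
                    reference_levels = list(education = c("<=Gr8", "Gr9-10",
                                                          ">=Gr11")))
  expect_equal(b$n, nrow(coh))
  expect_true(all(c("education=Gr9-10", "education=>=Gr11", "on_cart:time")
                  %in% colnames(b$Xs)))
  expect_equal(colnames(b$Xn), "on_cart")
  i <- match("on_cart:time", colnames(b$Xs))
  ord <- order(match(coh$subject_id, unique(coh$subject_id)), coh$time)
  expect_equal(unname(b$Xs[, i]), coh$on_cart[ord] * coh$time[ord])
  # empty npo set reduces to the proportional-odds design
  b0 <- build_design(coh, model_spec(shared = "time", random = "slope"))
  expect_equal(ncol(b0$Xn), 0L)
  expect_error(build_design(coh, model_spec(shared = "nope")), "missing column")
  coh2 <- coh; coh2$education[1] <- "other"
  expect_error(build_design(coh2, sp,
                            reference_levels = list(education = c("<=Gr8",
                                                                  "Gr9-10",
                                                                  ">=Gr11"))),
               "unseen category")
  expect_error(model_spec(shared = "x", npo = "x"), "disjoint")
})
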