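# Shared fixtures, built in code.

# subject-level table encoding the printed baseline counts of the cohort
# (denominator 219); used to check the descriptive arithmetic
baseline_fixture <- function() {
  expand_counts <- function(levels, counts)
    rep(levels, counts)
  data.frame(
    education = expand_counts(c("<=Gr8", "Gr9-10", ">=Gr11"), c(16, 50, 153)),
    marital = expand_counts(c("single", "stable", "many_partners"),
                            c(34, 174, 11)),
    contraceptive = expand_counts(c("no", "yes"), c(40, 179)),
    anemia = expand_counts(c("no", "yes"), c(208, 11)),
    tb = expand_counts(c("no", "yes"), c(201, 18)),
    immunostate = expand_counts(c("<200", "200-349", "350-499", ">=500"),
                                c(9, 41, 89, 80)),
    age_group = expand_counts(c("18-20", "21-39", ">=40"), c(29, 178, 12)),
    sex_under_alcohol = expand_counts(c("no", "yes"), c(197, 22)))
}

# small exogenous-covariate cohort configuration for estimation experiments:
# mean-zero visit covariate, binary subject covariate, no treatment dynamics
# (cART never triggers), fixed follow-up horizon
recovery_config <- function(n_subjects = 300, horizon = 5, rate = 1,
                            D = matrix(c(12.21, -0.36, -0.36, 0.02), 2),
                            beta = c(time = 0.3, log_vl = -0.58,
                                     sex_under_alcohol = 0.35),
                            thresholds = log(c(0.02, 19.87, 24.51)),
                            random = "slope") {
  pars <- param_vector(thresholds,
                       shared = beta,
                       D = if (random == "intercept")
                         matrix(c(D[1, 1], 0, 0, 0), 2) else D)
  specs <- default_covariate_specs()
  specs$visit <- list(log_vl = list(type = "normal", mean = 0, sd = 0.85))
  # balanced binary design covariate for estimation experiments
  specs$subject <- list(sex_under_alcohol = list(type = "binary", prob = 0.5))
  sim_config(n_subjects = n_subjects, max_followup = horizon,
             visit_rate = rate, followup = list(type = "fixed"),
             true_params = pars, covariate_specs = specs,
             cart_rule = 99, panel_loadings = NULL, seed = 1L)
}

recovery_spec <- function(random = "slope")
  model_spec(shared = c("time", "log_vl", "sex_under_alcohol"),
             random = random)
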