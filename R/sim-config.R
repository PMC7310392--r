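# Configuration for the synthetic longitudinal cohort generator. Defaults
# emulate the cohort the analysis targets: 219 HIV-seroconverted women
# followed for up to 13.13 years (median follow-up about 2.1 years), a
# four-category WHO immunological stage outcome with large between-subject
# heterogeneity, cART initiated once the stage falls below the CD4-500 band,
# and clinical panels with a block latent-factor structure.

#' Default generating parameters for the synthetic cohort
#'
#' Thresholds and random-effects covariance on the scale of the reported
#' fitted model (exp(thresholds) = 0.02, 19.87, 24.51; intercept variance
#' 12.21, intercept-slope covariance -0.36, slope variance 0.02). The time
#' ("visit") effect and the cART effect are category-specific; continuous
#' covariates act proportionally with odds ratios at the reported scale.
#' Continuous covariates are centered at their generating means so the
#' thresholds retain their interpretation at a typical covariate pattern.
#'
#' @return An [param_vector()] object.
#' @export
default_true_params <- function() {
  npo <- cbind(
    time = log(c(0.55, 0.66, 1.76)),
    on_cart = log(c(1.42, 1.27, 1.28)))
  param_vector(
    thresholds = log(c(0.02, 19.87, 24.51)),
    shared = c(log_vl = log(0.56),
               qol_phys = log(1.11),
               qol_psych = log(0.77),
               qol_indep = log(1.02),
               qol_social = log(0.93),
               electrolyte = log(1.09),
               rbc_indices = log(0.96),
               mononuclear = log(1.79)),
    npo = npo,
    D = matrix(c(12.21, -0.36, -0.36, 0.02), 2, 2),
    centers = c(log_vl = 4.46, qol_phys = 14, qol_psych = 14,
                qol_indep = 14, qol_social = 14))
}

#' Default covariate specifications for the synthetic cohort
#'
#' Subject-level categorical frequencies follow the reported baseline
#' distribution of the cohort (age group 29/178/12 of 219, education
#' 16/50/153, marital status 34/174/11, sex under the influence of alcohol
#' 22/219); weight is normal around 65 kg. Visit-level log10 viral load is
#' centered at the reported median 4.46 within the reported range
#' 1.47-6.81; quality-of-life domain scores live on a 4-20 scale; clinical
#' factor scores are standard normal.
#'
#' @return Named list with `subject` and `visit` covariate descriptors.
#' @export
default_covariate_specs <- function() {
  list(
    subject = list(
      age_group = list(type = "categorical",
                       levels = c("18-20", "21-39", ">=40"),
                       probs = c(29, 178, 12) / 219),
      education = list(type = "categorical",
                       levels = c("<=Gr8", "Gr9-10", ">=Gr11"),
                       probs = c(16, 50, 153) / 219),
      marital = list(type = "categorical",
                     levels = c("single", "stable", "many_partners"),
                     probs = c(34, 174, 11) / 219),
      sex_under_alcohol = list(type = "binary", prob = 22 / 219),
      weight = list(type = "normal", mean = 65, sd = 10,
                    min = 40, max = 120)),
    visit = list(
      log_vl = list(type = "normal", mean = 4.46, sd = 0.85,
                    min = 1.47, max = 6.81),
      qol_phys = list(type = "normal", mean = 14, sd = 3, min = 4, max = 20),
      qol_psych = list(type = "normal", mean = 14, sd = 3, min = 4, max = 20),
      qol_indep = list(type = "normal", mean = 14, sd = 3, min = 4, max = 20),
      qol_social = list(type = "normal", mean = 14, sd = 3, min = 4, max = 20),
      electrolyte = list(type = "normal", mean = 0, sd = 1),
      rbc_indices = list(type = "normal", mean = 0, sd = 1),
      mononuclear = list(type = "normal", mean = 0, sd = 1)))
}

#' Default clinical-panel loading matrix
#'
#' Block loading matrix tying nine observable clinical variables to the three
#' latent factor scores the generator produces (electrolyte, red-blood-cell
#' indices, mononuclear), with the within-block loading magnitudes of the
#' reported rotated solution. Used to synthesize raw panel columns so the
#' factor-reduction stage has genuine structure to recover.
#'
#' @return 9 x 3 numeric loading matrix.
#' @export
default_panel_loadings <- function() {
  L <- matrix(0, 9, 3,
              dimnames = list(
                c("sodium", "chloride", "calcium",
                  "mcv", "mch", "mchc", "rdw",
                  "lymphocytes", "basophils"),
                c("electrolyte", "rbc_indices", "mononuclear")))
  L[c("sodium", "chloride", "calcium"), "electrolyte"] <- c(0.994, 0.455, 0.213)
  L[c("mcv", "mch", "mchc", "rdw"), "rbc_indices"] <- c(0.953, 0.825, 0.521, -0.592)
  L[c("lymphocytes", "basophils"), "mononuclear"] <- c(0.838, 0.616)
  L
}

#' Build a simulation configuration
#'
#' @param n_subjects number of subjects (default 219).
#' @param max_followup maximum follow-up in years (default 13.13).
#' @param visit_rate expected visits per year after baseline (default 3).
#' @param followup visit-horizon process: `list(type = "exponential",
#'   median = 2.12)` draws a per-subject follow-up horizon with the given
#'   median (years), truncated at `max_followup`; `list(type = "fixed")`
#'   follows every subject to `max_followup`.
#' @param true_params generating [param_vector()].
#' @param covariate_specs covariate descriptors, see
#'   [default_covariate_specs()].
#' @param cart_rule stage code at or above which cART is triggered (default 2,
#'   i.e. CD4 below 500); initiation takes effect from the next visit.
#' @param panel_loadings optional loading matrix for raw clinical panel
#'   columns (`NULL` to omit them).
#' @param seed default random seed for the generator.
#' @return Validated configuration of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 219,
                       max_followup = 13.13,
                       visit_rate = 3,
                       followup = list(type = "exponential", median = 2.12),
                       true_params = default_true_params(),
                       covariate_specs = default_covariate_specs(),
                       cart_rule = 2,
                       panel_loadings = default_panel_loadings(),
                       seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (max_followup < 0) stop("max_followup must be non-negative")
  if (visit_rate <= 0) stop("visit_rate must be positive")
  if (!followup$type %in% c("exponential", "fixed"))
    stop("followup$type must be 'exponential' or 'fixed'")
  validate_params(true_params)
  structure(list(n_subjects = as.integer(n_subjects),
                 max_followup = max_followup,
                 visit_rate = visit_rate,
                 followup = followup,
                 true_params = true_params,
                 covariate_specs = covariate_specs,
                 cart_rule = cart_rule,
                 panel_loadings = panel_loadings,
                 seed = as.integer(seed)),
            class = "sim_config")
}
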