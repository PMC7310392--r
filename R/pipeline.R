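# End-to-end orchestration: simulate (or load) a cohort, stage and describe
# it, reduce the clinical panel, fit the proportional- and
# non-proportional-odds growth models, test proportionality, compare DIC,
# and write a report directory with a manifest.

# small deterministic multiplicative hash for config fingerprinting
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build a pipeline configuration
#'
#' Exactly one of `input_path` (a cohort CSV) or `sim` (a [sim_config()])
#' must be given.
#'
#' @param input_path optional path to an existing long-format cohort CSV.
#' @param sim optional [sim_config()] for a simulated cohort.
#' @param shared,npo,time_interactions covariate sets for the growth model;
#'   the non-proportional fit frees `npo`, the proportional fit treats those
#'   covariates as shared.
#' @param random random-effects structure, see [model_spec()].
#' @param fa_vars columns of the visit table entering the factor-reduction
#'   stage.
#' @param baseline_categorical,baseline_continuous variables for the
#'   baseline table (computed on each subject's first visit).
#' @param quad_order quadrature order for both fits.
#' @param mcmc_iters,mcmc_burnin chain settings for the DIC stage.
#' @param seed master seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_path = NULL, sim = sim_config(),
                            shared = c("time", "log_vl", "qol_phys"),
                            npo = c("on_cart"),
                            time_interactions = character(),
                            random = "slope",
                            fa_vars = rownames(default_panel_loadings()),
                            baseline_categorical = c("age_group", "education",
                                                     "marital"),
                            baseline_continuous = c("log_vl", "weight"),
                            quad_order = 5,
                            mcmc_iters = 1500, mcmc_burnin = 500,
                            seed = 1L) {
  if (is.null(input_path) == is.null(sim))
    stop("exactly one of input_path / sim must be given")
  structure(list(input_path = input_path, sim = sim,
                 shared = shared, npo = npo,
                 time_interactions = time_interactions, random = random,
                 fa_vars = fa_vars,
                 baseline_categorical = baseline_categorical,
                 baseline_continuous = baseline_continuous,
                 quad_order = quad_order,
                 mcmc_iters = mcmc_iters, mcmc_burnin = mcmc_burnin,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a long-format visit table
#'
#' Structural checks ahead of modelling: required columns, stage codes in
#' 1..K, non-negative finite times, binary non-reverting cART indicator, and
#' stage/CD4 consistency where CD4 is present. Always returns a report; an
#' empty issue table means the input passed.
#'
#' @param table long-format visit table.
#' @param K number of outcome categories.
#' @return Data frame with columns `row`, `field`, `issue` (zero rows if
#'   clean).
#' @export
validate_input <- function(table, K = 4) {
  issues <- list()
  note <- function(row, field, issue)
    issues[[length(issues) + 1]] <<- data.frame(row = row, field = field,
                                                issue = issue)
  for (col in c("subject_id", "time", "stage"))
    if (is.null(table[[col]])) note(NA, col, "required column missing")
  if (length(issues) == 0) {
    bad <- which(!(table$stage %in% seq_len(K)))
    for (r in bad) note(r, "stage",
                        sprintf("stage %s outside 1..%d", table$stage[r], K))
    bad <- which(!is.finite(table$time) | table$time < 0)
    for (r in bad) note(r, "time", "negative or non-finite time")
    if (!is.null(table$on_cart)) {
      bad <- which(!(table$on_cart %in% c(0, 1)))
      for (r in bad) note(r, "on_cart", "not 0/1")
      for (id in unique(table$subject_id)) {
        idx <- which(table$subject_id == id)
        idx <- idx[order(table$time[idx])]
        oc <- table$on_cart[idx]
        drop <- which(diff(oc) < 0)
        for (d in drop) note(idx[d + 1], "on_cart",
                             "cART indicator reverts within subject")
      }
    }
    if (!is.null(table$cd4)) {
      ok <- !is.na(table$cd4) & table$stage %in% 1:4
      if (any(ok)) {
        mism <- which(ok)[who_stage(table$cd4[ok]) != table$stage[ok]]
        for (r in mism) note(r, "cd4", "cd4 inconsistent with stage")
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(row = integer(0), field = character(0),
                  issue = character(0))
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or load + validation), baseline
#' descriptives on first visits, factor reduction of the clinical panel,
#' proportional-odds fit, non-proportional-odds fit (started from the
#' proportional estimates), likelihood-ratio proportionality test, MCMC fits
#' and DIC comparison, odds-ratio report, and a JSON manifest with the
#' configuration hash and seeds. Any stage failure halts with the stage name;
#' artifacts of completed stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return The output directory path, invisibly; the manifest lists the
#'   artifacts.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  emit <- function(name) artifacts <<- c(artifacts, name)

  # 1. cohort
  cohort <- stage("cohort", {
    if (!is.null(config$input_path)) {
      x <- read_cohort(config$input_path)
      iss <- validate_input(x)
      if (nrow(iss)) stop("input failed validation: ",
                          paste(utils::head(iss$issue, 3), collapse = "; "))
      x
    } else {
      x <- simulate_cohort(config$sim, seed = seed)
      write_cohort(x, file.path(outdir, "cohort.csv"))
      emit("cohort.csv")
      x
    }
  })

  # 2. baseline descriptives on first visits
  stage("baseline", {
    first <- cohort[!duplicated(cohort$subject_id), ]
    bt <- baseline_table(first,
                         categorical = intersect(config$baseline_categorical,
                                                 names(first)),
                         continuous = intersect(config$baseline_continuous,
                                                names(first)))
    write.csv(bt$categorical, file.path(outdir, "baseline_table.csv"),
              row.names = FALSE)
    txt <- file.path(outdir, "baseline_table.txt")
    sink(txt); print(bt); sink()
    emit("baseline_table.csv")
  })

  # 3-4. factor reduction
  stage("factors", {
    fa_vars <- intersect(config$fa_vars, names(cohort))
    if (length(fa_vars) < 2) stop("fewer than 2 factor-analysis variables")
    red <- reduce_panel(cohort[, fa_vars])
    ld <- data.frame(variable = rep(rownames(red$solution$loadings),
                                    ncol(red$solution$loadings)),
                     factor = rep(colnames(red$solution$loadings),
                                  each = nrow(red$solution$loadings)),
                     loading = as.numeric(red$solution$loadings),
                     strength = as.character(red$strength),
                     cumulative_variance = red$solution$variance_explained)
    write.csv(ld, file.path(outdir, "fa_loadings.csv"), row.names = FALSE)
    emit("fa_loadings.csv")
    write.csv(data.frame(subject_id = cohort$subject_id,
                         time = cohort$time, red$scores),
              file.path(outdir, "fa_scores.csv"), row.names = FALSE)
    emit("fa_scores.csv")
  })

  # 5-6. growth model fits
  spec_po <- model_spec(shared = c(config$shared, config$npo),
                        npo = character(),
                        time_interactions = config$time_interactions,
                        random = config$random)
  spec_npo <- model_spec(shared = config$shared, npo = config$npo,
                         time_interactions = config$time_interactions,
                         random = config$random)
  fit_po <- stage("fit_po", ogm(cohort, spec_po,
                                quad_order = config$quad_order))
  stage("fit_po", write_fit(fit_po, file.path(outdir, "fit_po"), seed))
  emit("fit_po.csv")
  fit_npo <- if (length(config$npo)) {
    stage("fit_npo", ogm(cohort, spec_npo, quad_order = config$quad_order,
                         init = fit_po))
  } else NULL
  stage("fit_npo", {
    if (is.null(fit_npo)) {
      write_json(list(skipped = TRUE,
                      reason = "no category-specific covariates configured"),
                 file.path(outdir, "fit_npo_meta.json"))
      write.csv(data.frame(), file.path(outdir, "fit_npo.csv"),
                row.names = FALSE)
    } else write_fit(fit_npo, file.path(outdir, "fit_npo"), seed)
    emit("fit_npo.csv")
  })

  # 7. proportionality test
  stage("lr_test", {
    if (is.null(fit_npo)) {
      write_json(list(skipped = TRUE,
                      reason = "LR test needs a non-empty npo set"),
                 file.path(outdir, "lr_test.json"))
    } else {
      lr <- lr_proportionality_test(fit_po, fit_npo)
      write_json(list(skipped = FALSE, statistic = lr$statistic, df = lr$df,
                      p_value = lr$p_value, reject = lr$reject),
                 file.path(outdir, "lr_test.json"))
    }
    emit("lr_test.json")
  })

  # 8. DIC comparison
  dic <- stage("dic", {
    mc_po <- ogm_mcmc(cohort, spec_po, iters = config$mcmc_iters,
                      burnin = config$mcmc_burnin,
                      quad_order = config$quad_order,
                      seed = seed + 1L, init = fit_po)
    mc_npo <- if (!is.null(fit_npo))
      ogm_mcmc(cohort, spec_npo, iters = config$mcmc_iters,
               burnin = config$mcmc_burnin,
               quad_order = config$quad_order,
               seed = seed + 2L, init = fit_npo)
    else mc_po
    cmp <- compare_dic(mc_po, mc_npo)
    write.csv(round_df(cmp$table, 6), file.path(outdir, "dic_report.csv"),
              row.names = FALSE)
    emit("dic_report.csv")
    cmp
  })

  # 9. odds-ratio report
  stage("report", {
    rep_fit <- if (is.null(fit_npo)) fit_po else fit_npo
    tab <- odds_ratio_table(rep_fit)
    write.csv(round_df(as.data.frame(tab), 6),
              file.path(outdir, "report.csv"), row.names = FALSE)
    txt <- file.path(outdir, "report.txt")
    sink(txt); print(tab); sink()
    emit("report.csv")
  })

  manifest <- list(
    package = "ordgrowth",
    version = as.character(utils::packageVersion("ordgrowth")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(unclass(config)),
    seed = seed,
    artifacts = artifacts,
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write_json(manifest, file.path(outdir, "manifest.json"))
  invisible(outdir)
}

write_fit <- function(fit, stem, seed) {
  tab <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    se = unname(fit$se),
                    ci_low = fit$ci[, 1], ci_high = fit$ci[, 2])
  write.csv(round_df(tab, 10), paste0(stem, ".csv"), row.names = FALSE)
  write_json(list(minus2loglik = fit$minus2loglik, icc = fit$icc,
                  converged = fit$converged, iterations = fit$iterations,
                  gradient_norm = fit$gradient_norm,
                  quad_order = fit$quad_order, seed = seed),
             paste0(stem, "_meta.json"))
}
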