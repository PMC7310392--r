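# Synthetic longitudinal cohort generator. All randomness flows from one
# seed; visit- and outcome-level draws use per-subject substreams so a
# subject's trajectory is reproducible regardless of cohort ordering.

draw_covariate <- function(spec, n) {
  switch(spec$type,
         categorical = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
         binary = rbinom(n, 1, spec$prob),
         normal = {
           x <- rnorm(n, spec$mean, spec$sd)
           if (!is.null(spec$min)) x <- pmin(pmax(x, spec$min), spec$max)
           x
         },
         stop("unknown covariate type: ", spec$type))
}

substream_seeds <- function(seed, n, offset = 0L) {
  set.seed(seed + offset)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate subject-level data
#'
#' Draws subject-level covariates from the configured frequency
#' distributions and the random intercept and slope `(u0, u1)` from a
#' mean-zero bivariate normal with covariance `D` taken from
#' `config$true_params`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return Data frame with one row per subject: `subject_id`, the configured
#'   subject-level covariates, and `u0`, `u1`.
#' @export
simulate_subjects <- function(config, seed = config$seed) {
  validate_params(config$true_params)
  n <- config$n_subjects
  set.seed(seed)
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)))
  for (nm in names(config$covariate_specs$subject))
    out[[nm]] <- draw_covariate(config$covariate_specs$subject[[nm]], n)
  D <- config$true_params$D
  if (all(D == 0)) {
    u <- matrix(0, n, 2)
  } else {
    L <- chol_psd2(D)
    z <- matrix(rnorm(2 * n), n, 2)
    u <- z %*% t(L)
  }
  out$u0 <- u[, 1]
  out$u1 <- u[, 2]
  out
}

#' Simulate visit schedules and time-varying covariates
#'
#' Every subject gets a baseline visit at time 0 plus a homogeneous Poisson
#' stream of visits at `config$visit_rate` per year over the subject's
#' follow-up horizon (drawn per `config$followup`, truncated at
#' `config$max_followup`). Disease phase is assigned from time: II in the
#' first 3 months, III from 3 to 12 months, IV afterwards; phase V (on cART)
#' is set later by [simulate_ordinal_outcomes()] once treatment starts.
#' Time-varying covariates are drawn per visit from the configured
#' distributions; when `config$panel_loadings` is present, raw clinical panel
#' columns are generated from the latent factor-score columns plus
#' independent noise.
#'
#' @param subjects output of [simulate_subjects()].
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return Long-format data frame, one row per visit, without outcomes
#'   (`stage`, `cd4` set to `NA`, `on_cart` 0).
#' @export
simulate_visits <- function(subjects, config, seed = config$seed) {
  if (nrow(subjects) == 0) stop("subjects must be non-empty")
  n <- nrow(subjects)
  seeds <- substream_seeds(seed, n, offset = 1L)
  rows <- vector("list", n)
  vspecs <- config$covariate_specs$visit
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    horizon <- switch(config$followup$type,
                      fixed = config$max_followup,
                      exponential = min(rexp(1, log(2) / config$followup$median),
                                        config$max_followup))
    nv <- if (horizon > 0) rpois(1, config$visit_rate * horizon) else 0
    times <- c(0, sort(runif(nv, 0, horizon)))
    m <- length(times)
    df <- data.frame(subject_id = subjects$subject_id[i], time = times)
    for (nm in names(vspecs))
      df[[nm]] <- draw_covariate(vspecs[[nm]], m)
    rows[[i]] <- df
  }
  long <- do.call(rbind, rows)
  long$phase <- ifelse(long$time < 0.25, "II",
                       ifelse(long$time < 1, "III", "IV"))
  long$stage <- NA_integer_
  long$cd4 <- NA_real_
  long$on_cart <- 0L
  if (!is.null(config$panel_loadings)) {
    L <- config$panel_loadings
    fac <- as.matrix(long[, colnames(L), drop = FALSE])
    noise_sd <- sqrt(pmax(1 - rowSums(L^2), 0.1))
    set.seed(seed + 2L)
    E <- matrix(rnorm(nrow(long) * nrow(L)), nrow(long), nrow(L))
    panel <- fac %*% t(L) + sweep(E, 2, noise_sd, `*`)
    colnames(panel) <- rownames(L)
    long <- cbind(long, panel)
  }
  keep <- c("subject_id", "time", "phase", "stage", "cd4", "on_cart",
            setdiff(names(long), c("subject_id", "time", "phase", "stage",
                                   "cd4", "on_cart")))
  long <- long[, keep]
  merge(long, subjects, by = "subject_id", sort = FALSE)
}

# resolve a covariate name against a row environment; "a:b" is a product
sim_col <- function(row, name) {
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    return(Reduce(`*`, lapply(parts, function(p) sim_col(row, p))))
  }
  v <- row[[name]]
  if (is.null(v)) stop("covariate '", name, "' not found in table")
  as.numeric(v)
}

#' Simulate ordinal outcomes along each trajectory
#'
#' Walks each subject's visits in time order. At each visit the cumulative
#' logits are
#' `thresholds[k] + x*' beta_c[k] + x' beta + u0 + u1 * time` (covariates
#' centered per `params$centers`), the stage is drawn from the implied
#' category probabilities, and a CD4 count is drawn uniformly within the
#' stage's WHO band so that staging round-trips. Once a visit's stage reaches
#' `cart_rule` (CD4 below 500 at the default), cART is switched on from the
#' next visit onwards and the phase becomes "V"; `on_cart` never reverts.
#'
#' Parameter vectors whose cumulative logits are non-monotone at an observed
#' covariate pattern abort the simulation with an error naming the offending
#' row.
#'
#' @param long_table visit table from [simulate_visits()] (must contain the
#'   covariates named in `params` plus `u0`, `u1`).
#' @param params generating [param_vector()].
#' @param seed integer seed.
#' @param cart_rule stage code triggering cART (default 2).
#' @return The visit table with `stage`, `cd4`, `on_cart`, `phase` filled in.
#' @export
simulate_ordinal_outcomes <- function(long_table, params, seed = 1L,
                                      cart_rule = 2) {
  validate_params(params)
  K <- length(params$thresholds) + 1
  ids <- unique(long_table$subject_id)
  seeds <- substream_seeds(seed, length(ids), offset = 3L)
  long_table <- long_table[order(match(long_table$subject_id, ids),
                                 long_table$time), ]
  out <- long_table
  n <- nrow(out)
  shared_names <- names(params$shared)
  npo_names <- colnames(params$npo)
  centers <- params$centers
  center_of <- function(nm) if (!is.null(centers) && nm %in% names(centers))
    centers[[nm]] else 0
  uses_cart <- function(nm) "on_cart" %in% strsplit(nm, ":", fixed = TRUE)[[1]]
  col_of <- function(nm) {
    # centered covariate column; "time" stays raw; products center factors
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      return(Reduce(`*`, lapply(parts, col_of)))
    }
    if (nm == "time") return(out$time)
    v <- out[[nm]]
    if (is.null(v)) stop("covariate '", nm, "' not found in table")
    as.numeric(v) - center_of(nm)
  }
  # static part of the K-1 cumulative logits (everything except cART terms,
  # which depend on the trajectory as it unfolds)
  Eta <- matrix(rep(params$thresholds, each = n), n, K - 1)
  for (nm in shared_names[!vapply(shared_names, uses_cart, logical(1))])
    Eta <- Eta + params$shared[[nm]] * col_of(nm)
  for (nm in npo_names[!vapply(npo_names, uses_cart, logical(1))])
    Eta <- Eta + outer(col_of(nm), params$npo[, nm])
  Eta <- Eta + out$u0 + out$u1 * out$time
  cart_shared <- shared_names[vapply(shared_names, uses_cart, logical(1))]
  cart_npo <- npo_names[vapply(npo_names, uses_cart, logical(1))]
  tim <- out$time
  stage_v <- integer(n)
  cart_v <- integer(n)
  sub_idx <- split(seq_len(n), match(out$subject_id, ids))
  for (s in seq_along(ids)) {
    set.seed(seeds[s])
    on_cart <- 0L
    for (r in sub_idx[[s]]) {
      cart_v[r] <- on_cart
      eta <- Eta[r, ]
      if (on_cart == 1L) {
        for (nm in cart_shared) {
          x <- prod(vapply(strsplit(nm, ":", fixed = TRUE)[[1]],
                           function(p) if (p == "on_cart") 1 else
                             if (p == "time") tim[r] else
                               as.numeric(out[[p]][r]) - center_of(p),
                           numeric(1)))
          eta <- eta + params$shared[[nm]] * x
        }
        for (nm in cart_npo) {
          x <- prod(vapply(strsplit(nm, ":", fixed = TRUE)[[1]],
                           function(p) if (p == "on_cart") 1 else
                             if (p == "time") tim[r] else
                               as.numeric(out[[p]][r]) - center_of(p),
                           numeric(1)))
          eta <- eta + params$npo[, nm] * x
        }
      }
      cum <- plogis(eta)
      pk <- diff(c(0, cum, 1))
      if (any(pk < 0))
        stop(sprintf(paste0("non-monotone cumulative probabilities at subject ",
                            "%s, time %.3f (covariate pattern row %d)"),
                     ids[s], tim[r], r))
      stg <- min(findInterval(runif(1), cumsum(pk)) + 1L, K)
      stage_v[r] <- stg
      if (stg >= cart_rule) on_cart <- 1L
    }
  }
  out$stage <- stage_v
  out$on_cart <- cart_v
  out$phase[out$on_cart == 1L] <- "V"
  out$cd4 <- if (K == 4) {
    set.seed(seed + 7L)
    cd4_from_stage(stage_v)
  } else NA_real_
  rownames(out) <- NULL
  out
}

#' Simulate a clinical panel from a planted loading matrix
#'
#' Generates `X = F loadings' + E` with standard-normal latent factors `F`
#' and independent normal noise `E`; used to validate the factor-reduction
#' stage against known structure.
#'
#' @param loadings variables x factors matrix (more variables than factors).
#' @param n number of observations.
#' @param noise_sd scalar or per-variable noise standard deviation.
#' @param seed integer seed.
#' @return List with `X` (n x variables), `factors` (n x factors).
#' @export
simulate_clinical_panel <- function(loadings, n, noise_sd = 0.5, seed = 1L) {
  loadings <- as.matrix(loadings)
  if (nrow(loadings) <= ncol(loadings))
    stop("loadings must have more rows (variables) than columns (factors)")
  set.seed(seed)
  Fm <- matrix(rnorm(n * ncol(loadings)), n, ncol(loadings))
  E <- matrix(rnorm(n * nrow(loadings)), n, nrow(loadings))
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, nrow(loadings))
  X <- Fm %*% t(loadings) + sweep(E, 2, noise_sd, `*`)
  if (!is.null(rownames(loadings))) colnames(X) <- rownames(loadings)
  else colnames(X) <- paste0("V", seq_len(nrow(loadings)))
  list(X = X, factors = Fm)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: subjects, visit schedules and covariates, then
#' ordinal outcomes, under one configuration and seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return Long-format visit table; the configuration and seed are attached
#'   as attributes `sim_config` and `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  subjects <- simulate_subjects(config, seed)
  long <- simulate_visits(subjects, config, seed)
  long <- simulate_ordinal_outcomes(long, config$true_params, seed,
                                    cart_rule = config$cart_rule)
  attr(long, "sim_config") <- config
  attr(long, "seed") <- seed
  long
}

#' Write / read a cohort table as CSV
#'
#' Plain headered CSV, one row per visit; the seed is recorded in a
#' `# seed:` comment-free sidecar convention is avoided — the seed travels in
#' the pipeline manifest instead.
#'
#' @param long visit table.
#' @param path file path.
#' @return `read_cohort` returns the visit table.
#' @export
write_cohort <- function(long, path) {
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
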