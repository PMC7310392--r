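# Comparison of the proportional- and non-proportional-odds fits:
# likelihood-ratio test of proportionality, DIC comparison, and the
# odds-ratio report table.

#' Likelihood-ratio test of the proportional-odds assumption
#'
#' Compares a proportional-odds fit (restricted) against the
#' non-proportional-odds fit (general) on the same data and covariates. The
#' statistic is the difference of the `-2 log L` values; the degrees of
#' freedom are the number of freed coefficients, `(K - 2)` per
#' category-specific covariate column.
#'
#' @param fit_po restricted `"ogm"` fit (no category-specific effects among
#'   the covariates freed in `fit_npo`).
#' @param fit_npo general `"ogm"` fit.
#' @param alpha significance level for the reported decision.
#' @return Object of class `"ogm_lrtest"` with `statistic`, `df`, `p_value`
#'   and `reject`.
#' @export
lr_proportionality_test <- function(fit_po, fit_npo, alpha = 0.05) {
  if (fit_po$K != fit_npo$K)
    stop("fits have different numbers of outcome categories")
  if (fit_po$n != fit_npo$n)
    stop("fits are not on the same data (row counts differ)")
  freed <- fit_npo$npo_cols
  po_cov <- c(fit_po$shared_cols, fit_po$npo_cols)
  npo_cov <- c(fit_npo$shared_cols, freed)
  if (!setequal(po_cov, npo_cov) || length(fit_po$npo_cols))
    stop("models are not nested: the restricted fit must share all covariates ",
         "of the general fit, with none category-specific")
  m <- length(freed)
  if (m == 0) stop("general fit has no category-specific covariates")
  df <- (fit_po$K - 2) * m
  stat <- fit_po$minus2loglik - fit_npo$minus2loglik
  if (stat < -1e-4)
    stop("negative likelihood-ratio statistic (", format(stat),
         "); refit the general model starting from the restricted estimates")
  stat <- max(stat, 0)
  p <- pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 alpha = alpha, reject = p < alpha,
                 npo_covariates = freed),
            class = "ogm_lrtest")
}

#' @export
print.ogm_lrtest <- function(x, ...) {
  cat("Likelihood-ratio test of the proportional-odds assumption\n")
  cat(sprintf("  chi-squared = %.2f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  %s proportional odds at alpha = %g\n",
              if (x$reject) "REJECT" else "do not reject", x$alpha))
  invisible(x)
}

#' Compare two posterior fits by DIC
#'
#' Reports `dbar`, `pD` and DIC for both fits and prefers the lower DIC.
#' If either chain carries a convergence warning the comparison is reported
#' without declaring a preference.
#'
#' @param po,npo `"ogm_mcmc"` fits of the proportional- and
#'   non-proportional-odds models.
#' @return Object of class `"ogm_dic"`.
#' @export
compare_dic <- function(po, npo) {
  tab <- data.frame(
    model = c("proportional", "non-proportional"),
    dbar = c(po$dbar, npo$dbar),
    pD = c(po$pD, npo$pD),
    dic = c(po$dic, npo$dic))
  ok <- po$converged && npo$converged
  preferred <- if (ok) tab$model[which.min(tab$dic)] else NA_character_
  structure(list(table = tab,
                 delta_dic = po$dic - npo$dic,
                 preferred = preferred,
                 converged = ok,
                 warnings = c(po$warnings, npo$warnings)),
            class = "ogm_dic")
}

#' @export
print.ogm_dic <- function(x, ...) {
  cat("DIC comparison\n")
  print(round_df(x$table, 2))
  cat(sprintf("  delta DIC (PO - NPO) = %.2f\n", x$delta_dic))
  if (!x$converged)
    cat("  WARNING: non-converged chain(s); no preference declared\n",
        paste(" ", x$warnings, collapse = "\n"), "\n")
  else cat("  preferred:", x$preferred, "\n")
  invisible(x)
}

#' Odds-ratio report table
#'
#' Lays out a fitted model as exponentiated estimates with exponentiated 95%
#' intervals per covariate per cumulative logit (shared covariates repeat the
#' same odds ratio across logits; thresholds are reported as `exp(delta_k)`
#' in their own logit's column), with three-band significance stars, followed
#' by the random components, the latent-scale ICC, `-2 log L` and, for
#' posterior fits, the DIC block.
#'
#' @param fit an `"ogm"` (Wald intervals) or `"ogm_mcmc"` (credible
#'   intervals) fit.
#' @return Data frame of class `"ogm_or_table"` with columns `term`, `block`,
#'   `logit`, `or`, `ci_low`, `ci_high`, `stars` (diagnostics rows carry the
#'   plain value in `or`).
#' @export
odds_ratio_table <- function(fit) {
  mcmc <- inherits(fit, "ogm_mcmc")
  if (!mcmc && !isTRUE(fit$converged))
    warning("fit did not converge; table reflects the last iterate")
  est <- fit$estimates
  ci <- fit$ci
  K <- fit$K
  p_of <- function(nm) {
    if (mcmc) {
      dr <- fit$draws[, nm]
      2 * min(mean(dr > 0), mean(dr < 0))
    } else {
      2 * pnorm(-abs(est[[nm]] / fit$se[[nm]]))
    }
  }
  rows <- list()
  add <- function(term, block, logit, nm, exponentiate = TRUE) {
    e <- est[[nm]]; lo <- ci[nm, 1]; hi <- ci[nm, 2]
    if (exponentiate) { e <- exp(e); lo <- exp(lo); hi <- exp(hi) }
    rows[[length(rows) + 1]] <<- data.frame(
      term = term, block = block, logit = logit,
      or = e, ci_low = lo, ci_high = hi,
      stars = star_band(p_of(nm)))
  }
  for (k in seq_len(K - 1))
    add(paste0("threshold_", k), "threshold", k, paste0("delta_", k))
  is_slope <- function(nm) grepl(":", nm, fixed = TRUE) &&
    any(strsplit(nm, ":", fixed = TRUE)[[1]] == "time")
  for (nm in fit$shared_cols) {
    block <- if (nm == "time" || is_slope(nm)) "time_slope" else "main"
    for (k in seq_len(K - 1)) add(nm, block, k, nm)
  }
  for (nm in fit$npo_cols) {
    block <- if (nm == "time" || is_slope(nm)) "time_slope" else "main"
    for (k in seq_len(K - 1))
      add(nm, block, k, paste0("logit", k, ":", nm))
  }
  for (nm in intersect(c("var_u0", "cov_u0u1", "var_u1"), names(est)))
    add(nm, "random", NA, nm, exponentiate = FALSE)
  diag_rows <- data.frame(
    term = c("icc_latent", "minus2loglik",
             if (mcmc) c("dbar", "pD", "dic")),
    block = "diagnosis", logit = NA,
    or = c(fit$icc,
           if (mcmc) -2 * mean(fit$loglik_draws) else fit$minus2loglik,
           if (mcmc) c(fit$dbar, fit$pD, fit$dic)),
    ci_low = NA, ci_high = NA, stars = "")
  out <- rbind(do.call(rbind, rows), diag_rows)
  rownames(out) <- NULL
  class(out) <- c("ogm_or_table", "data.frame")
  out
}

#' @export
print.ogm_or_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  wide <- df[df$block %in% c("threshold", "main", "time_slope"), ]
  terms <- unique(wide$term)
  K1 <- max(wide$logit, na.rm = TRUE)
  cat("Exp(beta) (95% CI) per cumulative logit\n")
  hdr <- paste0("logit ", seq_len(K1))
  cat(sprintf("%-28s %s\n", "", paste(sprintf("%-24s", hdr), collapse = "")))
  for (tm in terms) {
    sub <- wide[wide$term == tm, ]
    cells <- vapply(seq_len(K1), function(k) {
      r <- sub[sub$logit == k, ]
      if (!nrow(r)) return(sprintf("%-24s", ""))
      sprintf("%-24s", sprintf("%.2f (%.2f, %.2f)%s", r$or, r$ci_low,
                               r$ci_high, r$stars))
    }, character(1))
    cat(sprintf("%-28s %s\n", tm, paste(cells, collapse = "")))
  }
  other <- df[df$block %in% c("random", "diagnosis"), ]
  cat("Random components / diagnostics\n")
  for (i in seq_len(nrow(other)))
    cat(sprintf("  %-20s %10.4f %s\n", other$term[i], other$or[i],
                other$stars[i]))
  invisible(x)
}
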