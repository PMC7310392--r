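# Maximum-likelihood fitting of the two-level cumulative-logit growth model.
# The optimizer works on an unconstrained parameterization (first threshold
# plus log-increments; random-effects covariance as log standard deviations
# and atanh correlation); standard errors come from the inverse numerical
# Hessian, mapped to the natural scale by the delta method.

default_start <- function(bundle, dims) {
  # thresholds from the logits of the marginal cumulative proportions,
  # coefficients zero, D = diag(1, 0.01)
  K <- dims$K
  cum <- cumsum(tabulate(bundle$y, K))[seq_len(K - 1)] / bundle$n
  cum <- pmin(pmax(cum, 1 / (2 * bundle$n)), 1 - 1 / (2 * bundle$n))
  delta <- qlogis(cum)
  if (any(diff(delta) <= 0)) delta <- sort(delta) + seq_len(K - 1) * 1e-6
  theta_pack(delta, rep(0, dims$ps), matrix(0, K - 1, dims$pn),
             diag(c(1, 0.01)), dims)
}

natural_params <- function(theta, dims, bundle) {
  up <- theta_unpack(theta, dims)
  est <- c(up$delta, up$beta_s, as.numeric(up$beta_n))
  nms <- c(paste0("delta_", seq_len(dims$K - 1)), colnames(bundle$Xs))
  if (dims$pn)
    nms <- c(nms, as.vector(outer(paste0("logit", seq_len(dims$K - 1), ":"),
                                  colnames(bundle$Xn), paste0)))
  if (dims$re == "intercept") {
    est <- c(est, up$D[1, 1])
    nms <- c(nms, "var_u0")
  } else if (dims$re == "slope") {
    est <- c(est, up$D[1, 1], up$D[1, 2], up$D[2, 2])
    nms <- c(nms, "var_u0", "cov_u0u1", "var_u1")
  }
  setNames(est, nms)
}

numeric_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Fit a multilevel cumulative-logit growth model by maximum likelihood
#'
#' Fits the proportional-odds or non-proportional-odds two-level
#' cumulative-logit model with random intercept (and optionally time slope),
#' maximizing the marginal likelihood computed by adaptive Gauss-Hermite
#' quadrature. Standard errors are taken from the inverse numerical Hessian;
#' 95% Wald intervals are formed on the estimation scale and reported on the
#' natural scale (odds ratios in [odds_ratio_table()]). The latent-scale
#' intraclass correlation [icc_latent()] is computed from the fitted
#' intercept variance.
#'
#' @param data long-format visit table, or an `"ogm_design"` bundle.
#' @param spec an [model_spec()] (ignored when `data` is already a bundle).
#' @param quad_order quadrature order per random-effect dimension.
#' @param init optional starting value: an `"ogm"` fit (e.g. the
#'   proportional-odds fit when adding category-specific effects), a named
#'   list with `delta`, `beta_s`, `beta_n`, `D`, or a raw theta vector. The
#'   default start uses thresholds at the marginal cumulative-frequency
#'   logits, zero coefficients and `D = diag(1, 0.01)`.
#' @param se if `FALSE`, skip the Hessian (faster; no intervals).
#' @param reference_levels passed to [build_design()].
#' @param control passed to [stats::nlminb()].
#' @return Object of class `"ogm"`.
#' @export
ogm <- function(data, spec = NULL, quad_order = 9, init = NULL, se = TRUE,
                reference_levels = NULL, control = list()) {
  bundle <- if (inherits(data, "ogm_design")) data
            else build_design(data, spec, reference_levels)
  spec <- bundle$spec
  dims <- theta_dims(bundle)
  K <- dims$K
  obs <- tabulate(bundle$y, K)
  if (any(obs == 0))
    stop("outcome category ", paste(which(obs == 0), collapse = ", "),
         " never observed; merge categories before fitting")
  gh <- gauss_hermite(quad_order)

  theta0 <- if (is.null(init)) {
    default_start(bundle, dims)
  } else if (inherits(init, "ogm")) {
    init_from_fit(init, bundle, dims)
  } else if (is.list(init)) {
    theta_pack(init$delta, init$beta_s,
               if (is.null(init$beta_n)) matrix(0, K - 1, dims$pn)
               else init$beta_n,
               if (is.null(init$D)) diag(c(1, 0.01)) else init$D, dims)
  } else as.numeric(init)
  if (length(theta0) != dims$n_theta)
    stop("init has wrong length (", length(theta0), " vs ", dims$n_theta, ")")

  negll <- function(theta) {
    up <- theta_unpack(theta, dims)
    v <- marginal_ll_raw(up, bundle, gh)$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  ctrl <- modifyList(list(iter.max = 500, eval.max = 4000,
                          rel.tol = 1e-10), control)
  opt <- nlminb(theta0, negll, control = ctrl)
  theta_hat <- opt$par

  grad <- numeric_jacobian(function(t) negll(t), theta_hat)[1, ]
  est <- natural_params(theta_hat, dims, bundle)

  se_nat <- rep(NA_real_, length(est))
  vcov_nat <- matrix(NA_real_, length(est), length(est),
                     dimnames = list(names(est), names(est)))
  vcov_theta <- NULL
  if (se) {
    H <- optimHess(theta_hat, negll)
    vcov_theta <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov_theta)) {
      J <- numeric_jacobian(function(t) natural_params(t, dims, bundle),
                            theta_hat)
      vcov_nat <- J %*% vcov_theta %*% t(J)
      dimnames(vcov_nat) <- list(names(est), names(est))
      se_nat <- sqrt(pmax(diag(vcov_nat), 0))
    }
  }
  ci <- cbind(lower = est - 1.96 * se_nat, upper = est + 1.96 * se_nat)

  up <- theta_unpack(theta_hat, dims)
  params <- param_vector(
    thresholds = up$delta,
    shared = setNames(up$beta_s, colnames(bundle$Xs)),
    npo = if (dims$pn) {
      m <- up$beta_n; colnames(m) <- colnames(bundle$Xn); m
    } else NULL,
    D = up$D)

  structure(list(
    call = match.call(),
    spec = spec,
    params = params,
    theta = theta_hat,
    theta_names = theta_names(bundle, dims),
    dims = dims,
    estimates = est,
    se = setNames(se_nat, names(est)),
    ci = ci,
    vcov = vcov_nat,
    vcov_theta = vcov_theta,
    loglik = -opt$objective,
    minus2loglik = 2 * opt$objective,
    icc = icc_latent(up$D[1, 1]),
    converged = opt$convergence == 0,
    iterations = opt$iterations,
    gradient_norm = max(abs(grad)),
    quad_order = quad_order,
    n = bundle$n, n_subjects = bundle$n_subjects, K = K,
    n_params = dims$n_theta,
    shared_cols = colnames(bundle$Xs),
    npo_cols = colnames(bundle$Xn)),
    class = "ogm")
}

# start a (possibly larger) model from a fitted one: shared coefficients map
# by column name; a covariate moving from shared to category-specific starts
# at equal per-logit coefficients
init_from_fit <- function(fit, bundle, dims) {
  K <- dims$K
  beta_s <- setNames(rep(0, dims$ps), colnames(bundle$Xs))
  common <- intersect(names(fit$params$shared), names(beta_s))
  beta_s[common] <- fit$params$shared[common]
  beta_n <- matrix(0, K - 1, dims$pn,
                   dimnames = list(NULL, colnames(bundle$Xn)))
  for (nm in colnames(bundle$Xn)) {
    if (nm %in% names(fit$params$shared))
      beta_n[, nm] <- fit$params$shared[[nm]]
    else if (!is.null(fit$params$npo) && nm %in% colnames(fit$params$npo))
      beta_n[, nm] <- fit$params$npo[, nm]
  }
  theta_pack(fit$params$thresholds, unname(beta_s), unname(beta_n),
             fit$params$D, dims)
}

#' @export
print.ogm <- function(x, ...) {
  type <- if (length(x$npo_cols)) "non-proportional odds" else "proportional odds"
  cat(sprintf("Multilevel cumulative-logit growth model (%s)\n", type))
  cat(sprintf("  %d visits, %d subjects, K = %d; random effects: %s\n",
              x$n, x$n_subjects, x$K, x$spec$random))
  cat(sprintf("  -2 log L = %.2f; ICC (latent) = %.3f; converged: %s\n",
              x$minus2loglik, x$icc, x$converged))
  cat("Thresholds:", format(x$params$thresholds, digits = 4), "\n")
  if (length(x$params$shared)) {
    cat("Shared coefficients:\n")
    print(round(x$params$shared, 4))
  }
  if (!is.null(x$params$npo)) {
    cat("Category-specific coefficients (rows = cumulative logits):\n")
    print(round(x$params$npo, 4))
  }
  cat("Random-effects covariance D:\n")
  print(round(x$params$D, 4))
  invisible(x)
}

#' @export
summary.ogm <- function(object, ...) {
  z <- object$estimates / object$se
  p <- 2 * pnorm(-abs(z))
  tab <- data.frame(estimate = object$estimates, se = object$se,
                    ci_low = object$ci[, 1], ci_high = object$ci[, 2],
                    z = z, p_value = p,
                    stars = star_band(p))
  out <- list(table = tab, minus2loglik = object$minus2loglik,
              icc = object$icc, converged = object$converged,
              n = object$n, n_subjects = object$n_subjects)
  class(out) <- "summary.ogm"
  out
}

#' @export
print.summary.ogm <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d visits in %d subjects; -2 log L = %.2f; ICC = %.3f\n",
              x$n, x$n_subjects, x$minus2loglik, x$icc))
  print(round_df(x$table, digits))
  invisible(x)
}

round_df <- function(df, digits) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]))
    df[[j]] <- round(df[[j]], digits)
  df
}

star_band <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", "ns"))))
}

#' @export
coef.ogm <- function(object, ...) object$estimates

#' @export
vcov.ogm <- function(object, ...) object$vcov

#' @export
logLik.ogm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Predicted category probabilities
#'
#' Evaluates the fitted category probabilities for each row of `newdata` at
#' a fixed random effect (population-typical `u = (0, 0)` by default).
#'
#' @param object fitted `"ogm"`.
#' @param newdata visit table with the model covariates; defaults cannot be
#'   reconstructed, so it must be supplied.
#' @param u length-2 random effect at which to evaluate.
#' @param ... unused.
#' @return Matrix, rows matching `newdata`, K columns of probabilities.
#' @export
predict.ogm <- function(object, newdata, u = c(0, 0), ...) {
  bundle <- build_design(newdata, object$spec)
  up <- list(delta = object$params$thresholds,
             beta_s = unname(object$params$shared[colnames(bundle$Xs)]),
             beta_n = if (length(object$npo_cols))
               unname(object$params$npo[, colnames(bundle$Xn), drop = FALSE])
             else matrix(0, object$K - 1, 0))
  eta <- matrix(rep(up$delta, each = bundle$n), bundle$n, object$K - 1)
  if (ncol(bundle$Xs)) eta <- eta + as.numeric(bundle$Xs %*% up$beta_s)
  if (ncol(bundle$Xn)) eta <- eta + bundle$Xn %*% t(up$beta_n)
  eta <- eta + u[1] + u[2] * bundle$time
  cum <- plogis(eta)
  P <- cbind(cum, 1) - cbind(0, cum)
  colnames(P) <- paste0("p", seq_len(object$K))
  P
}

#' Simulate outcomes from a fitted model
#'
#' Draws new random effects per subject from the fitted covariance and new
#' stages per visit from the fitted category probabilities, over the rows of
#' `newdata`.
#'
#' @param object fitted `"ogm"`.
#' @param nsim number of simulated outcome vectors.
#' @param seed integer seed.
#' @param newdata visit table (defaults are not stored; must be supplied).
#' @param ... unused.
#' @return Data frame of `nsim` simulated stage columns.
#' @export
simulate.ogm <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  set.seed(seed)
  bundle <- build_design(newdata, object$spec)
  up <- list(delta = object$params$thresholds,
             beta_s = unname(object$params$shared[colnames(bundle$Xs)]),
             beta_n = if (length(object$npo_cols))
               unname(object$params$npo[, colnames(bundle$Xn), drop = FALSE])
             else matrix(0, object$K - 1, 0))
  eta0 <- matrix(rep(up$delta, each = bundle$n), bundle$n, object$K - 1)
  if (ncol(bundle$Xs)) eta0 <- eta0 + as.numeric(bundle$Xs %*% up$beta_s)
  if (ncol(bundle$Xn)) eta0 <- eta0 + bundle$Xn %*% t(up$beta_n)
  L <- chol_psd2(object$params$D)
  out <- matrix(NA_integer_, bundle$n, nsim)
  for (s in seq_len(nsim)) {
    u <- matrix(rnorm(2 * bundle$n_subjects), ncol = 2) %*% t(L)
    idx <- rep(seq_len(bundle$n_subjects),
               bundle$last - bundle$first + 1L)
    eta <- eta0 + u[idx, 1] + u[idx, 2] * bundle$time
    cum <- plogis(eta)
    P <- cbind(cum, 1) - cbind(0, cum)
    r <- runif(bundle$n)
    cs <- t(apply(P, 1, cumsum))
    out[, s] <- 1L + rowSums(r > cs[, -object$K, drop = FALSE])
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}
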