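# Bayesian estimation by adaptive random-walk Metropolis on the same
# unconstrained parameterization as the MLE, targeting the marginal
# likelihood (random effects integrated out by quadrature) plus the prior.
# Primarily used to compute the deviance information criterion.

log_prior <- function(theta, dims, prior) {
  n_fixed <- (dims$K - 1) + dims$ps + dims$pn * (dims$K - 1)
  lp <- sum(stats::dnorm(theta[seq_len(n_fixed)], 0, prior$coef_sd, log = TRUE))
  i <- n_fixed
  if (dims$re == "intercept") {
    s0 <- exp(theta[i + 1])
    lp <- lp - s0^2 / (2 * prior$sd_scale^2) + theta[i + 1]  # half-normal + Jacobian
  } else if (dims$re == "slope") {
    s0 <- exp(theta[i + 1]); s1 <- exp(theta[i + 2])
    rho <- tanh(theta[i + 3])
    lp <- lp - s0^2 / (2 * prior$sd_scale^2) + theta[i + 1]
    lp <- lp - s1^2 / (2 * prior$sd_scale^2) + theta[i + 2]
    lp <- lp + log1p(-rho^2)  # uniform on rho, Jacobian of tanh
  }
  lp
}

#' Fit the model by adaptive random-walk Metropolis
#'
#' Samples the unconstrained parameters of the two-level cumulative-logit
#' model from their posterior, with the random effects integrated out of the
#' likelihood by adaptive Gauss-Hermite quadrature at every evaluation.
#' Default priors: diffuse normal (sd 10) on thresholds-increments and
#' coefficients, half-normal (scale 5) on the random-effect standard
#' deviations, uniform on the intercept-slope correlation. The proposal
#' covariance and global scale adapt during burn-in (target acceptance about
#' 0.3) and are frozen afterwards.
#'
#' Reports the deviance summaries used for model comparison: `dbar` (mean
#' posterior deviance), `pD = dbar - D(posterior mean)`, `dic = dbar + pD`.
#'
#' @param data long-format visit table or an `"ogm_design"` bundle.
#' @param spec an [model_spec()].
#' @param iters total iterations (including burn-in).
#' @param burnin burn-in iterations discarded from all summaries.
#' @param quad_order quadrature order for the marginal likelihood.
#' @param seed integer seed.
#' @param init optional start: an `"ogm"` fit or theta vector (recommended:
#'   the MLE).
#' @param prior list with `coef_sd` (default 10) and `sd_scale` (default 5).
#' @param reference_levels passed to [build_design()].
#' @return Object of class `"ogm_mcmc"` with draws (natural scale),
#'   posterior medians and 95% credible intervals, acceptance rate, deviance
#'   summaries and ICC at the posterior-median intercept variance.
#' @export
ogm_mcmc <- function(data, spec = NULL, iters = 4000, burnin = 1000,
                     quad_order = 5, seed = 1L, init = NULL,
                     prior = list(coef_sd = 10, sd_scale = 5),
                     reference_levels = NULL) {
  bundle <- if (inherits(data, "ogm_design")) data
            else build_design(data, spec, reference_levels)
  spec <- bundle$spec
  dims <- theta_dims(bundle)
  gh <- gauss_hermite(quad_order)
  prior <- modifyList(list(coef_sd = 10, sd_scale = 5), prior)

  theta <- if (is.null(init)) default_start(bundle, dims)
           else if (inherits(init, "ogm")) init$theta
           else as.numeric(init)
  d <- length(theta)

  ll_fun <- function(th) {
    v <- marginal_ll_raw(theta_unpack(th, dims), bundle, gh)$loglik
    if (is.nan(v)) stop("NaN posterior density; check data and priors")
    v
  }
  lp_fun <- function(th, ll) ll + log_prior(th, dims, prior)

  set.seed(seed)
  ll_cur <- ll_fun(theta)
  if (!is.finite(ll_cur)) stop("initial parameter value has zero likelihood")
  post_cur <- lp_fun(theta, ll_cur)

  draws <- matrix(NA_real_, iters, d)
  lls <- numeric(iters)
  scale <- 2.38 / sqrt(d)
  chol_prop <- diag(d) * 0.1
  acc_window <- 0
  n_acc <- 0
  for (it in seq_len(iters)) {
    prop <- theta + scale * as.numeric(chol_prop %*% rnorm(d))
    ll_p <- ll_fun(prop)
    post_p <- if (is.finite(ll_p)) lp_fun(prop, ll_p) else -Inf
    if (is.finite(post_p) && log(runif(1)) < post_p - post_cur) {
      theta <- prop; ll_cur <- ll_p; post_cur <- post_p
      n_acc <- n_acc + 1; acc_window <- acc_window + 1
    }
    draws[it, ] <- theta
    lls[it] <- ll_cur
    if (it <= burnin && it %% 50 == 0) {
      rate <- acc_window / 50
      scale <- scale * exp(0.8 * (rate - 0.3))
      acc_window <- 0
      if (it >= 200) {
        S <- stats::cov(draws[max(1, it - 500):it, , drop = FALSE])
        S <- S + diag(1e-8, d)
        ch <- tryCatch(t(chol(S)), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- ch
      }
    }
  }
  keep <- draws[(burnin + 1):iters, , drop = FALSE]
  keep_ll <- lls[(burnin + 1):iters]
  accept_rate <- n_acc / iters
  warn <- character(0)
  if (accept_rate < 0.1 || accept_rate > 0.6)
    warn <- sprintf("acceptance rate %.2f outside [0.1, 0.6]", accept_rate)

  dev <- -2 * keep_ll
  dbar <- mean(dev)
  theta_bar <- colMeans(keep)
  dev_at_mean <- -2 * ll_fun(theta_bar)
  pD <- dbar - dev_at_mean
  dic <- dbar + pD

  nat <- t(apply(keep, 1, natural_params, dims = dims, bundle = bundle))
  med <- apply(nat, 2, median)
  ci <- t(apply(nat, 2, quantile, c(0.025, 0.975)))
  colnames(ci) <- c("lower", "upper")

  up_med <- theta_unpack(apply(keep, 2, median), dims)
  params_med <- param_vector(
    thresholds = up_med$delta,
    shared = setNames(up_med$beta_s, colnames(bundle$Xs)),
    npo = if (dims$pn) {
      m <- up_med$beta_n; colnames(m) <- colnames(bundle$Xn); m
    } else NULL,
    D = up_med$D)

  structure(list(
    call = match.call(), spec = spec, dims = dims,
    draws = nat, draws_theta = keep, loglik_draws = keep_ll,
    estimates = med, ci = ci,
    params = params_med,
    accept_rate = accept_rate,
    dbar = dbar, pD = pD, dic = dic,
    icc = icc_latent(if ("var_u0" %in% names(med)) med[["var_u0"]]
                     else up_med$D[1, 1]),
    converged = length(warn) == 0,
    warnings = warn,
    iters = iters, burnin = burnin, quad_order = quad_order, seed = seed,
    n = bundle$n, n_subjects = bundle$n_subjects, K = dims$K,
    shared_cols = colnames(bundle$Xs), npo_cols = colnames(bundle$Xn)),
    class = "ogm_mcmc")
}

#' @export
print.ogm_mcmc <- function(x, ...) {
  type <- if (length(x$npo_cols)) "non-proportional odds" else "proportional odds"
  cat(sprintf("Posterior fit (%s), %d kept draws (acceptance %.2f)\n",
              type, nrow(x$draws), x$accept_rate))
  cat(sprintf("  dbar = %.2f, pD = %.2f, DIC = %.2f; ICC = %.3f\n",
              x$dbar, x$pD, x$dic, x$icc))
  if (length(x$warnings)) cat("  WARNING:", x$warnings, "\n")
  tab <- cbind(median = x$estimates, x$ci)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.ogm_mcmc <- function(object, ...) object$estimates
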