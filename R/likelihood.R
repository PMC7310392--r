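# Likelihood machinery: category probabilities, conditional and marginal
# log-likelihood (adaptive Gauss-Hermite quadrature over the random effects),
# and the unconstrained parameterization used by the optimizer and sampler.

#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for integration against `exp(-x^2)`, as used by the
#' adaptive quadrature. Thin wrapper over [pracma::gaussHermite()].
#'
#' @param n quadrature order (>= 1).
#' @return List with `x` (nodes) and `w` (weights).
#' @export
gauss_hermite <- function(n) {
  if (n < 1) stop("quadrature order must be >= 1")
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, w = gh$w)
}

#' Category probabilities for one covariate pattern
#'
#' Evaluates `P(Y <= k) = expit(threshold_k + x*' beta_c[k] + x' beta + u0 +
#' u1 * time)` and differences it into the K category probabilities. A
#' parameter/pattern combination with non-monotone cumulative probabilities
#' (possible under non-proportional odds) raises a condition of class
#' `"ordgrowth_invalid_params"`, which the likelihood consumes as `-Inf`.
#'
#' @param params an [param_vector()].
#' @param row named list or one-row data frame with the covariates named in
#'   `params` (and `time` when used).
#' @param u length-2 random effect `(u0, u1)`.
#' @return Numeric vector of K probabilities summing to 1.
#' @export
category_probabilities <- function(params, row, u = c(0, 0)) {
  validate_params(params)
  centers <- params$centers
  center_of <- function(nm) if (!is.null(centers) && nm %in% names(centers))
    centers[[nm]] else 0
  val_of <- function(nm) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      return(prod(vapply(parts, val_of, numeric(1))))
    }
    v <- row[[nm]]
    if (is.null(v)) stop("covariate '", nm, "' not found in row")
    as.numeric(v) - center_of(nm)
  }
  eta <- params$thresholds
  for (nm in names(params$shared)) eta <- eta + params$shared[[nm]] * val_of(nm)
  for (nm in colnames(params$npo)) eta <- eta + params$npo[, nm] * val_of(nm)
  tim <- if (!is.null(row[["time"]])) as.numeric(row[["time"]]) else 0
  eta <- eta + u[1] + u[2] * tim
  pk <- diff(c(0, plogis(eta), 1))
  if (any(pk < 0))
    stop(structure(class = c("ordgrowth_invalid_params", "error", "condition"),
                   list(message = "non-monotone cumulative probabilities",
                        call = sys.call(-1))))
  pk
}

#' Conditional log-likelihood of a subject's visits given the random effects
#'
#' Sum over the subject's visits of the log probability of the observed
#' stage, conditional on `(u0, u1)`; visits are independent given the random
#' effects. Invalid parameter/pattern combinations give `-Inf`.
#'
#' @param params an [param_vector()].
#' @param subject_rows data frame of the subject's visits (with the outcome
#'   column `stage` and covariates).
#' @param u length-2 random effect.
#' @param outcome name of the outcome column.
#' @return Scalar log-likelihood.
#' @export
conditional_loglik <- function(params, subject_rows, u = c(0, 0),
                               outcome = "stage") {
  ll <- 0
  for (r in seq_len(nrow(subject_rows))) {
    row <- subject_rows[r, ]
    pk <- tryCatch(category_probabilities(params, row, u),
                   ordgrowth_invalid_params = function(e) NULL)
    if (is.null(pk)) return(-Inf)
    p <- pk[[row[[outcome]]]]
    if (p <= 0) return(-Inf)
    ll <- ll + log(p)
  }
  ll
}

# ---- unconstrained parameterization -----------------------------------------
# theta = [delta_1, log diff(delta)_{2..K-1}, beta_shared, beta_npo (by
#          covariate, K-1 each), re block]
# re block: none -> (); intercept -> log sd0; slope -> (log sd0, log sd1,
# atanh rho). Thresholds stay ordered and D positive definite by construction.

theta_dims <- function(bundle) {
  K <- bundle$K
  ps <- ncol(bundle$Xs)
  pn <- ncol(bundle$Xn)
  re <- bundle$spec$random
  nre <- switch(re, none = 0L, intercept = 1L, slope = 3L)
  list(K = K, ps = ps, pn = pn, re = re, nre = nre,
       n_theta = (K - 1) + ps + pn * (K - 1) + nre)
}

theta_unpack <- function(theta, dims) {
  K <- dims$K
  d1 <- theta[1]
  delta <- if (K > 2) cumsum(c(d1, exp(theta[2:(K - 1)]))) else d1
  i <- K - 1
  beta_s <- if (dims$ps) theta[i + seq_len(dims$ps)] else numeric(0)
  i <- i + dims$ps
  beta_n <- if (dims$pn)
    matrix(theta[i + seq_len(dims$pn * (K - 1))], K - 1, dims$pn)
  else matrix(0, K - 1, 0)
  i <- i + dims$pn * (K - 1)
  if (dims$re == "none") {
    L <- matrix(0, 2, 2); re_mode <- 0L
    D <- matrix(0, 2, 2)
  } else if (dims$re == "intercept") {
    s0 <- exp(theta[i + 1])
    L <- matrix(c(s0, 0, 0, 0), 2, 2); re_mode <- 1L
    D <- matrix(c(s0^2, 0, 0, 0), 2, 2)
  } else {
    s0 <- exp(theta[i + 1]); s1 <- exp(theta[i + 2])
    rho <- tanh(theta[i + 3])
    L <- matrix(c(s0, rho * s1, 0, s1 * sqrt(1 - rho^2)), 2, 2)
    D <- matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2, 2)
    re_mode <- 2L
  }
  list(delta = delta, beta_s = beta_s, beta_n = beta_n,
       L = L, D = D, re_mode = re_mode)
}

theta_pack <- function(delta, beta_s, beta_n, D, dims) {
  K <- dims$K
  th <- c(delta[1], if (K > 2) log(diff(delta)))
  th <- c(th, beta_s)
  if (dims$pn) th <- c(th, as.numeric(beta_n))
  if (dims$re == "intercept") {
    th <- c(th, 0.5 * log(max(D[1, 1], 1e-8)))
  } else if (dims$re == "slope") {
    s0 <- sqrt(max(D[1, 1], 1e-8)); s1 <- sqrt(max(D[2, 2], 1e-8))
    rho <- D[1, 2] / (s0 * s1)
    rho <- max(min(rho, 0.99), -0.99)
    th <- c(th, log(s0), log(s1), atanh(rho))
  }
  th
}

theta_names <- function(bundle, dims) {
  K <- dims$K
  nm <- c("delta_1", if (K > 2) paste0("log_incr_", 2:(K - 1)))
  nm <- c(nm, colnames(bundle$Xs))
  if (dims$pn)
    nm <- c(nm, as.vector(outer(paste0("logit", seq_len(K - 1), ":"),
                                colnames(bundle$Xn), paste0)))
  nm <- c(nm, switch(dims$re, none = character(0),
                     intercept = "log_sd_u0",
                     slope = c("log_sd_u0", "log_sd_u1", "atanh_rho")))
  nm
}

# raw marginal log-likelihood at unpacked parameters
marginal_ll_raw <- function(up, bundle, gh, per_subject = FALSE) {
  res <- ogm_marginal_ll_cpp(up$delta, up$beta_s, up$beta_n,
                             bundle$Xs, bundle$Xn,
                             as.integer(bundle$y), bundle$time,
                             as.integer(bundle$first - 1L),
                             as.integer(bundle$last - 1L),
                             up$L, up$re_mode, gh$x, gh$w,
                             per_subject)
  res
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Integrates the random effects out of the two-level cumulative-logit
#' likelihood: per subject, the integrand is re-centred at its mode and
#' re-scaled by its Laplace curvature, and a tensor Gauss-Hermite grid of the
#' given order is applied over the standardized bivariate effect. A
#' degenerate slope variance collapses to one-dimensional quadrature;
#' `D = 0` reduces to the conditional log-likelihood at `u = 0`. Parameter
#' vectors with non-monotone cumulative logits at an observed pattern give
#' `-Inf`.
#'
#' @param params an [param_vector()] whose `shared` names match the bundle's
#'   shared design columns and whose `npo` columns match the bundle's
#'   category-specific columns.
#' @param bundle an [build_design()] bundle.
#' @param quad_order quadrature order per dimension (default 9).
#' @param per_subject if `TRUE`, also return the per-subject contributions.
#' @return Scalar log-likelihood, or a list when `per_subject = TRUE`.
#' @export
marginal_loglik <- function(params, bundle, quad_order = 9,
                            per_subject = FALSE) {
  validate_params(params)
  ns <- colnames(bundle$Xs)
  if (length(ns) && !setequal(names(params$shared), ns))
    stop("shared coefficient names do not match the design columns")
  beta_s <- if (length(ns)) params$shared[ns] else numeric(0)
  nn <- colnames(bundle$Xn)
  if (length(nn) && (is.null(params$npo) || !setequal(colnames(params$npo), nn)))
    stop("npo coefficient columns do not match the design columns")
  beta_n <- if (length(nn)) params$npo[, nn, drop = FALSE]
            else matrix(0, bundle$K - 1, 0)
  D <- params$D
  re_mode <- if (all(D == 0)) 0L else if (D[2, 2] <= 0) 1L else 2L
  if (bundle$spec$random == "none") re_mode <- 0L
  if (bundle$spec$random == "intercept") re_mode <- min(re_mode, 1L)
  up <- list(delta = params$thresholds, beta_s = unname(beta_s),
             beta_n = unname(as.matrix(beta_n)),
             L = chol_psd2(D), re_mode = re_mode)
  gh <- gauss_hermite(quad_order)
  res <- marginal_ll_raw(up, bundle, gh, per_subject)
  if (per_subject) list(loglik = res$loglik, per_subject = res$per_subject)
  else res$loglik
}
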