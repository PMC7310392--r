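#' Construct a parameter vector for the cumulative-logit growth model
#'
#' Bundles the full parameter state of the two-level cumulative-logit model:
#' the K-1 strictly increasing thresholds on the logit scale, shared
#' (proportional-odds) coefficients, category-specific (non-proportional-odds)
#' coefficients, and the 2x2 covariance of the random intercept and time
#' slope. Optionally carries centering constants subtracted from covariates
#' before they enter the linear predictor.
#'
#' The model is
#' \deqn{\mathrm{logit}\, P(Y_{ti} \le k) = \delta^{(k)} + x^{*\prime}_{ti}
#'   \beta_c^{(k)} + x'_{ti}\beta + u_{0i} + u_{1i} t,}
#' with \eqn{(u_0, u_1) \sim N(0, D)}. A positive coefficient moves mass
#' towards low-numbered (better) outcome categories.
#'
#' @param thresholds numeric vector of K-1 strictly increasing thresholds.
#' @param shared named numeric vector of proportional-odds coefficients
#'   (may be empty). The reserved name `"time"` refers to the time column;
#'   names containing `":"` denote products of columns (interactions).
#' @param npo (K-1) x m numeric matrix of category-specific coefficients,
#'   one named column per non-proportional covariate, or `NULL`.
#' @param D 2x2 symmetric positive semidefinite covariance of the random
#'   intercept and slope; entries `[1,1]` intercept variance, `[2,2]` slope
#'   variance. Use a zero matrix for no random effects.
#' @param centers optional named numeric vector of centering constants.
#' @return An object of class `"ogm_params"`.
#' @examples
#' param_vector(log(c(0.02, 19.87, 24.51)),
#'              shared = c(time = 0.3),
#'              D = matrix(c(12.21, -0.36, -0.36, 0.02), 2))
#' @export
param_vector <- function(thresholds, shared = numeric(0), npo = NULL,
                         D = matrix(0, 2, 2), centers = NULL) {
  p <- structure(list(thresholds = as.numeric(thresholds),
                      shared = shared, npo = npo,
                      D = D, centers = centers),
                 class = "ogm_params")
  validate_params(p)
  p
}

#' Validate a parameter vector
#'
#' Checks strict threshold ordering, finiteness, conformity of the
#' category-specific coefficient matrix, and positive semidefiniteness of the
#' random-effects covariance.
#'
#' @param params an [param_vector()] object (or a bare list with the same
#'   fields).
#' @return `params`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_params <- function(params) {
  th <- params$thresholds
  if (length(th) < 1 || anyNA(th) || any(!is.finite(th)))
    stop("thresholds must be finite and non-empty")
  if (length(th) > 1 && any(diff(th) <= 0))
    stop("thresholds must be strictly increasing")
  if (length(params$shared) && is.null(names(params$shared)))
    stop("shared coefficients must be named")
  if (!is.null(params$npo)) {
    if (!is.matrix(params$npo) || nrow(params$npo) != length(th))
      stop("npo must be a (K-1) x m matrix matching the thresholds")
    if (is.null(colnames(params$npo)))
      stop("npo columns must be named")
  }
  D <- params$D
  if (!is.matrix(D) || !all(dim(D) == 2) || abs(D[1, 2] - D[2, 1]) > 1e-12)
    stop("D must be a symmetric 2x2 matrix")
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("D must be positive semidefinite")
  invisible(params)
}

# lower Cholesky factor of a PSD 2x2 covariance; handles degenerate cases
chol_psd2 <- function(D) {
  L <- matrix(0, 2, 2)
  if (D[1, 1] > 0) {
    L[1, 1] <- sqrt(D[1, 1])
    L[2, 1] <- D[2, 1] / L[1, 1]
    s <- D[2, 2] - L[2, 1]^2
    L[2, 2] <- sqrt(max(s, 0))
  } else {
    L[2, 2] <- sqrt(max(D[2, 2], 0))
  }
  L
}

#' @export
print.ogm_params <- function(x, ...) {
  K <- length(x$thresholds) + 1
  cat("Cumulative-logit growth model parameters (K =", K, "categories)\n")
  cat("  thresholds:", format(x$thresholds, digits = 4), "\n")
  if (length(x$shared)) {
    cat("  shared coefficients:\n")
    print(x$shared)
  }
  if (!is.null(x$npo)) {
    cat("  category-specific coefficients (rows = cumulative logits):\n")
    print(x$npo)
  }
  cat("  random-effects covariance D:\n")
  print(x$D)
  invisible(x)
}
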