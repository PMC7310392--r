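# Exploratory factor reduction of clinical panels: principal-component
# extraction from the correlation matrix, Kaiser retention, varimax rotation,
# loading-strength classification, regression-method factor scores.

varimax_criterion <- function(L) {
  # sum over factors of the variance of squared loadings
  sq <- L^2
  sum(apply(sq, 2, function(col) mean((col - mean(col))^2)))
}

#' Extract principal-component factors from a clinical panel
#'
#' Eigendecomposition of the correlation matrix; loadings are eigenvectors
#' scaled by the square root of their eigenvalues. Factors are retained by the
#' Kaiser criterion (eigenvalue strictly greater than 1; values within 1e-10
#' of 1 are not retained). If no eigenvalue exceeds 1 the first factor is
#' retained so the solution is non-empty.
#'
#' @param X numeric matrix or data frame, observations x variables; more
#'   observations than variables, no zero-variance column.
#' @return An object of class `"factor_solution"` with fields `eigenvalues`
#'   (all, descending), `loadings` (variables x retained factors), `rotation`
#'   (identity until rotated), `variance_explained` (cumulative fraction for
#'   the retained factors), `scoring_weights`, `variable_names`,
#'   `factor_names`, and the correlation matrix `R`.
#' @export
extract_components <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X))
    stop("need more observations than variables")
  sds <- apply(X, 2, sd)
  if (any(!is.finite(sds) | sds == 0)) {
    bad <- colnames(X)[!is.finite(sds) | sds == 0]
    if (is.null(bad)) bad <- which(!is.finite(sds) | sds == 0)
    stop("zero-variance or non-finite column(s): ", paste(bad, collapse = ", "))
  }
  R <- cor(X)
  if (anyNA(R))
    stop("correlation matrix contains NA")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  e <- eigen(R, symmetric = TRUE)
  vals <- e$values
  nret <- sum(vals > 1 + 1e-10)
  if (nret == 0) {
    message("no eigenvalue exceeds 1; retaining the first factor")
    nret <- 1
  }
  L <- e$vectors[, seq_len(nret), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(nret)]), nret)
  # sign convention: the largest-magnitude loading of each factor is positive
  for (j in seq_len(nret)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("F", seq_len(nret)))
  sol <- structure(list(
    eigenvalues = vals,
    loadings = L,
    rotation = diag(nret),
    variance_explained = sum(vals[seq_len(nret)]) / ncol(X),
    scoring_weights = solve(R, L),
    variable_names = colnames(X),
    factor_names = colnames(L),
    R = R,
    center = colMeans(X),
    scale = sds,
    rotated = FALSE,
    converged = TRUE),
    class = "factor_solution")
  sol
}

#' Varimax rotation of a factor solution
#'
#' Orthogonal rotation maximizing the varimax criterion (the sum over factors
#' of the variance of squared loadings) by iterated pairwise planar rotations,
#' with Kaiser row normalization. After rotation each factor's
#' largest-magnitude loading is made positive and factors are reordered by
#' explained variance. A one-factor solution is returned unchanged.
#'
#' @param solution a `"factor_solution"` from [extract_components()].
#' @param tol stop when a full sweep improves the criterion by less than this.
#' @param max_iter maximum number of sweeps; non-convergence returns the best
#'   iterate with `converged = FALSE`.
#' @return The rotated `"factor_solution"`; `rotation` holds the accumulated
#'   orthogonal rotation matrix and `scoring_weights` are recomputed for the
#'   rotated loadings.
#' @export
varimax_rotate <- function(solution, tol = 1e-8, max_iter = 1000) {
  L <- solution$loadings
  m <- ncol(L)
  if (m < 2) return(solution)
  h <- sqrt(rowSums(L^2))          # Kaiser normalization
  h[h == 0] <- 1
  A <- L / h
  Tm <- diag(m)
  crit_old <- varimax_criterion(A)
  converged <- FALSE
  for (sweep in seq_len(max_iter)) {
    for (p in seq_len(m - 1)) {
      for (q in seq((p + 1), m)) {
        x <- A[, p]; y <- A[, q]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- sum(2 * u * v) - 2 * sum(u) * sum(v) / nrow(A)
        den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / nrow(A)
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-12) next
        cs <- cos(phi); sn <- sin(phi)
        A[, p] <- cs * x + sn * y
        A[, q] <- -sn * x + cs * y
        tp <- Tm[, p]; tq <- Tm[, q]
        Tm[, p] <- cs * tp + sn * tq
        Tm[, q] <- -sn * tp + cs * tq
      }
    }
    crit <- varimax_criterion(A)
    if (crit - crit_old < tol) { converged <- TRUE; break }
    crit_old <- crit
  }
  L2 <- A * h
  # sign convention and ordering by explained variance
  sgn <- rep(1, m)
  for (j in seq_len(m)) {
    i <- which.max(abs(L2[, j]))
    if (L2[i, j] < 0) sgn[j] <- -1
  }
  L2 <- sweep(L2, 2, sgn, `*`)
  Tm <- sweep(Tm, 2, sgn, `*`)
  ord <- order(colSums(L2^2), decreasing = TRUE)
  L2 <- L2[, ord, drop = FALSE]
  Tm <- Tm[, ord, drop = FALSE]
  dimnames(L2) <- list(solution$variable_names,
                       paste0("F", seq_len(m)))
  out <- solution
  out$loadings <- L2
  out$rotation <- Tm
  out$scoring_weights <- solve(solution$R, L2)
  out$rotated <- TRUE
  out$converged <- converged
  out$criterion <- varimax_criterion(L2)
  out
}

#' Classify loading strengths
#'
#' Bands the absolute loading: weak below 0.4, moderate from 0.4 to 0.6
#' inclusive, strong above 0.6.
#'
#' @param loadings numeric matrix (or vector) of loadings.
#' @return Character matrix of `"weak"`, `"moderate"`, `"strong"` with the
#'   same shape as `loadings`.
#' @examples
#' classify_loadings(c(0.925, -0.592, 0.4, 0.2))
#' @export
classify_loadings <- function(loadings) {
  a <- abs(loadings)
  out <- ifelse(a < 0.4, "weak", ifelse(a <= 0.6, "moderate", "strong"))
  if (is.matrix(loadings)) dimnames(out) <- dimnames(loadings)
  out
}

#' Regression-method factor scores
#'
#' Scores each observation on each (rotated) factor by the regression method:
#' standardized data times the inverse correlation matrix times the loadings.
#' Scores have mean approximately zero.
#'
#' @param X data with the same columns (by name) as the solution.
#' @param solution a `"factor_solution"`.
#' @return observations x factors numeric matrix.
#' @export
score_factors <- function(X, solution) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!identical(sort(colnames(X)), sort(solution$variable_names))) {
    extra <- setdiff(colnames(X), solution$variable_names)
    missing <- setdiff(solution$variable_names, colnames(X))
    stop("column mismatch; missing: [", paste(missing, collapse = ", "),
         "], unexpected: [", paste(extra, collapse = ", "), "]")
  }
  X <- X[, solution$variable_names, drop = FALSE]
  Z <- scale(X, center = solution$center, scale = solution$scale)
  S <- Z %*% solution$scoring_weights
  colnames(S) <- solution$factor_names
  S
}

#' Full factor-reduction pipeline for one panel
#'
#' Extraction, varimax rotation (when at least two factors are retained),
#' loading classification and regression scores, in one call.
#'
#' @inheritParams extract_components
#' @param tol,max_iter passed to [varimax_rotate()].
#' @return A list: `solution` (rotated), `strength` (classified loadings),
#'   `scores`.
#' @export
reduce_panel <- function(X, tol = 1e-8, max_iter = 1000) {
  sol <- extract_components(X)
  sol <- varimax_rotate(sol, tol = tol, max_iter = max_iter)
  list(solution = sol,
       strength = classify_loadings(sol$loadings),
       scores = score_factors(X, sol))
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat(sprintf("Factor solution: %d of %d factors retained (%s)\n",
              ncol(x$loadings), length(x$eigenvalues),
              if (isTRUE(x$rotated)) "varimax-rotated" else "unrotated"))
  cat("Eigenvalues:", format(round(x$eigenvalues, digits)), "\n")
  cat(sprintf("Cumulative variance explained: %.1f%%\n",
              100 * x$variance_explained))
  print(round(x$loadings, digits))
  invisible(x)
}
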