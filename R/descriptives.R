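# Baseline descriptive statistics and correlation screening.

# round half up to `digits` decimals (display convention for percentages;
# base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Baseline descriptive table
#'
#' Counts and percentages for categorical variables and median / interquartile
#' range for continuous variables, in the layout of a cohort baseline table.
#' Percentages use the variable's non-missing count as denominator and are
#' rounded half-up to one decimal. Quantiles use the default
#' linear-interpolation rule (type 7).
#'
#' @param data a data frame with one row per subject.
#' @param categorical character vector of categorical variable names.
#' @param continuous character vector of continuous variable names.
#' @param levels optional named list giving the admissible category levels
#'   per categorical variable (in display order). Values outside the declared
#'   set raise an error naming the variable and value.
#' @return An object of class `"ogm_baseline"`: a list with data frames
#'   `categorical` (variable, level, count, percent) and `continuous`
#'   (variable, median, q1, q3), plus the denominators used.
#' @examples
#' d <- data.frame(edu = rep(c("low", "mid", "high"), c(16, 50, 153)))
#' baseline_table(d, categorical = "edu",
#'                levels = list(edu = c("low", "mid", "high")))
#' @export
baseline_table <- function(data, categorical = character(),
                           continuous = character(), levels = NULL) {
  miss <- setdiff(c(categorical, continuous), names(data))
  if (length(miss))
    stop("variables not found in data: ", paste(miss, collapse = ", "))
  cat_rows <- list()
  denoms <- c()
  for (v in categorical) {
    x <- data[[v]]
    x <- x[!is.na(x)]
    x <- as.character(x)
    lv <- if (!is.null(levels) && !is.null(levels[[v]])) levels[[v]]
          else sort(unique(x))
    bad <- setdiff(unique(x), lv)
    if (length(bad))
      stop(sprintf("variable '%s' has value(s) outside declared levels: %s",
                   v, paste(bad, collapse = ", ")))
    n <- length(x)
    cnt <- vapply(lv, function(l) sum(x == l), integer(1))
    cat_rows[[v]] <- data.frame(variable = v, level = lv,
                                count = as.integer(cnt),
                                percent = round_half_up(100 * cnt / n, 1),
                                row.names = NULL)
    denoms[v] <- n
  }
  cont_rows <- list()
  for (v in continuous) {
    x <- data[[v]]
    x <- x[!is.na(x)]
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    cont_rows[[v]] <- data.frame(variable = v, median = q[2],
                                 q1 = q[1], q3 = q[3], row.names = NULL)
    denoms[v] <- length(x)
  }
  structure(list(categorical = do.call(rbind, c(cat_rows, list(NULL))),
                 continuous = do.call(rbind, c(cont_rows, list(NULL))),
                 denominators = denoms),
            class = "ogm_baseline")
}

#' @export
print.ogm_baseline <- function(x, ...) {
  cat("Baseline characteristics\n")
  if (!is.null(x$categorical)) {
    for (v in unique(x$categorical$variable)) {
      sub <- x$categorical[x$categorical$variable == v, ]
      cat(sprintf("%s, n (%%)\n", v))
      for (i in seq_len(nrow(sub)))
        cat(sprintf("  %-28s %d (%.1f)\n", sub$level[i], sub$count[i],
                    sub$percent[i]))
    }
  }
  if (!is.null(x$continuous)) {
    for (i in seq_len(nrow(x$continuous)))
      cat(sprintf("%s, Median (IQR)  %.2f (%.2f-%.2f)\n",
                  x$continuous$variable[i], x$continuous$median[i],
                  x$continuous$q1[i], x$continuous$q3[i]))
  }
  invisible(x)
}

#' Pairwise correlations with significance bands
#'
#' Pearson correlations with two-sided p-values from the t approximation and
#' the conventional three-band star coding (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `ns` otherwise), the tabular counterpart of a
#' correlogram. Missing values are handled pairwise-complete; zero-variance
#' columns yield undefined correlations, reported as `NA` and listed in the
#' returned warning records.
#'
#' @param X numeric matrix or data frame, observations x variables.
#' @return An object of class `"ogm_corr"`: list with matrices `r`, `p`,
#'   `stars`, the pairwise `n`, and a character vector `warnings`.
#' @export
correlation_significance <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  vn <- colnames(X)
  r <- matrix(NA_real_, p, p, dimnames = list(vn, vn))
  pv <- matrix(NA_real_, p, p, dimnames = list(vn, vn))
  nn <- matrix(NA_integer_, p, p, dimnames = list(vn, vn))
  warnings <- character(0)
  sds <- apply(X, 2, sd, na.rm = TRUE)
  degen <- which(is.na(sds) | sds == 0)
  if (length(degen))
    warnings <- sprintf("zero-variance column: %s", vn[degen])
  diag(r) <- 1
  diag(pv) <- 0
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      ok <- complete.cases(X[, c(i, j)])
      n <- sum(ok)
      nn[i, j] <- nn[j, i] <- n
      if (n < 3 || i %in% degen || j %in% degen) next
      rij <- suppressWarnings(cor(X[ok, i], X[ok, j]))
      if (is.na(rij)) next
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        pij <- 0
      } else {
        tt <- rij * sqrt((n - 2) / (1 - rij^2))
        pij <- 2 * pt(-abs(tt), df = n - 2)
      }
      pv[i, j] <- pv[j, i] <- pij
    }
  }
  stars <- matrix("ns", p, p, dimnames = list(vn, vn))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  stars[!is.na(pv) & pv < 0.001] <- "***"
  stars[is.na(pv)] <- NA_character_
  diag(stars) <- ""
  structure(list(r = r, p = pv, stars = stars, n = nn, warnings = warnings),
            class = "ogm_corr")
}

#' @export
print.ogm_corr <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (stars: * <0.05, ** <0.01, *** <0.001)\n")
  m <- matrix(paste0(format(round(x$r, digits)), " ", x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  print(m, quote = FALSE)
  if (length(x$warnings)) cat("Warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}
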