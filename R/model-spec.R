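# Model specification and design construction for the two-level
# cumulative-logit growth model.

#' Specify a cumulative-logit growth model
#'
#' Names the outcome, the time variable, and which covariates act
#' proportionally (one coefficient across all cumulative logits), which are
#' category-specific (one coefficient per logit; the non-proportional-odds
#' part), and which interact with time. Interactions are built as derived
#' columns named `"covariate:time"`; they act proportionally unless the
#' derived name is listed in `npo`.
#'
#' @param outcome name of the ordinal outcome column (codes 1..K).
#' @param time name of the time column (years).
#' @param K number of outcome categories (default 4).
#' @param shared character vector of proportional-odds covariate names; the
#'   name `time` includes the time trend itself.
#' @param npo character vector of category-specific covariate names
#'   (disjoint from `shared`).
#' @param time_interactions covariates whose product with time enters the
#'   model.
#' @param random `"slope"` for correlated random intercept and time slope,
#'   `"intercept"` for intercept only, `"none"` for a single-level fit.
#' @param subject name of the subject identifier column.
#' @return Object of class `"ogm_spec"`.
#' @export
model_spec <- function(outcome = "stage", time = "time", K = 4,
                       shared = character(), npo = character(),
                       time_interactions = character(),
                       random = c("slope", "intercept", "none"),
                       subject = "subject_id") {
  random <- match.arg(random)
  if (K < 2) stop("K must be >= 2")
  overlap <- intersect(shared, npo)
  if (length(overlap))
    stop("shared and npo sets must be disjoint; overlap: ",
         paste(overlap, collapse = ", "))
  needs_time <- random == "slope" || length(time_interactions) ||
    time %in% c(shared, npo)
  if (needs_time && !nzchar(time))
    stop("a time variable is required for slopes or time interactions")
  structure(list(outcome = outcome, time = time, K = as.integer(K),
                 shared = shared, npo = npo,
                 time_interactions = time_interactions,
                 random = random, subject = subject),
            class = "ogm_spec")
}

expand_column <- function(data, name, spec, reference_levels) {
  # numeric column -> itself; categorical -> treatment dummies against the
  # reference level (declared, or the first sorted level)
  if (name == spec$time) {
    m <- matrix(as.numeric(data[[name]]), ncol = 1)
    colnames(m) <- name
    return(m)
  }
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    cols <- lapply(parts, expand_column, data = data, spec = spec,
                   reference_levels = reference_levels)
    if (any(vapply(cols, ncol, 1L) != 1))
      stop("interactions with categorical covariates are not supported: ", name)
    m <- cols[[1]] * cols[[2]]
    colnames(m) <- name
    return(m)
  }
  x <- data[[name]]
  if (is.null(x)) stop("column not found in data: ", name)
  if (is.numeric(x)) {
    m <- matrix(as.numeric(x), ncol = 1)
    colnames(m) <- name
    return(m)
  }
  x <- as.character(x)
  declared <- reference_levels[[name]]
  lv <- if (!is.null(declared)) declared else sort(unique(x))
  bad <- setdiff(unique(x), lv)
  if (length(bad))
    stop(sprintf("unseen category level in '%s': %s", name,
                 paste(bad, collapse = ", ")))
  f <- factor(x, levels = lv)
  m <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0(name, "=", lv[-1])
  m
}

#' Build the design bundle for a model specification
#'
#' Deterministically assembles, per subject, the outcome codes, the shared
#' and category-specific design matrices (categorical covariates expanded
#' against their reference levels, time interactions as product columns),
#' the time vector, and the row-to-subject index structures consumed by the
#' likelihood. Rows are sorted by subject and time.
#'
#' @param data long-format visit table.
#' @param spec an [model_spec()].
#' @param reference_levels optional named list of declared level sets per
#'   categorical covariate; the first level is the reference.
#' @return Object of class `"ogm_design"`.
#' @export
build_design <- function(data, spec, reference_levels = NULL) {
  needed <- c(spec$outcome, spec$subject,
              if (nzchar(spec$time)) spec$time)
  base_named <- unique(unlist(strsplit(c(spec$shared, spec$npo,
                                         spec$time_interactions), ":")))
  needed <- unique(c(needed, setdiff(base_named, spec$time)))
  miss <- setdiff(needed, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0) stop("data has no rows")
  y <- data[[spec$outcome]]
  if (anyNA(y)) stop("missing outcome values")
  if (!all(y %in% seq_len(spec$K)))
    stop("outcome codes must be integers in 1..", spec$K)
  ord <- order(match(data[[spec$subject]], unique(data[[spec$subject]])),
               data[[spec$time]])
  data <- data[ord, ]
  y <- as.integer(data[[spec$outcome]])
  tim <- if (nzchar(spec$time)) as.numeric(data[[spec$time]])
         else rep(0, nrow(data))

  inter <- if (length(spec$time_interactions))
    paste0(spec$time_interactions, ":", spec$time) else character(0)
  shared_terms <- c(spec$shared, setdiff(inter, spec$npo))
  npo_terms <- spec$npo

  bind_cols <- function(terms) {
    if (!length(terms)) return(matrix(0, nrow(data), 0))
    do.call(cbind, lapply(terms, expand_column, data = data, spec = spec,
                          reference_levels = reference_levels))
  }
  Xs <- bind_cols(shared_terms)
  Xn <- bind_cols(npo_terms)

  ids <- unique(data[[spec$subject]])
  pos <- match(data[[spec$subject]], ids)
  first <- vapply(seq_along(ids), function(i) min(which(pos == i)), 1L)
  last <- vapply(seq_along(ids), function(i) max(which(pos == i)), 1L)

  structure(list(y = y, Xs = Xs, Xn = Xn, time = tim,
                 first = first, last = last,
                 subject_ids = ids, K = spec$K,
                 n = nrow(data), n_subjects = length(ids),
                 spec = spec),
            class = "ogm_design")
}

#' @export
print.ogm_design <- function(x, ...) {
  cat(sprintf("Design bundle: %d visits, %d subjects, K = %d\n",
              x$n, x$n_subjects, x$K))
  cat("  shared columns:", if (ncol(x$Xs)) paste(colnames(x$Xs), collapse = ", ")
      else "(none)", "\n")
  cat("  category-specific columns:",
      if (ncol(x$Xn)) paste(colnames(x$Xn), collapse = ", ") else "(none)", "\n")
  cat("  random effects:", x$spec$random, "\n")
  invisible(x)
}
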