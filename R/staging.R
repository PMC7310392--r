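#' WHO immunological stage labels
#'
#' @return Character vector of the four stage labels, in code order
#'   (1 = normal ... 4 = severe).
#' @export
stage_labels <- function() c("normal", "mild", "advanced", "severe")

# CD4 band edges (cells/mm3), closed on the left:
# [500, Inf) -> 1, [350, 500) -> 2, [200, 350) -> 3, [0, 200) -> 4
.cd4_breaks <- c(0, 200, 350, 500, Inf)

#' Classify CD4 counts into WHO immunological stages
#'
#' Maps a CD4 cell count (cells/mm3) to the four-category WHO immunological
#' classification: normal (>= 500), mild (350-499), advanced (200-349) and
#' severe (< 200). Band boundaries are closed on the left, so a count of
#' exactly 350 is "mild" and 500 is "normal".
#'
#' @param cd4 numeric vector of CD4 counts; must be finite and non-negative.
#' @param labels if `TRUE`, return an ordered factor with labels from
#'   [stage_labels()]; otherwise integer codes 1..4.
#' @return Integer stage codes (1 best ... 4 worst), or an ordered factor.
#' @examples
#' who_stage(c(520, 350, 150))   # 1 2 4
#' @export
who_stage <- function(cd4, labels = FALSE) {
  if (anyNA(cd4) || any(!is.finite(cd4)))
    stop("cd4 must be finite and non-missing")
  if (any(cd4 < 0))
    stop("cd4 must be non-negative")
  code <- 4L - (findInterval(cd4, .cd4_breaks[2:4]))
  if (labels)
    factor(stage_labels()[code], levels = stage_labels(), ordered = TRUE)
  else code
}

# CD4 sampling intervals per stage used by the cohort generator: WHO bands,
# with the open ends capped at 1200 (top) and 50 (bottom) for realism.
.cd4_stage_lo <- c(500, 350, 200, 50)
.cd4_stage_hi <- c(1200, 500, 350, 200)

#' Draw CD4 counts consistent with given stages
#'
#' Inverse of [who_stage()] up to the band: draws a CD4 count uniformly
#' within the stage's band so that `who_stage(cd4_from_stage(s)) == s`.
#' The unbounded ends of the WHO bands are capped at 1200 (normal) and
#' 50 (severe).
#'
#' @param stage integer vector of stage codes 1..4.
#' @return Numeric CD4 counts (cells/mm3).
#' @export
cd4_from_stage <- function(stage) {
  if (any(!stage %in% 1:4)) stop("stage codes must be in 1..4")
  lo <- .cd4_stage_lo[stage]
  hi <- .cd4_stage_hi[stage]
  lo + runif(length(stage)) * (hi - lo) * 0.999999
}
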