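#' Latent-scale intraclass correlation
#'
#' Share of total latent variance attributable to subjects in a two-level
#' cumulative-logit model: `sigma2_v0 / (sigma2_v0 + pi^2/3)`, where the
#' level-one variance is that of the standard logistic distribution,
#' `pi^2/3`.
#'
#' @param sigma_v0_sq non-negative intercept variance (vectorized).
#' @return ICC in `[0, 1)`.
#' @examples
#' icc_latent(pi^2 / 3)   # 0.5
#' icc_latent(12.21)      # 0.7877
#' @export
icc_latent <- function(sigma_v0_sq) {
  if (anyNA(sigma_v0_sq) || any(sigma_v0_sq < 0))
    stop("sigma_v0_sq must be non-negative")
  sigma_v0_sq / (sigma_v0_sq + pi^2 / 3)
}
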