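## MCMC model configuration and validation.

#' Model configuration for the CAR prevalence model
#'
#' Collects the model variant, hyperprior values and MCMC controls.
#'
#' Variants: `"leroux"` (structured effect with free mixing parameter rho,
#' plus an unstructured iid effect), `"bym"` (ICAR structured effect,
#' rho fixed at 1, plus iid effect), `"icar_only"` (structured effect
#' only), `"iid_only"` (unstructured effect only). Gamma(shape, rate)
#' priors are placed on the precisions \eqn{1/\tau_u^2}, \eqn{1/\tau_v^2}
#' (equivalently inverse-gamma on the variances); the defaults
#' (1, 0.5) and (1, 0.01) are weakly informative, with the unstructured
#' prior flatter so it can absorb pure overdispersion.
#'
#' @param variant model variant, see Details.
#' @param alpha_u,beta_u gamma shape/rate for the structured precision.
#' @param alpha_v,beta_v gamma shape/rate for the unstructured precision.
#' @param beta_prior_sd zero-mean normal prior sd on the intercept and
#'   fixed effects (on the standardized-covariate scale).
#' @param n_iterations,burn_in,thinning MCMC schedule; retained draws are
#'   every `thinning`-th after `burn_in`.
#' @param seed RNG seed; identical seed + inputs give identical draws.
#' @param offset_enabled include a log-offset term in the linear predictor
#'   (relative-risk parameterization); off by default so the linear
#'   predictor is `alpha + X beta + u + v` on the logit-prevalence scale.
#' @return list of class `model_config`.
#' @export
model_config <- function(variant = c("leroux", "bym", "icar_only", "iid_only"),
                         alpha_u = 1, beta_u = 0.5,
                         alpha_v = 1, beta_v = 0.01,
                         beta_prior_sd = 10,
                         n_iterations = 50000, burn_in = 10000,
                         thinning = 10, seed = 1,
                         offset_enabled = FALSE) {
  variant <- match.arg(variant)
  stopifnot(alpha_u > 0, beta_u > 0, alpha_v > 0, beta_v > 0,
            beta_prior_sd > 0, thinning >= 1,
            n_iterations > burn_in, burn_in >= 0)
  structure(list(variant = variant,
                 alpha_u = alpha_u, beta_u = beta_u,
                 alpha_v = alpha_v, beta_v = beta_v,
                 beta_prior_sd = beta_prior_sd,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed),
                 offset_enabled = isTRUE(offset_enabled)),
            class = "model_config")
}

variant_has_u <- function(variant) variant != "iid_only"
variant_has_v <- function(variant) variant != "icar_only"
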