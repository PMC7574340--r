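## The two missing-data mechanisms: plug-in prediction for suppressed
## responses, and spatial imputation of missing area-level covariates.

#' Plug-in (out-of-sample) prevalence prediction for suppressed responses
#'
#' For a region whose response was suppressed but whose covariate is
#' observed, the prevalence is predicted from the fixed effects alone with
#' the random effects set to zero: per retained draw,
#' \eqn{p = logit^{-1}(\alpha + X_r^T \beta)}. The full posterior of the
#' fixed effects is used by default; `point_estimate = TRUE` plugs in
#' their posterior means instead (a single number, no interval).
#'
#' @param samples a `posterior_samples` object from [run_mcmc()].
#' @param x_row named numeric vector of the region's covariate values
#'   (same covariates the model was fitted with, original fitted scale).
#' @param conf credible level.
#' @param point_estimate use posterior-mean coefficients only.
#' @return one-row data frame `p_hat`, `sd`, `ci_low`, `ci_high`, `cv`,
#'   `provenance = "plug-in"`.
#' @export
predict_out_of_sample <- function(samples, x_row, conf = 0.95,
                                  point_estimate = FALSE) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (anyNA(x_row))
    stop("covariate missing for this region: impute_covariate first ",
         "(plug-in prediction is the missing-response mechanism)")
  xr <- c(1, as.numeric(x_row[samples$covariates]))
  if (anyNA(xr)) stop("x_row must name the fitted covariates: ",
                      paste(samples$covariates, collapse = ", "))
  if (point_estimate) {
    p <- plogis(sum(colMeans(samples$beta) * xr))
    out <- data.frame(p_hat = p, sd = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, cv = NA_real_,
                      provenance = "plug-in", stringsAsFactors = FALSE)
    return(out)
  }
  p <- plogis(as.vector(samples$beta %*% xr))
  a <- (1 - conf) / 2
  q <- quantile(p, c(a, 1 - a), names = FALSE)
  pm <- mean(p)
  psd <- sd(p)
  data.frame(p_hat = pm, sd = psd, ci_low = q[1], ci_high = q[2],
             cv = coefficient_of_variation(pm, psd),
             provenance = "plug-in", stringsAsFactors = FALSE)
}

#' Spatial imputation of a missing area-level covariate
#'
#' Missing scores are replaced by the posterior-mean surface of a Gaussian
#' BYM smoother ([gaussian_car_smooth()]) fitted to the observed scores;
#' observed entries pass through unchanged. The completed vector can then
#' be plugged into the prevalence model. Imputation uncertainty is not
#' propagated (posterior mean plugged in); `draws = TRUE` additionally
#' returns the smoother's posterior sd at the imputed regions for
#' sensitivity analysis.
#'
#' @param scores numeric vector over the graph's regions with `NA` where
#'   missing.
#' @param graph a [region_graph()].
#' @param config smoother [model_config()] (see [gaussian_car_smooth()]).
#' @param draws also return imputation sd.
#' @return list with `scores` (completed vector), `imputed` (logical
#'   flags) and, when `draws`, `imputation_sd`.
#' @export
impute_covariate <- function(scores, graph,
                             config = model_config(n_iterations = 6000,
                                                   burn_in = 1000,
                                                   thinning = 5),
                             draws = FALSE) {
  miss <- is.na(scores)
  if (all(miss)) stop("all scores missing; nothing to smooth from")
  if (!any(miss)) {
    out <- list(scores = scores, imputed = miss)
    if (draws) out$imputation_sd <- rep(NA_real_, length(scores))
    return(out)
  }
  sm <- gaussian_car_smooth(scores, graph, config)
  completed <- scores
  completed[miss] <- sm$mean[miss]
  out <- list(scores = completed, imputed = miss)
  if (draws) {
    isd <- rep(NA_real_, length(scores))
    isd[miss] <- sm$sd[miss]
    out$imputation_sd <- isd
  }
  out
}
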