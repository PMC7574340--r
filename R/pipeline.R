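## End-to-end small-area estimation: direct estimates, covariate
## imputation, model fit, plug-in prediction, and the comparison report.

#' Run the full small-area estimation pipeline
#'
#' Sequences the whole analysis on a region dataset: (1) direct estimates
#' with the reporting suppression rule; (2) spatial imputation of missing
#' covariates via the Gaussian BYM smoother; (3) the binomial CAR model
#' fitted by MCMC, with suppressed responses treated as missing; (4)
#' posterior prevalence summaries, with suppressed-response regions
#' replaced by the plug-in predictor (fixed effects only, random effects
#' zero); (5) the model-vs-direct comparison report. Every region
#' receives an estimate with a provenance tag (`fitted`, `plug-in`, or
#' `imputed-covariate`).
#'
#' @param data region data frame: `region_id`, `N`, `y`, `score` (the
#'   raw covariate; NA where missing). `y` may already be NA for
#'   suppressed regions.
#' @param graph a [region_graph()] over exactly these regions, with no
#'   isolated regions.
#' @param config a [model_config()].
#' @param suppression_minimum reporting minimum for the direct estimates.
#' @param smooth_config [model_config()] for the covariate smoother.
#' @return list of class `sae_fit`: `direct` (direct estimates), `model`
#'   (small-area estimates for every region), `samples` (posterior
#'   draws), `comparison` ([comparison_report()]), `imputed_score`
#'   (completed covariate), `standardization` (center/scale).
#' @export
sae_pipeline <- function(data, graph, config = model_config(),
                         suppression_minimum = 15,
                         smooth_config = model_config(n_iterations = 6000,
                                                      burn_in = 1000,
                                                      thinning = 5,
                                                      seed = config$seed)) {
  stopifnot(inherits(graph, "region_graph"))
  ord <- match(graph$region_ids, as.character(data$region_id))
  if (anyNA(ord)) stop("data rows missing for some graph regions")
  data <- data[ord, , drop = FALSE]

  direct <- direct_prevalence(
    ifelse(is.na(data$y), 0, data$y), data$N,
    region_id = data$region_id,
    suppression_minimum = suppression_minimum)
  # regions whose y arrived already masked are missing responses too
  direct$suppressed <- direct$suppressed | is.na(data$y)
  est_cols <- c("p_hat", "se", "cv", "ci_low", "ci_high")
  direct[direct$suppressed, est_cols] <- NA_real_

  imp <- impute_covariate(data$score, graph, smooth_config)
  std <- standardize(imp$scores)
  fit_data <- data.frame(region_id = data$region_id, N = data$N,
                         y = ifelse(direct$suppressed, NA, data$y),
                         x = std$z, stringsAsFactors = FALSE)

  samples <- run_mcmc(fit_data, graph, config, covariates = "x")
  model <- posterior_prevalence(samples)
  model$provenance[imp$imputed] <- "imputed-covariate"

  # missing-response mechanism: plug-in prediction with u = v = 0
  for (r in which(direct$suppressed)) {
    pin <- predict_out_of_sample(samples, c(x = std$z[r]))
    model[r, c("p_hat", "sd", "ci_low", "ci_high", "cv")] <-
      pin[, c("p_hat", "sd", "ci_low", "ci_high", "cv")]
    model$provenance[r] <- "plug-in"
  }

  structure(list(direct = direct, model = model, samples = samples,
                 comparison = comparison_report(direct, model),
                 imputed_score = imp$scores,
                 standardization = std[c("center", "scale")]),
            class = "sae_fit")
}

#' @export
print.sae_fit <- function(x, ...) {
  cat("sae_fit:", nrow(x$model), "regions (",
      sum(x$model$provenance == "fitted"), "fitted,",
      sum(x$model$provenance == "plug-in"), "plug-in,",
      sum(x$model$provenance == "imputed-covariate"), "imputed-covariate )\n")
  print(x$comparison)
  invisible(x)
}
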