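## Comparison of model-based and direct estimates, model checking,
## and map-ready binned outputs.

#' Coefficient-of-variation improvement
#'
#' The difference of the percent CVs, direct minus model-based
#' (\eqn{CV^o - CV^e}), in percentage points: the precision gained by
#' spatial pooling. Positive values mean the model-based estimate is the
#' more precise one. Undefined (NA) where either CV is missing; such
#' regions are excluded, never zero-filled.
#'
#' @param cv_direct,cv_model percent CVs.
#' @return percentage-point differences, vectorized.
#' @export
cv_difference <- function(cv_direct, cv_model) {
  ifelse(is.na(cv_direct) | is.na(cv_model), NA_real_, cv_direct - cv_model)
}

#' Percent relative bias of the direct estimate against the model
#'
#' \eqn{(\hat p^e - \hat p^o) / \hat p^e \times 100\%}: positive values
#' mean the direct estimate under-estimates the prevalence, negative that
#' it over-estimates.
#'
#' @param p_model model-based estimates (> 0 where defined).
#' @param p_direct direct estimates.
#' @return signed percent, NA where the model estimate is 0 or missing.
#' @export
relative_bias <- function(p_model, p_direct) {
  ifelse(is.na(p_model) | is.na(p_direct) | p_model == 0, NA_real_,
         (p_model - p_direct) / p_model * 100)
}

#' Quantile bins for map display
#'
#' Assigns each defined value to one of `length(percentiles) + 1` ordered
#' bins with cutpoints at the given percentiles of the defined values
#' (default 20/40/60/80, the usual five-class choropleth scale).
#' Percentiles use linear interpolation between order statistics; values
#' exactly on a cutpoint go to the lower bin (left-closed bins except the
#' first). Degenerate (duplicated) cutpoints collapse bins, with a warning.
#'
#' @param values numeric vector; NAs are passed through as NA bins.
#' @param percentiles cutpoint percentiles in (0, 100).
#' @return list with `bins` (ordered factor), `cutpoints`, and
#'   `n_defined`.
#' @export
quantile_bins <- function(values, percentiles = c(20, 40, 60, 80)) {
  ok <- !is.na(values)
  if (sum(ok) < length(percentiles) + 1)
    stop("too few defined values (need at least ",
         length(percentiles) + 1, ")")
  cut_pts <- quantile(values[ok], probs = percentiles / 100, names = FALSE)
  uniq <- unique(cut_pts)
  if (length(uniq) < length(cut_pts))
    warning("degenerate cutpoints collapsed (tied percentiles)")
  breaks <- c(-Inf, uniq, Inf)
  bins <- cut(values, breaks = breaks, right = TRUE, ordered_result = TRUE)
  list(bins = bins, cutpoints = cut_pts, n_defined = sum(ok))
}

#' Normality check of posterior-mean random effects
#'
#' Measures the straightness of the normal q-q plot of the effect vector:
#' the correlation between the ordered effects and the corresponding
#' standard normal quantiles (values near 1 indicate the effects are
#' consistent with a normal distribution; materially lower values flag
#' skewness or heavy tails).
#'
#' @param effects numeric vector of posterior-mean effects (>= 10 values).
#' @return list with `score` (correlation in \[-1, 1\], NA if degenerate),
#'   `theoretical` and `ordered` (the q-q pairs for plotting), and
#'   `degenerate` flag.
#' @export
random_effect_normality <- function(effects) {
  effects <- effects[!is.na(effects)]
  n <- length(effects)
  if (n < 10) stop("need at least 10 effects for a q-q diagnostic")
  o <- sort(effects)
  q <- qnorm(ppoints(n))
  if (sd(o) == 0)
    return(list(score = NA_real_, theoretical = q, ordered = o,
                degenerate = TRUE))
  list(score = cor(q, o), theoretical = q, ordered = o, degenerate = FALSE)
}

#' Build the model-vs-direct comparison report
#'
#' Joins direct and model-based estimates by region, computes the CV
#' difference and relative bias, attaches quantile-bin labels for both,
#' and lists the regions excluded from comparison (those without a direct
#' estimate: suppressed or no-sample regions).
#'
#' @param direct a `direct_estimates` data frame ([direct_prevalence()]).
#' @param model a `small_area_estimates` data frame
#'   ([posterior_prevalence()] or the pipeline).
#' @param percentiles bin cutpoint percentiles (see [quantile_bins()]).
#' @return list of class `comparison_report`: `table` (per-region metrics
#'   and bins) and `excluded_ids`.
#' @export
comparison_report <- function(direct, model,
                              percentiles = c(20, 40, 60, 80)) {
  m <- match(direct$region_id, model$region_id)
  if (anyNA(m)) stop("model estimates missing for some regions")
  tab <- data.frame(
    region_id = direct$region_id,
    N = direct$N,
    p_direct = direct$p_hat, cv_direct = direct$cv,
    p_model = model$p_hat[m], cv_model = model$cv[m],
    provenance = model$provenance[m],
    stringsAsFactors = FALSE)
  tab$cv_difference <- cv_difference(tab$cv_direct, tab$cv_model)
  tab$relative_bias <- relative_bias(tab$p_model, tab$p_direct)
  tab$cv_difference_bin <- tryCatch(
    quantile_bins(tab$cv_difference, percentiles)$bins,
    error = function(e) factor(rep(NA, nrow(tab))))
  tab$relative_bias_bin <- tryCatch(
    quantile_bins(tab$relative_bias, percentiles)$bins,
    error = function(e) factor(rep(NA, nrow(tab))))
  excluded <- tab$region_id[is.na(tab$p_direct)]
  structure(list(table = tab, excluded_ids = excluded),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  ok <- !is.na(x$table$cv_difference)
  cat("comparison_report:", nrow(x$table), "regions,",
      length(x$excluded_ids), "excluded from comparison\n")
  if (any(ok)) {
    cat(sprintf("mean CV improvement: %.2f points; mean relative bias: %.2f%%\n",
                mean(x$table$cv_difference[ok]),
                mean(x$table$relative_bias[ok], na.rm = TRUE)))
  }
  invisible(x)
}

#' Prior sensitivity refits
#'
#' Refits the model under alternative hyperprior settings and reports the
#' maximum absolute change in posterior prevalence means across regions,
#' relative to the baseline configuration.
#'
#' @param data,graph,config as in [run_mcmc()].
#' @param alternate_priors list of named lists of [model_config()]
#'   arguments to override (e.g. `list(list(beta_v = 0.1))`).
#' @param covariates covariate column names.
#' @return data frame with one row per setting: the overridden values and
#'   `max_abs_change` in posterior prevalence means.
#' @export
sensitivity_refit <- function(data, graph, config, alternate_priors,
                              covariates = "x") {
  base <- posterior_prevalence(run_mcmc(data, graph, config, covariates))
  rows <- lapply(seq_along(alternate_priors), function(i) {
    ov <- alternate_priors[[i]]
    args <- modifyList(unclass(config), ov)
    cfg <- do.call(model_config, args)
    est <- posterior_prevalence(run_mcmc(data, graph, cfg, covariates))
    data.frame(setting = i,
               overrides = paste(names(ov), unlist(ov), sep = "=",
                                 collapse = ", "),
               max_abs_change = max(abs(est$p_hat - base$p_hat)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
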