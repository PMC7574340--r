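## Direct (crude) prevalence estimation and the reporting suppression rule.

#' Direct prevalence estimates with binomial uncertainty
#'
#' The direct estimate for region r is the crude proportion
#' \eqn{\hat p_r = y_r / N_r} with binomial standard error
#' \eqn{\sqrt{\hat p (1-\hat p)/N}}, a normal-approximation 95% interval
#' truncated to \[0, 1\] (Wilson intervals available via `interval`),
#' and the percent coefficient of variation \eqn{se/\hat p \times 100}.
#' No pooling across regions takes place.
#'
#' @param y vector of event counts per region.
#' @param N vector of totals per region (children assessed).
#' @param region_id optional identifiers.
#' @param conf confidence level (default 0.95).
#' @param interval `"normal"` (default) or `"wilson"`.
#' @param suppression_minimum totals below this are suppressed (flagged,
#'   estimates withheld); the default 15 mirrors common reporting minima
#'   for small-count census collections. Use 0 to disable.
#' @return data frame of class `direct_estimates`: `region_id`, `N`, `y`,
#'   `p_hat`, `se`, `cv` (percent, NA where \eqn{\hat p = 0} or suppressed),
#'   `ci_low`, `ci_high`, `no_sample` (N = 0), `suppressed`. Suppressed
#'   regions are retained as rows with NA estimates, never dropped.
#' @export
direct_prevalence <- function(y, N, region_id = NULL, conf = 0.95,
                              interval = c("normal", "wilson"),
                              suppression_minimum = 15) {
  interval <- match.arg(interval)
  if (length(y) != length(N)) stop("y and N must have equal length")
  if (any(N < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE))
    stop("negative counts")
  if (any(y > N, na.rm = TRUE)) stop("y > N for some region")
  if (is.null(region_id)) region_id <- as.character(seq_along(y))
  n <- length(y)

  p <- ifelse(N > 0, y / N, NA_real_)
  se <- ifelse(N > 0, sqrt(p * (1 - p) / N), NA_real_)
  z <- qnorm(1 - (1 - conf) / 2)
  if (interval == "normal") {
    lo <- pmax(p - z * se, 0)
    hi <- pmin(p + z * se, 1)
  } else {
    den <- 1 + z^2 / N
    mid <- (p + z^2 / (2 * N)) / den
    half <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / den
    lo <- pmax(mid - half, 0)
    hi <- pmin(mid + half, 1)
  }
  cv <- coefficient_of_variation(p, se)

  suppressed <- apply_suppression(N, minimum = suppression_minimum)
  out <- data.frame(region_id = as.character(region_id), N = N, y = y,
                    p_hat = p, se = se, cv = cv, ci_low = lo, ci_high = hi,
                    no_sample = is.na(p), suppressed = suppressed,
                    stringsAsFactors = FALSE)
  # suppressed regions carry no estimate
  est_cols <- c("p_hat", "se", "cv", "ci_low", "ci_high")
  out[out$suppressed, est_cols] <- NA_real_
  class(out) <- c("direct_estimates", "data.frame")
  out
}

#' Percent coefficient of variation
#'
#' \eqn{CV = \sigma / \hat p \times 100\%}: the spread of an estimate
#' relative to its level, the standard precision metric for small-area
#' estimates. Undefined (NA) where the estimate is zero.
#'
#' @param p_hat estimate(s), proportion scale.
#' @param sigma standard error / posterior standard deviation.
#' @return percent CV, vectorized; NA where `p_hat` is 0 or missing.
#' @export
coefficient_of_variation <- function(p_hat, sigma) {
  ifelse(!is.na(p_hat) & p_hat > 0, sigma / p_hat * 100, NA_real_)
}

#' Reporting suppression rule
#'
#' Regions whose assessed count falls below the reporting minimum have
#' their responses suppressed for confidentiality; downstream they are
#' treated as missing responses (the model predicts them out-of-sample).
#'
#' @param N vector of assessed counts.
#' @param minimum reporting minimum (default 15); counts strictly below
#'   it are suppressed.
#' @return logical vector of suppression flags.
#' @export
apply_suppression <- function(N, minimum = 15) {
  if (any(N < 0, na.rm = TRUE)) stop("negative counts")
  N < minimum
}
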