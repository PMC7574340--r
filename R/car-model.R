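## The Bayesian hierarchical model: binomial logistic GLMM with Leroux/ICAR
## structured plus unstructured random effects, fitted by Metropolis-within-
## Gibbs (C++ backend), and a Gaussian BYM smoother for covariate imputation.

#' CAR full-conditional mean and variance for one region
#'
#' Under the intrinsic CAR prior, the structured effect of region j given
#' its neighbours is normal with mean the neighbour average and variance
#' \eqn{\tau_u^2 / d_j} where \eqn{d_j} is the neighbour count. The Leroux
#' extension mixes towards independence with parameter \eqn{\rho}:
#' mean \eqn{\rho \sum_i u_i w_{ji} / (\rho d_j + 1 - \rho)} and variance
#' \eqn{\tau_u^2 / (\rho d_j + 1 - \rho)}; \eqn{\rho = 1} recovers the ICAR
#' formulas, \eqn{\rho = 0} gives independent N(0, \eqn{\tau_u^2}) effects.
#'
#' @param u vector of current structured effects (all regions).
#' @param j region index (1-based).
#' @param graph a [region_graph()].
#' @param tau2_u structured variance.
#' @param rho mixing parameter in \[0, 1\] (1 = ICAR).
#' @return list with `mean` and `variance`.
#' @export
car_full_conditional <- function(u, j, graph, tau2_u, rho = 1) {
  stopifnot(inherits(graph, "region_graph"), length(u) == n_regions(graph),
            rho >= 0, rho <= 1, tau2_u > 0)
  d <- graph$neighbor_counts[j]
  if (rho == 1 && d == 0)
    stop("ICAR full conditional undefined for isolated region ",
         graph$region_ids[j])
  S <- sum(u * graph$W[j, ])
  denom <- rho * d + (1 - rho)
  list(mean = rho * S / denom, variance = tau2_u / denom)
}

#' Joint log posterior of the model state (up to an additive constant)
#'
#' Sums the binomial log likelihood over regions with observed responses,
#' the CAR (Leroux/ICAR) log prior for the structured effects, the iid
#' normal log prior for the unstructured effects, the normal prior for the
#' fixed effects, and the gamma hyperpriors on the precisions. Used for
#' sampler validation; the sampler itself works with conditional ratios.
#'
#' @param state list with `beta` (includes the intercept first), `u`, `v`,
#'   `tau2_u`, `tau2_v`, `rho`.
#' @param data region data frame with columns `N`, `y` (NA = missing
#'   response) and the covariate columns.
#' @param graph a [region_graph()].
#' @param config a [model_config()].
#' @param covariates names of covariate columns in `data`.
#' @return scalar log posterior (finite for interior states).
#' @export
log_posterior <- function(state, data, graph, config, covariates = "x") {
  n <- n_regions(graph)
  X <- model_matrix(data, covariates)
  if (any(!is.finite(X))) stop("non-finite covariate")
  off <- linear_offset(data, config, n)
  eta <- off + as.vector(X %*% state$beta) + state$u + state$v
  obs <- !is.na(data$y) & data$N > 0

  e <- eta[obs]
  lse <- ifelse(e > 0, e + log1p(exp(-e)), log1p(exp(e))) # stable log(1+e^eta)
  lp <- sum(data$y[obs] * e - data$N[obs] * lse)

  W <- graph$W
  d <- graph$neighbor_counts
  rho <- state$rho
  if (variant_has_u(config$variant)) {
    # Leroux/ICAR prior: -Q(u)/(2 tau_u^2) - (n*/2) log tau_u^2 (+ log det part,
    # constant in u and tau_u^2 given rho; included via eigenvalues for rho)
    Qpair <- sum((outer(state$u, state$u, "-")^2 * W)) / 2
    Q <- rho * Qpair + (1 - rho) * sum(state$u^2)
    nstar <- if (config$variant == "leroux") n else n - max(graph_components(graph))
    lam <- laplacian_eigenvalues(graph)
    logdet <- if (config$variant == "leroux")
      sum(log(rho * lam + 1 - rho)) else 0
    lp <- lp - Q / (2 * state$tau2_u) - nstar / 2 * log(state$tau2_u) +
      logdet / 2
    # gamma(alpha_u, beta_u) on the precision 1/tau2_u
    lp <- lp + (config$alpha_u - 1) * log(1 / state$tau2_u) -
      config$beta_u / state$tau2_u - 2 * log(state$tau2_u)
  }
  if (variant_has_v(config$variant)) {
    lp <- lp - sum(state$v^2) / (2 * state$tau2_v) -
      n / 2 * log(state$tau2_v)
    lp <- lp + (config$alpha_v - 1) * log(1 / state$tau2_v) -
      config$beta_v / state$tau2_v - 2 * log(state$tau2_v)
  }
  lp <- lp - sum(state$beta^2) / (2 * config$beta_prior_sd^2)
  lp
}

model_matrix <- function(data, covariates) {
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (length(covariates)) {
    Xc <- as.matrix(data[, covariates, drop = FALSE])
    storage.mode(Xc) <- "double"
    X <- cbind(X, Xc)
  }
  X
}

linear_offset <- function(data, config, n) {
  if (isTRUE(config$offset_enabled)) {
    if (is.null(data$offset)) stop("offset_enabled but no offset column")
    log(data$offset)
  } else rep(0, n)
}

laplacian_eigenvalues <- function(graph) {
  L <- diag(graph$neighbor_counts) - graph$W
  eigen(L, symmetric = TRUE, only.values = TRUE)$values
}

#' Fit the CAR prevalence model by Metropolis-within-Gibbs MCMC
#'
#' Binomial likelihood \eqn{y_r \sim Bin(N_r, p_r)} with
#' \eqn{logit(p_r) = \alpha + X_r^T \beta + u_r + v_r} (plus an optional
#' log offset), Leroux/ICAR prior on the structured effects u, iid normal
#' on v, gamma priors on the precisions, uniform(0, 1) on the Leroux
#' \eqn{\rho}. Sampling: adaptive random-walk Metropolis for the fixed
#' effects and each \eqn{u_r}, \eqn{v_r} (step sizes tuned during burn-in
#' only), conjugate inverse-gamma Gibbs draws for the variances, and
#' Metropolis on \eqn{logit(\rho)}. ICAR effects are re-centred to sum to
#' zero each sweep, with the shift absorbed by the intercept.
#'
#' Regions with `NA` responses (suppressed counts) or `N = 0` contribute
#' no likelihood term; their random effects are drawn from the prior
#' conditionals, keeping the graph intact.
#'
#' @param data data frame with columns `region_id`, `N`, `y` (NA allowed),
#'   the covariate columns, and optionally `offset`. Rows must cover
#'   exactly the graph's regions (matched by `region_id`).
#' @param graph a [region_graph()]; for ICAR-based variants it must have
#'   no isolated regions (see [find_and_remove_isolated()]).
#' @param config a [model_config()].
#' @param covariates names of covariate columns (default `"x"`).
#' @return object of class `posterior_samples`: matrices `beta`
#'   (draws x coefficients), `u`, `v` (draws x regions), vectors `tau2_u`,
#'   `tau2_v`, `rho`, acceptance rates, and the inputs needed to form
#'   prevalence draws.
#' @seealso [posterior_prevalence()]
#' @export
run_mcmc <- function(data, graph, config = model_config(),
                     covariates = "x") {
  stopifnot(inherits(graph, "region_graph"), inherits(config, "model_config"))
  ord <- match(graph$region_ids, as.character(data$region_id))
  if (anyNA(ord))
    stop("data rows missing for regions: ",
         paste(setdiff(graph$region_ids, data$region_id), collapse = ", "))
  data <- data[ord, , drop = FALSE]
  if (any(data$N < 0)) stop("negative N")
  if (any(!is.na(data$y) & (data$y < 0 | data$y > data$N)))
    stop("invalid counts: need 0 <= y <= N")
  if (!any(!is.na(data$y) & data$N > 0))
    stop("no region with an observed response")

  n <- n_regions(graph)
  has_u <- variant_has_u(config$variant)
  has_v <- variant_has_v(config$variant)
  rho_free <- config$variant == "leroux"
  if (has_u && !rho_free && any(graph$neighbor_counts == 0))
    stop("graph has isolated regions; ICAR prior undefined ",
         "(remove them with find_and_remove_isolated)")

  X <- model_matrix(data, covariates)
  if (any(!is.finite(X))) stop("non-finite covariate")
  off <- linear_offset(data, config, n)
  lam <- if (has_u && rho_free) laplacian_eigenvalues(graph) else numeric(n)
  comp <- graph_components(graph)
  nstar_icar <- n - max(comp)
  adj0 <- lapply(neighbor_list(graph), function(ix) as.integer(ix - 1L))

  y <- as.numeric(data$y)
  y[data$N == 0] <- NA_real_

  set.seed(config$seed)
  raw <- cpp_binomial_car_mcmc(
    y, as.numeric(data$N), X, adj0,
    config$alpha_u, config$beta_u, config$alpha_v, config$beta_v,
    config$beta_prior_sd, off, lam,
    has_u, has_v, rho_free,
    0.5, as.integer(nstar_icar),
    config$n_iterations, config$burn_in, config$thinning)

  colnames(raw$beta) <- colnames(X)
  colnames(raw$u) <- colnames(raw$v) <- graph$region_ids
  structure(list(
    beta = raw$beta, u = raw$u, v = raw$v,
    tau2_u = raw$tau2_u, tau2_v = raw$tau2_v, rho = raw$rho,
    acceptance = raw$acceptance, n_kept = raw$n_kept,
    region_ids = graph$region_ids, X = X, offset = off,
    covariates = covariates, config = config
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", x$n_kept, "retained draws,",
      length(x$region_ids), "regions, variant", x$config$variant, "\n")
  cat("acceptance rates:",
      paste(names(x$acceptance), round(x$acceptance, 2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Small-area prevalence estimates from posterior draws
#'
#' For each retained draw the region prevalence is the inverse logit of
#' the linear predictor \eqn{\alpha + X_r^T\beta + u_r + v_r}; the draws
#' are summarised by posterior mean, sd, equal-tailed 95% credible
#' interval, and the percent coefficient of variation.
#'
#' @param samples a `posterior_samples` object from [run_mcmc()].
#' @param conf credible level (default 0.95).
#' @return data frame of class `small_area_estimates`: `region_id`,
#'   `p_hat`, `sd`, `ci_low`, `ci_high`, `cv`, `provenance` (all
#'   `"fitted"` here; the pipeline overwrites plug-in / imputed rows).
#' @export
posterior_prevalence <- function(samples, conf = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"))
  eta <- samples$beta %*% t(samples$X) # draws x regions
  eta <- sweep(eta, 2, samples$offset, "+")
  if (ncol(samples$u)) eta <- eta + samples$u
  if (ncol(samples$v)) eta <- eta + samples$v
  p <- plogis(eta)
  a <- (1 - conf) / 2
  qs <- apply(p, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  pm <- colMeans(p)
  psd <- apply(p, 2, sd)
  out <- data.frame(
    region_id = samples$region_ids,
    p_hat = pm, sd = psd,
    ci_low = qs[1, ], ci_high = qs[2, ],
    cv = coefficient_of_variation(pm, psd),
    provenance = "fitted", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("small_area_estimates", "data.frame")
  out
}

#' Gaussian BYM spatial smoother
#'
#' Fits intercept + ICAR structured + iid unstructured random effects with
#' a Gaussian likelihood to the observed entries of a continuous areal
#' field (all conjugate Gibbs updates), and returns the posterior-mean
#' smoothed surface over every region, including those with missing
#' values. This is the smoother behind [impute_covariate()]. Fitting is
#' done on the standardized scale and back-transformed.
#'
#' @param values numeric vector over the graph's regions, `NA` where
#'   missing; at least 2 observed.
#' @param graph a [region_graph()] with no isolated regions.
#' @param config a [model_config()] supplying hyperpriors, MCMC schedule
#'   and seed (variant is ignored; the smoother is always BYM). The
#'   default schedule is shorter than the binomial model's because every
#'   update is conjugate.
#' @return list with `mean` and `sd` vectors (original scale) plus draws
#'   of the variance parameters.
#' @export
gaussian_car_smooth <- function(values, graph,
                                config = model_config(n_iterations = 6000,
                                                      burn_in = 1000,
                                                      thinning = 5)) {
  stopifnot(inherits(graph, "region_graph"))
  n <- n_regions(graph)
  if (length(values) != n) stop("values length must match graph")
  obs <- !is.na(values)
  if (sum(obs) < 2) stop("need at least 2 observed values to smooth")
  if (any(graph$neighbor_counts == 0))
    stop("graph has isolated regions; ICAR smoother undefined")

  ctr <- mean(values[obs])
  scl <- sd(values[obs])
  if (scl == 0) scl <- 1 # constant field: smooth on the centred scale
  z <- (values - ctr) / scl

  comp <- graph_components(graph)
  adj0 <- lapply(neighbor_list(graph), function(ix) as.integer(ix - 1L))
  set.seed(config$seed)
  raw <- cpp_gaussian_bym_mcmc(
    z, adj0,
    config$alpha_u, config$beta_u, config$alpha_v, config$beta_v,
    1, 0.01, # weak gamma prior on the error precision
    10, as.integer(n - max(comp)),
    config$n_iterations, config$burn_in, config$thinning)

  list(mean = raw$mean * scl + ctr, sd = raw$sd * scl,
       tau2_u = raw$tau2_u * scl^2, tau2_v = raw$tau2_v * scl^2,
       sigma2_e = raw$sigma2_e * scl^2, n_kept = raw$n_kept)
}
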