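test_that("CAR full conditional reproduces the conditional mean and variance formulas", {
  g <- path_graph(4)
  # all neighbours equal c: conditional mean is c under ICAR
  u <- c(3, 5, 3, 1)
  fc <- car_full_conditional(u, 3, g, tau2_u = 1, rho = 1)
  expect_equal(fc$mean, 3)

  # degree 2, neighbour values (1, 3), tau2 = 2: mean 2, variance 1
  u2 <- c(1, 0, 3, 0)
  fc2 <- car_full_conditional(u2, 2, g, tau2_u = 2, rho = 1)
  expect_equal(fc2$mean, 2)
  expect_equal(fc2$variance, 1)

  # rho = 0: independence limit, mean 0 and variance tau2
  fc0 <- car_full_conditional(u2, 2, g, tau2_u = 2, rho = 0)
  expect_equal(fc0$mean, 0)
  expect_equal(fc0$variance, 2)

  # isolated region has no ICAR conditional
  iso <- adjacency_from_edges(1:3, cbind(1, 2))
  expect_error(car_full_conditional(c(0, 0, 0), 3, iso, 1, rho = 1),
               "isolated")
})

test_that("Leroux conditional interpolates continuously between independence and ICAR", {
  g <- grid_graph(3, 3)
  set.seed(9)
  u <- rnorm(9)
  for (j in c(1, 5)) {
    d <- g$neighbor_counts[j]
    S <- sum(u[g$W[j, ] == 1])
    # exact algebra at the endpoints
    ic <- car_full_conditional(u, j, g, 1.7, rho = 1)
    expect_identical(ic$mean, S / d)
    expect_identical(ic$variance, 1.7 / d)
    id <- car_full_conditional(u, j, g, 1.7, rho = 0)
    expect_identical(id$mean, 0)
    expect_identical(id$variance, 1.7)
    # continuity: a fine rho grid has no jumps
    rhos <- seq(0, 1, by = 0.02)
    ms <- vapply(rhos, function(r)
      car_full_conditional(u, j, g, 1.7, r)$mean, numeric(1))
    vs <- vapply(rhos, function(r)
      car_full_conditional(u, j, g, 1.7, r)$variance, numeric(1))
    expect_lt(max(abs(diff(ms))), 0.3)
    expect_lt(max(abs(diff(vs))), 0.3)
  }
})

test_that("log posterior agrees with an independently coded term-by-term sum", {
  g <- path_graph(3)
  data <- data.frame(region_id = 1:3, N = c(50, 80, 20), y = c(4, 9, 1),
                     x = c(-1, 0, 1))
  cfg <- model_config(variant = "bym", n_iterations = 100, burn_in = 10,
                      thinning = 1)
  state <- list(beta = c(-2, 0.3), u = c(0.1, -0.2, 0.1),
                v = c(0.05, 0, -0.05), tau2_u = 0.3, tau2_v = 0.1, rho = 1)

  # oracle: enumerate every term directly from the model definition
  eta <- state$beta[1] + state$beta[2] * data$x + state$u + state$v
  ll <- sum(dbinom(data$y, data$N, plogis(eta), log = TRUE))
  Wg <- g$W
  prior_u <- -icar_pairsum(state$u, Wg) / (2 * state$tau2_u) -
    (3 - 1) / 2 * log(state$tau2_u)
  prior_v <- sum(dnorm(state$v, 0, sqrt(state$tau2_v), log = TRUE))
  prior_b <- sum(dnorm(state$beta, 0, cfg$beta_prior_sd, log = TRUE))
  hyper <- dgamma(1 / state$tau2_u, cfg$alpha_u, rate = cfg$beta_u, log = TRUE) +
    log(1 / state$tau2_u^2) +
    dgamma(1 / state$tau2_v, cfg$alpha_v, rate = cfg$beta_v, log = TRUE) +
    log(1 / state$tau2_v^2)
  oracle <- ll + prior_u + prior_v + prior_b + hyper

  lp <- log_posterior(state, data, g, cfg, covariates = "x")
  # both are defined up to additive constants; compare differences between
  # two states so constants cancel
  state2 <- state
  state2$u <- c(-0.3, 0.2, 0.1)
  state2$tau2_u <- 0.5
  eta2 <- state$beta[1] + state$beta[2] * data$x + state2$u + state$v
  ll2 <- sum(dbinom(data$y, data$N, plogis(eta2), log = TRUE))
  prior_u2 <- -icar_pairsum(state2$u, Wg) / (2 * state2$tau2_u) -
    (3 - 1) / 2 * log(state2$tau2_u)
  hyper2 <- dgamma(1 / state2$tau2_u, cfg$alpha_u, rate = cfg$beta_u,
                   log = TRUE) + log(1 / state2$tau2_u^2) +
    dgamma(1 / state$tau2_v, cfg$alpha_v, rate = cfg$beta_v, log = TRUE) +
    log(1 / state$tau2_v^2)
  oracle2 <- ll2 + prior_u2 + prior_v + prior_b + hyper2
  lp2 <- log_posterior(state2, data, g, cfg, covariates = "x")
  expect_equal(lp - lp2, oracle - oracle2, tolerance = 1e-10)
})

test_that("log posterior sharpens with doubled counts and ignores rho at u = 0", {
  g <- grid_graph(3, 3)
  data <- data.frame(region_id = 1:9, N = rep(100, 9), x = rnorm(9))
  set.seed(2)
  data$y <- rbinom(9, data$N, 0.1)
  cfg <- model_config(variant = "leroux", n_iterations = 100, burn_in = 10,
                      thinning = 1)
  at <- function(b0, dat) log_posterior(
    list(beta = c(b0, 0), u = rep(0, 9), v = rep(0, 9),
         tau2_u = 0.2, tau2_v = 0.1, rho = 0.5), dat, g, cfg, "x")
  phat <- sum(data$y) / sum(data$N)
  b_mode <- qlogis(phat)
  doubled <- data
  doubled$N <- 2 * data$N
  doubled$y <- 2 * data$y
  # likelihood curvature doubles: the drop away from the mode is larger
  drop1 <- at(b_mode, data) - at(b_mode + 0.5, data)
  drop2 <- at(b_mode, doubled) - at(b_mode + 0.5, doubled)
  expect_gt(drop2, drop1)

  # with u = 0 the CAR quadratic form vanishes: only the Leroux log
  # determinant depends on rho
  st <- function(rho) list(beta = c(-2, 0), u = rep(0, 9), v = rep(0, 9),
                           tau2_u = 0.2, tau2_v = 0.1, rho = rho)
  lam <- eigen(diag(g$neighbor_counts) - g$W, symmetric = TRUE,
               only.values = TRUE)$values
  ld <- function(r) sum(log(r * lam + 1 - r)) / 2
  expect_equal(
    log_posterior(st(0.3), data, g, cfg, "x") - ld(0.3),
    log_posterior(st(0.8), data, g, cfg, "x") - ld(0.8),
    tolerance = 1e-10)
})

test_that("identical seeds give identical retained draws", {
  st <- generate_study(36, seed = 4)
  cfg <- model_config(variant = "leroux", n_iterations = 800, burn_in = 200,
                      thinning = 2, seed = 123)
  f1 <- run_mcmc(st$data, st$graph, cfg)
  f2 <- run_mcmc(st$data, st$graph, cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$tau2_u, f2$tau2_u)
  expect_identical(f1$rho, f2$rho)
  # a different seed moves the draws
  f3 <- run_mcmc(st$data, st$graph,
                 model_config(variant = "leroux", n_iterations = 800,
                              burn_in = 200, thinning = 2, seed = 124))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("run_mcmc validates inputs and graph structure", {
  st <- generate_study(16, seed = 8)
  iso <- adjacency_from_edges(st$data$region_id, cbind("1", "2"))
  expect_error(run_mcmc(st$data, iso, model_config(variant = "bym",
                                                   n_iterations = 100,
                                                   burn_in = 10)),
               "isolated")
  bad <- st$data
  bad$y[1] <- bad$N[1] + 5
  expect_error(run_mcmc(bad, st$graph, model_config(n_iterations = 100,
                                                    burn_in = 10)),
               "y <= N")
})

test_that("iid-only variant agrees with an independently coded sampler", {
  # data from a logistic random-intercept model with no spatial structure
  set.seed(31)
  n <- 30
  N <- sample(200:800, n, replace = TRUE)
  v_true <- rnorm(n, 0, sqrt(0.09))
  y <- rbinom(n, N, plogis(-2.2 + v_true))
  g <- grid_graph(5, 6) # graph is ignored by the iid variant's likelihood
  data <- data.frame(region_id = seq_len(n), N = N, y = y)

  cfg <- model_config(variant = "iid_only", n_iterations = 20000,
                      burn_in = 5000, thinning = 5, seed = 77)
  fit <- run_mcmc(data, g, cfg, covariates = character(0))

  # oracle: plain-R Metropolis-within-Gibbs written independently
  oracle <- local({
    set.seed(99)
    b0 <- -2; v <- rep(0, n); t2 <- 0.1
    keep_t2 <- numeric(0); keep_b0 <- numeric(0)
    llik <- function(eta, yy, NN) yy * eta - NN * log1p(exp(eta))
    for (it in 1:20000) {
      b0p <- b0 + rnorm(1, 0, 0.05)
      a <- sum(llik(b0p + v, y, N)) - sum(llik(b0 + v, y, N)) +
        dnorm(b0p, 0, 10, log = TRUE) - dnorm(b0, 0, 10, log = TRUE)
      if (log(runif(1)) < a) b0 <- b0p
      for (r in 1:n) {
        vp <- v[r] + rnorm(1, 0, 0.15)
        a <- llik(b0 + vp, y[r], N[r]) - llik(b0 + v[r], y[r], N[r]) +
          dnorm(vp, 0, sqrt(t2), log = TRUE) -
          dnorm(v[r], 0, sqrt(t2), log = TRUE)
        if (log(runif(1)) < a) v[r] <- vp
      }
      t2 <- 1 / rgamma(1, 1 + n / 2, rate = 0.01 + sum(v^2) / 2)
      if (it > 5000 && it %% 5 == 0) {
        keep_t2 <- c(keep_t2, t2); keep_b0 <- c(keep_b0, b0)
      }
    }
    list(t2 = keep_t2, b0 = keep_b0)
  })

  mcse <- function(x, nb = 30) {
    bm <- tapply(x, rep(seq_len(nb), each = ceiling(length(x) / nb))[
      seq_along(x)], mean)
    sd(bm) / sqrt(length(bm))
  }
  tol_t2 <- 2 * sqrt(mcse(fit$tau2_v)^2 + mcse(oracle$t2)^2)
  tol_b0 <- 2 * sqrt(mcse(fit$beta[, 1])^2 + mcse(oracle$b0)^2)
  expect_lt(abs(mean(fit$tau2_v) - mean(oracle$t2)), tol_t2 + 0.01)
  expect_lt(abs(mean(fit$beta[, 1]) - mean(oracle$b0)), tol_b0 + 0.02)
})

test_that("posterior prevalence summaries follow inverse-logit arithmetic", {
  # synthetic draws with known linear predictors
  fake <- structure(list(
    beta = cbind(c(0, 0, 0)), u = matrix(0, 3, 2), v = matrix(0, 3, 2),
    X = cbind(rep(1, 2)), offset = c(0, 0), region_ids = c("a", "b"),
    covariates = character(0),
    config = model_config(n_iterations = 10, burn_in = 1)),
    class = "posterior_samples")
  est <- posterior_prevalence(fake)
  expect_equal(est$p_hat, c(0.5, 0.5))
  expect_equal(est$sd, c(0, 0))

  fake$beta <- cbind(rep(-2.2, 3))
  est2 <- posterior_prevalence(fake)
  expect_equal(est2$p_hat, rep(plogis(-2.2), 2), tolerance = 1e-12)
  expect_equal(round(est2$p_hat[1], 4), 0.0998)
})

test_that("posterior spread shrinks when the assessed count grows", {
  st <- generate_study(36, seed = 21)
  small <- st$data
  big <- st$data
  big$N <- big$N * 10
  set.seed(1)
  big$y <- rbinom(nrow(big), big$N, st$truth$p)
  cfg <- model_config(variant = "leroux", n_iterations = 3000,
                      burn_in = 1000, thinning = 2, seed = 5)
  sd_small <- posterior_prevalence(run_mcmc(small, st$graph, cfg))$sd
  sd_big <- posterior_prevalence(run_mcmc(big, st$graph, cfg))$sd
  expect_lt(mean(sd_big), mean(sd_small))
})
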