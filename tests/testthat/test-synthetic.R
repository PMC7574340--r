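test_that("degenerate noise settings give exactly constant prevalence", {
  st <- generate_study(25, beta = c(qlogis(0.1), 0), tau2_u = 0,
                       tau2_v = 0, seed = 2)
  expect_equal(st$truth$p, rep(0.1, 25))
  expect_true(all(st$data$y <= st$data$N))
})

test_that("regeneration with the same seed is bit-identical", {
  a <- generate_study(49, seed = 33, n_small = 2, unit_level = TRUE)
  b <- generate_study(49, seed = 33, n_small = 2, unit_level = TRUE)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$units, b$units)
  c <- generate_study(49, seed = 34)
  expect_false(identical(a$data$y, c$data$y))
})

test_that("assessed counts match the skewed target profile", {
  means <- vapply(1:20, function(s)
    mean(generate_study(335, seed = s)$data$N), numeric(1))
  expect_lt(abs(mean(means) - 878.2) / 878.2, 0.15)
  # long right tail, bounded at the profile maximum
  all_N <- unlist(lapply(1:5, function(s) generate_study(335, seed = s)$data$N))
  expect_lte(max(all_N), 4441)
  expect_gt(max(all_N), 2000)
  expect_gt(mean(all_N) - median(all_N), 0) # right skew
})

test_that("structured-effect spatial autocorrelation increases with rho", {
  mi <- vapply(c(0, 0.5, 0.95), function(r) {
    vals <- vapply(1:8, function(s) {
      st <- generate_study(100, tau2_u = 0.5, tau2_v = 0, rho = r,
                           seed = 500 + s)
      morans_i(st$truth$u, st$graph$W)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mi) > 0))
  expect_gt(mi[3], 0.2)
})

test_that("unit-level Bernoulli aggregation matches binomial draws in distribution", {
  # first two moments of y in a fixed region across many seeds
  y_bin <- y_unit <- numeric(300)
  for (s in 1:300) {
    y_bin[s] <- generate_study(9, nrow = 3, seed = s)$data$y[1]
    st <- generate_study(9, nrow = 3, seed = s, unit_level = TRUE)
    y_unit[s] <- st$data$y[1]
    if (s <= 3) expect_equal(sum(st$units$outcome[st$units$region_id == "1"]),
                             st$data$y[1])
  }
  # same N and p sequences by seed, so moments must agree
  expect_lt(abs(mean(y_bin) - mean(y_unit)) / mean(y_bin), 0.1)
  expect_lt(abs(sd(y_bin) - sd(y_unit)) / sd(y_bin), 0.15)
})

test_that("score classification freezes reference cut-offs", {
  set.seed(10)
  ref <- sample(seq(0, 10, length.out = 1000)) # tie-free
  res <- assign_categories(ref)
  expect_equal(as.integer(table(res$category)), c(100, 150, 750))

  # identical scores: degenerate cut-offs, single category
  same <- assign_categories(rep(5, 20))
  expect_true(same$degenerate)
  expect_equal(length(unique(same$category)), 1)

  # an upward-shifted later cohort scores fewer than 10% vulnerable
  later <- assign_categories(ref + 0.5, reference = ref)
  expect_lt(mean(later$category == "vulnerable"), 0.10)

  expect_error(assign_categories(1:5, reference = numeric(0)), "empty")
})

test_that("missingness injection applies both administrative mechanisms", {
  st <- generate_study(335, n_small = 2, seed = 18)
  st2 <- inject_missingness(st, n_covariate_missing = 2)
  expect_equal(sum(st2$data$response_missing), 2)
  expect_equal(sum(st2$data$covariate_missing), 2)
  expect_false(any(st2$data$response_missing & st2$data$covariate_missing))
  expect_true(all(is.na(st2$data$y[st2$data$response_missing])))
  expect_true(all(is.na(st2$data$score[st2$data$covariate_missing])))
  # truth untouched
  expect_identical(st2$truth, st$truth)

  # a region with N = 5 is suppressed; nothing under threshold, no flags
  small <- generate_study(25, seed = 19)
  small$data$N[3] <- 5L
  flagged <- inject_missingness(small, n_covariate_missing = 0)
  expect_true(flagged$data$response_missing[3])
  big <- generate_study(25, seed = 20)
  big$data$N <- pmax(big$data$N, 20L)
  clean <- inject_missingness(big, n_covariate_missing = 0)
  expect_equal(sum(clean$data$response_missing), 0)
  expect_identical(ifelse(is.na(clean$data$y), -1L, clean$data$y),
                   ifelse(is.na(big$data$y), -1L, big$data$y))
})
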