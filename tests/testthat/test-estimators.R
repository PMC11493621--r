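test_that("the Wald ratio and its delta-method standard error are exact", {
  expect_equal(mr_wald_ratio(harmonized_set(0.5, 0.01, 0.25, 0.1))$beta, 0.5)
  expect_equal(mr_wald_ratio(harmonized_set(0.5, 0.01, 0.25, 0.1))$se, 0.2)
  expect_equal(mr_wald_ratio(harmonized_set(0.5, 0.01, 0, 0.1))$beta, 0)
  fit <- mr_wald_ratio(harmonized_set(0.2, 0.01, -0.1, 0.05))
  expect_equal(fit$beta, -0.5)
  expect_equal(fit$se, 0.25)
  expect_error(mr_wald_ratio(harmonized_set(0, 0.01, 0.1, 0.1)), "degenerate")
})

test_that("IVW equals the closed-form ratio of sums with the stated standard errors", {
  h <- harmonized_set(bx = c(0.5, 0.5), se_x = c(0.01, 0.01),
                      by = c(0.25, 0.25), se_y = c(0.1, 0.1))
  expect_equal(mr_ivw(h)$beta, 0.5)

  h <- harmonized_set(bx = c(0.1, 0.2, 0.3), se_x = rep(0.01, 3),
                      by = c(0.05, 0.10, 0.15), se_y = rep(0.1, 3))
  fit <- mr_ivw(h, model = "fixed")
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, sqrt(0.01 / 0.14))

  # random sets against the independent ratio-of-sums oracle
  for (s in 1:25) {
    h <- random_hset(sample(3:30, 1), seed = s)
    oracle <- sum(h$bx * h$by / h$se_y^2) / sum(h$bx^2 / h$se_y^2)
    expect_equal(mr_ivw(h, model = "fixed")$beta, oracle, tolerance = 1e-12)
    # random-effects se never deflates below the fixed-effect se
    expect_gte(mr_ivw(h)$se, mr_ivw(h, model = "fixed")$se)
  }
})

test_that("MR-Egger recovers exact linear and affine relationships", {
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  h <- harmonized_set(bx, rep(0.01, 5), 0.3 * bx, rep(0.05, 5))
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(attr(fit, "extra")$intercept, 0, tolerance = 1e-12)

  h <- harmonized_set(bx, rep(0.01, 5), 0.1 + 0.3 * bx, rep(0.05, 5))
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(attr(fit, "extra")$intercept, 0.1, tolerance = 1e-12)
  expect_error(mr_egger(harmonized_set(1:2 / 10, c(0.1, 0.1), 1:2 / 10,
                                       c(0.1, 0.1))), "at least 3")
})

test_that("the weighted median matches the centered-percentile oracle", {
  h <- harmonized_set(bx = c(1, 1, 1), se_x = rep(0.01, 3),
                      by = c(0.4, 0.4, 0.4), se_y = c(0.1, 0.2, 0.3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.4)

  # ratios (0.1, 0.2, 0.9) with equal weights -> 0.2
  h <- harmonized_set(bx = c(1, 1, 1), se_x = rep(0.01, 3),
                      by = c(0.1, 0.2, 0.9), se_y = c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.2)

  for (s in 1:20) {
    h <- random_hset(sample(3:25, 1), seed = 100 + s)
    ratio <- h$by / h$bx
    w <- (h$bx / h$se_y)^2
    expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta,
                 oracle_weighted_median(ratio, w), tolerance = 1e-12)
  }
})

test_that("the weighted mode finds the dominant ratio cluster", {
  h <- harmonized_set(bx = rep(1, 3), se_x = rep(0.01, 3),
                      by = rep(0.4, 3), se_y = rep(0.1, 3))
  expect_equal(mr_weighted_mode(h, n_boot = 50, seed = 1)$beta, 0.4)

  h <- harmonized_set(bx = rep(1, 4), se_x = rep(0.01, 4),
                      by = c(0.2, 0.2, 0.2, 0.9), se_y = rep(0.5, 4))
  fit <- mr_weighted_mode(h, n_boot = 50, seed = 1)
  expect_lt(abs(fit$beta - 0.2), 0.05)

  # grid oracle at the same bandwidth
  set.seed(41)
  h <- random_hset(12, seed = 41)
  ratio <- h$by / h$bx
  w <- (h$bx / h$se_y)^2
  bw <- 0.9 * mad(ratio) / 12^0.2
  grid_step <- (diff(range(ratio)) + 6 * bw) / 511
  expect_lt(abs(mr_weighted_mode(h, n_boot = 10, seed = 1)$beta -
                  oracle_weighted_mode(ratio, w, bw)),
            max(0.02, 2 * grid_step))
})

test_that("Bayesian weighted MR honors its likelihood-dominated limits", {
  bx <- c(0.12, 0.18, 0.25, 0.3, 0.22)
  h <- harmonized_set(bx, rep(1e-8, 5), 0.3 * bx, rep(1e-4, 5))
  expect_equal(mr_bwmr(h, prior_sd_theta = 1e4)$beta, 0.3, tolerance = 1e-6)

  # clean data: matches fixed-effect IVW within 1e-3
  for (s in 1:10) {
    set.seed(s)
    k <- 30
    gam <- abs(rnorm(k, 0, 0.1)) + 0.05
    h <- harmonized_set(gam, rep(1e-8, k), rnorm(k, 0.2 * gam, 0.01),
                        rep(0.01, k))
    expect_equal(mr_bwmr(h)$beta, mr_ivw(h, model = "fixed")$beta,
                 tolerance = 1e-3)
  }
})

test_that("Bayesian weighting down-weights gross outliers that bias IVW", {
  wins <- 0L
  for (s in 1:50) {
    set.seed(7000 + s)
    k <- 20
    gam <- abs(rnorm(k, 0, 0.15)) + 0.05
    bx <- rnorm(k, gam, 0.005)
    alpha <- c(rep(0, k - 2), 0.3, -0.25)   # two gross outliers
    by <- rnorm(k, 0.1 * gam + alpha, 0.01)
    h <- harmonized_set(bx, rep(0.005, k), by, rep(0.01, k))
    fit <- mr_bwmr(h)
    expect_lt(min(attr(fit, "extra")$weights[(k - 1):k]), 0.5)
    wins <- wins + (abs(fit$beta - 0.1) <
                      abs(mr_ivw(h, model = "fixed")$beta - 0.1))
  }
  expect_gte(wins, 35L)   # robustness wins in the clear majority of draws
})

test_that("estimators respect allele recoding, outcome reflection and outcome scaling", {
  set.seed(51)
  # instruments bounded away from bx = 0 keep the bootstrap ratios stable
  bx0 <- runif(15, 0.1, 0.5) * sample(c(-1, 1), 15, replace = TRUE)
  h <- harmonized_set(bx0, rep(0.01, 15), rnorm(15, 0.2 * bx0, 0.05),
                      runif(15, 0.03, 0.08))
  # joint sign flip of (bx, by) is an allele recoding: every Wald ratio, and
  # so every estimate, is unchanged
  recoded <- harmonized_set(-h$bx, h$se_x, -h$by, h$se_y)
  # negating the outcome alone negates the causal effect
  reflected <- harmonized_set(h$bx, h$se_x, -h$by, h$se_y)
  scaled <- harmonized_set(h$bx, h$se_x, 3 * h$by, 3 * h$se_y)
  fits <- list(
    function(x) mr_ivw(x),
    function(x) mr_ivw(x, model = "fixed"),
    function(x) mr_egger(x),
    function(x) mr_weighted_median(x, n_boot = 200, seed = 9),
    function(x) mr_weighted_mode(x, n_boot = 200, seed = 9),
    function(x) mr_bwmr(x, prior_sd_theta = 1e6)
  )
  for (f in fits) {
    base <- f(h)
    rec <- f(recoded)
    expect_equal(rec$beta, base$beta, tolerance = 1e-4)
    # bootstrap noise enters with the opposite sign after recoding
    expect_equal(rec$se, base$se, tolerance = 0.25)
    ref <- f(reflected)
    expect_equal(ref$beta, -base$beta, tolerance = 1e-4)
    # bootstrap ses under reflection use fresh noise patterns: compare loosely
    expect_equal(ref$se, base$se, tolerance = 0.25)
    sc <- f(scaled)
    expect_equal(sc$beta, 3 * base$beta, tolerance = 1e-4)
    expect_equal(sc$se, 3 * base$se, tolerance = 0.25)
  }
})

test_that("estimate objects keep odds ratios, intervals and p-values consistent", {
  for (s in 1:10) {
    h <- random_hset(8, seed = 200 + s)
    fit <- mr_ivw(h)
    expect_equal(fit$or_, exp(fit$beta), tolerance = 1e-12)
    expect_equal(fit$ci_low, exp(fit$beta - 1.959963985 * fit$se),
                 tolerance = 1e-12)
    expect_equal(fit$ci_high, exp(fit$beta + 1.959963985 * fit$se),
                 tolerance = 1e-12)
    expect_true(fit$ci_low < fit$or_ && fit$or_ < fit$ci_high)
    expect_equal(fit$pvalue, 2 * pnorm(-abs(fit$beta / fit$se)),
                 tolerance = 1e-6)
  }
})

test_that("the estimator panel adapts to the instrument count", {
  h1 <- harmonized_set(0.5, 0.01, 0.25, 0.1)
  expect_equal(nrow(mr_run_all(h1)), 1L)
  expect_equal(mr_run_all(h1)$method, "wald_ratio")

  h2 <- harmonized_set(c(0.5, 0.4), c(0.01, 0.01), c(0.25, 0.2), c(0.1, 0.1))
  expect_equal(mr_run_all(h2)$method, "ivw")

  h5 <- random_hset(5, seed = 61)
  est <- mr_run_all(h5, n_boot = 50, seed = 1)
  expect_equal(nrow(est), 5L)
  expect_setequal(est$method, c("ivw", "egger", "weighted_median",
                                "weighted_mode", "bwmr"))
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  h <- random_hset(10, seed = 71)
  a <- mr_weighted_median(h, n_boot = 100, seed = 5)
  b <- mr_weighted_median(h, n_boot = 100, seed = 5)
  c <- mr_weighted_median(h, n_boot = 100, seed = 6)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
})
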