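test_that("wald ratio implements the first-order delta method", {
  e <- mr_wald_ratio(0.1, 0.01, 0.02, 0.01)
  expect_equal(e$theta, 0.2)
  expect_equal(e$se, 0.1)
  expect_equal(mr_wald_ratio(0.1, 0.01, 0, 0.01)$theta, 0)
  expect_error(mr_wald_ratio(0, 0.01, 0.02, 0.01), "beta_exposure = 0")

  # second-order delta-method oracle: var = sy^2/gx^2 + gy^2 sx^2 / gx^4;
  # first-order SE agrees when the exposure is precisely estimated
  gx <- 0.2; sx <- 0.002; gy <- 0.05; sy <- 0.01
  se2 <- sqrt(sy^2 / gx^2 + gy^2 * sx^2 / gx^4)
  expect_equal(mr_wald_ratio(gx, sx, gy, sy)$se, se2, tolerance = 2e-3)
})

test_that("IVW reduces to the Wald ratio and obeys weight additivity", {
  one <- make_set(0.1, 0.01, 0.02, 0.01)
  expect_equal(mr_ivw(one)$theta, 0.2)
  expect_equal(mr_ivw(one)$se, 0.1)

  k <- 9
  copies <- make_set(rep(0.1, k), rep(0.01, k), rep(0.02, k), rep(0.01, k))
  fe <- mr_ivw(copies, mode = "fixed")
  expect_equal(fe$theta, 0.2)
  expect_equal(fe$se, 0.1 / sqrt(k))
})

test_that("IVW matches the independent weighted-regression oracle", {
  set.seed(31)
  for (rep in 1:5) {
    j <- 10
    gx <- rnorm(j, 0.1, 0.05); gy <- 0.3 * gx + rnorm(j, 0, 0.02)
    sy <- runif(j, 0.01, 0.05)
    s <- make_set(gx, 0.01, gy, sy)
    fit <- lm(gy ~ 0 + gx, weights = 1 / sy^2)
    sm <- summary(fit)
    fe <- mr_ivw(s, mode = "fixed")
    mre <- mr_ivw(s, mode = "mre")
    expect_equal(fe$theta, unname(coef(fit)), tolerance = 1e-12)
    expect_equal(mre$theta, fe$theta)
    # lm's weighted SE is exactly the multiplicative random-effects SE
    expect_equal(mre$se, unname(sm$coefficients[1, 2]), tolerance = 1e-12)
    expect_equal(fe$se, unname(sm$coefficients[1, 2]) / sm$sigma, tolerance = 1e-12)
    expect_equal(mre$se / fe$se, sqrt(mre$extras$phi), tolerance = 1e-12)
  }
})

test_that("MRE and FE share the point estimate; only the SE scales with phi", {
  sim <- simulate_two_sample(sim_config(n_snps = 50, sigma_alpha = 0.01,
                                        frac_invalid = 1, seed = 32))
  s <- harmonize(sim$exposure, sim$outcome)
  fe <- mr_ivw(s, "fixed"); mre <- mr_ivw(s, "mre")
  expect_equal(fe$theta, mre$theta)
  expect_equal(mre$se >= fe$se, mre$extras$phi >= 1)
})

test_that("Egger recovers intercept and slope exactly on noise-free data", {
  gx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  a <- 0.01; theta <- -0.2
  gy <- a + theta * gx
  s <- make_set(gx, 0.01, gy, c(0.01, 0.02, 0.01, 0.03, 0.02))
  e <- mr_egger(s)
  expect_equal(e$theta, theta, tolerance = 1e-10)
  expect_equal(e$extras$egger_intercept, a, tolerance = 1e-10)
})

test_that("Egger matches the weighted least-squares oracle with t inference", {
  set.seed(33)
  j <- 12
  gx <- abs(rnorm(j, 0.1, 0.05)) + 0.01
  gy <- 0.02 + 0.3 * gx + rnorm(j, 0, 0.05)  # noisy: phi > 1
  sy <- runif(j, 0.01, 0.03)
  s <- make_set(gx, 0.01, gy, sy)
  e <- mr_egger(s)
  fit <- summary(lm(gy ~ gx, weights = 1 / sy^2))
  expect_gt(e$extras$phi, 1)
  expect_equal(e$theta, unname(fit$coefficients[2, 1]), tolerance = 1e-12)
  expect_equal(e$se, unname(fit$coefficients[2, 2]), tolerance = 1e-12)
  expect_equal(e$pvalue, unname(fit$coefficients[2, 4]), tolerance = 1e-12)
  expect_equal(e$extras$egger_intercept, unname(fit$coefficients[1, 1]),
               tolerance = 1e-12)
  expect_equal(e$extras$intercept_p, unname(fit$coefficients[1, 4]),
               tolerance = 1e-12)
})

test_that("Egger orients instruments to non-negative exposure effects", {
  gx <- c(0.05, -0.1, 0.15, -0.2, 0.3)
  gy <- 0.01 * sign(gx) + 0.3 * gx
  s1 <- make_set(gx, 0.01, gy, 0.02)
  s2 <- make_set(abs(gx), 0.01, gy * sign(gx), 0.02)
  e1 <- mr_egger(s1); e2 <- mr_egger(s2)
  expect_equal(e1$theta, e2$theta)
  expect_equal(e1$extras$egger_intercept, e2$extras$egger_intercept)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  s <- make_set(c(1, 1, 1), 0.01, c(1, 2, 10), 0.02)
  expect_equal(mr_weighted_median(s, bootstrap_reps = 0)$theta, 2)

  # dominant weight: one precise SNP carries nearly all weight
  s2 <- make_set(c(1, 1, 1), 0.01, c(1, 5, 10) * c(1, 1, 1),
                 c(1000, 0.001, 1000))
  expect_equal(mr_weighted_median(s2, bootstrap_reps = 0)$theta, 5,
               tolerance = 1e-3)

  # equal weights, odd J: the ordinary median
  ratios <- c(0.5, 0.1, 0.9, 0.3, 0.7)
  s3 <- make_set(rep(1, 5), 0.01, ratios, 0.02)
  expect_equal(mr_weighted_median(s3, bootstrap_reps = 0)$theta,
               median(ratios))
  expect_error(mr_weighted_median(make_set(1, 0.1, 1, 0.1)), "at least 3")
})

test_that("weighted median matches a brute-force interpolated-percentile oracle", {
  set.seed(34)
  for (rep in 1:5) {
    j <- 15
    gx <- rnorm(j, 0.1, 0.03); gy <- 0.2 * gx + rnorm(j, 0, 0.02)
    sy <- runif(j, 0.01, 0.05)
    s <- make_set(gx, 0.01, gy, sy)
    theta <- gy / gx
    w <- (gx / sy)^2
    ord <- order(theta)
    cum <- (cumsum(w[ord]) - w[ord] / 2) / sum(w)
    k <- max(which(cum < 0.5))
    oracle <- theta[ord][k] + (theta[ord][k + 1] - theta[ord][k]) *
      (0.5 - cum[k]) / (cum[k + 1] - cum[k])
    expect_equal(mr_weighted_median(s, bootstrap_reps = 0)$theta, oracle,
                 tolerance = 1e-12)
  }
})

test_that("weighted median bootstrap is seed-reproducible", {
  sim <- simulate_two_sample(sim_config(n_snps = 30, seed = 35))
  s <- harmonize(sim$exposure, sim$outcome)
  a <- mr_weighted_median(s, bootstrap_reps = 200, seed = 9)
  b <- mr_weighted_median(s, bootstrap_reps = 200, seed = 9)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(s, bootstrap_reps = 200, seed = 10)
  expect_false(identical(a$se, c_$se))
})

test_that("weighted mode finds the plurality cluster and is translation-equivariant", {
  s <- make_set(rep(1, 4), 0.01, rep(0.7, 4), 0.02)
  expect_equal(mr_weighted_mode(s, bootstrap_reps = 0)$theta, 0.7)

  set.seed(36)
  ratios <- c(rnorm(7, 0.5, 0.01), 3.1, -2.4, 5.0)
  s2 <- make_set(rep(1, 10), 0.01, ratios, 0.02)
  m <- mr_weighted_mode(s2, bootstrap_reps = 0)$theta
  h <- 0.9 * min(sd(ratios), mad(ratios)) * 10^(-1 / 5)
  expect_lt(abs(m - 0.5), h)

  shift <- make_set(rep(1, 10), 0.01, ratios + 2, 0.02)
  m2 <- mr_weighted_mode(shift, bootstrap_reps = 0)$theta
  expect_equal(m2, m + 2, tolerance = h / 5)
})

test_that("Cochran's Q is zero for proportional data and scales with weights", {
  gx <- c(0.1, 0.2, 0.3, 0.4)
  s <- make_set(gx, 0.01, 0.5 * gx, 0.02)
  expect_equal(mr_cochran_q(s, 0.5)$q, 0)

  set.seed(37)
  gy <- 0.5 * gx + rnorm(4, 0, 0.05)
  s1 <- make_set(gx, 0.01, gy, 0.02)
  s2 <- make_set(gx, 0.01, gy, 0.04)
  expect_equal(mr_cochran_q(s2, 0.5)$q, mr_cochran_q(s1, 0.5)$q / 4)
})

test_that("null Cochran's Q follows its chi-square reference distribution", {
  set.seed(38)
  j <- 10; theta <- 0.3
  q <- replicate(2000, {
    gx <- runif(j, 0.05, 0.3)
    sy <- runif(j, 0.01, 0.05)
    gy <- theta * gx + rnorm(j, 0, sy)
    s <- make_set(gx, 0.001, gy, sy)
    mr_ivw(s)$extras$cochran_q
  })
  ks <- suppressWarnings(ks.test(q, pchisq, df = j - 1))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("estimators transform correctly under sign and scale changes", {
  sim <- simulate_two_sample(sim_config(n_snps = 40, seed = 39))
  s <- harmonize(sim$exposure, sim$outcome)
  neg <- s; neg$snps$beta_outcome <- -neg$snps$beta_outcome
  scaled <- s
  scaled$snps$beta_exposure <- 2 * scaled$snps$beta_exposure
  scaled$snps$se_exposure <- 2 * scaled$snps$se_exposure

  for (fn in list(function(x) mr_ivw(x)$theta,
                  function(x) mr_egger(x)$theta,
                  function(x) mr_weighted_median(x, bootstrap_reps = 0)$theta)) {
    expect_equal(fn(neg), -fn(s), tolerance = 1e-10)
    expect_equal(fn(scaled), fn(s) / 2, tolerance = 1e-10)
  }
  # mode: equality up to grid resolution
  m <- mr_weighted_mode(s, bootstrap_reps = 0)$theta
  expect_equal(mr_weighted_mode(neg, bootstrap_reps = 0)$theta, -m,
               tolerance = 1e-6)
})

test_that("the estimator battery serializes to a consistent table and JSON", {
  sim <- simulate_two_sample(sim_config(n_snps = 30, seed = 40))
  s <- harmonize(sim$exposure, sim$outcome)
  ests <- mr_all(s, bootstrap_reps = 100, seed = 4)
  tab <- estimates_table(ests)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$or, exp(tab$theta))
  path <- withr::local_tempfile(fileext = ".json")
  estimates_json(ests, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$ivw_mre$theta, ests$ivw_mre$theta, tolerance = 1e-12)
})
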