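test_that("multivariable IVW reduces to univariable IVW for one exposure", {
  gx <- seq(0.05, 0.5, length.out = 10)
  gy <- 0.3 * gx + c(0.001, -0.001, 0.002, -0.002, 0, 0.001, -0.001, 0, 0.001, -0.001)
  sy <- rep(0.05, 10)  # large SEs: phi below 1, floored
  s <- make_set(gx, 0.01, gy, sy)
  uni <- mr_ivw(s, mode = "fixed")
  mv <- mvmr_ivw(matrix(gx, ncol = 1), gy, sy, "x1")
  expect_equal(unname(mv$theta), uni$theta, tolerance = 1e-12)
  expect_equal(unname(mv$se), uni$se, tolerance = 1e-12)
})

test_that("multivariable IVW solves noise-free linear systems exactly", {
  set.seed(61)
  bx <- cbind(x1 = runif(12, 0.05, 0.3), x2 = runif(12, 0.05, 0.3))
  by <- 0.3 * bx[, 1] - 0.1 * bx[, 2]
  mv <- mvmr_ivw(bx, by, rep(0.02, 12))
  expect_equal(unname(mv$theta), c(0.3, -0.1), tolerance = 1e-10)
})

test_that("multivariable IVW matches an independent GLS oracle", {
  set.seed(62)
  j <- 50; k <- 3
  bx <- matrix(runif(j * k, 0.02, 0.3), j, k,
               dimnames = list(NULL, paste0("x", 1:k)))
  by <- bx %*% c(0.2, -0.1, 0.05) + rnorm(j, 0, 0.05)
  sy <- runif(j, 0.01, 0.04)
  mv <- mvmr_ivw(bx, drop(by), sy)
  fit <- summary(lm(by ~ 0 + bx, weights = 1 / sy^2))
  expect_equal(unname(mv$theta), unname(fit$coefficients[, 1]), tolerance = 1e-10)
  expect_gt(mv$phi, 1)  # noisy fit: no flooring in play
  expect_equal(unname(mv$se), unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("collinear exposures are rejected by name and scaling is equivariant", {
  bx <- cbind(a = seq(0.1, 1, 0.1), b = 2 * seq(0.1, 1, 0.1))
  expect_error(mvmr_ivw(bx, rnorm(10), rep(0.02, 10)), "collinear")

  set.seed(63)
  bx2 <- cbind(a = runif(20, 0.05, 0.3), b = runif(20, 0.05, 0.3))
  by <- drop(bx2 %*% c(0.2, -0.3)) + rnorm(20, 0, 0.02)
  sy <- rep(0.02, 20)
  base <- mvmr_ivw(bx2, by, sy)
  scaled <- mvmr_ivw(cbind(a = 2 * bx2[, 1], b = bx2[, 2]), by, sy)
  expect_equal(unname(scaled$theta["a"]), unname(base$theta["a"]) / 2,
               tolerance = 1e-10)
  expect_equal(unname(scaled$theta["b"]), unname(base$theta["b"]),
               tolerance = 1e-10)
})

test_that("the product method reproduces the worked mediation arithmetic", {
  res <- mediate_two_step(0.0504, 0.0194, 0.0601, 0.0267,
                          total_effect = 0.0878, bootstrap_reps = 5000,
                          seed = 64)
  expect_equal(round(res$indirect, 4), 0.0030)
  expect_equal(round(res$indirect_or, 3), 1.003)
  expect_equal(res$indirect_or, exp(res$beta1 * res$beta2))
  expect_equal(res$proportion_mediated, res$indirect / 0.0878)

  null1 <- mediate_two_step(0, 0.01, 0.5, 0.1, total_effect = 0.2,
                            bootstrap_reps = 500, seed = 65)
  expect_equal(null1$indirect, 0)
  expect_equal(null1$indirect_or, 1)
  expect_equal(null1$proportion_mediated, 0)
})

test_that("mediation is product-symmetric and its bootstrap CI collapses with the SEs", {
  a <- mediate_two_step(0.05, 0.01, 0.06, 0.02, 0.1, 2000, seed = 66)
  b <- mediate_two_step(0.06, 0.02, 0.05, 0.01, 0.1, 2000, seed = 66)
  expect_equal(a$indirect, b$indirect)

  tight <- mediate_two_step(0.05, 1e-8, 0.06, 1e-8, 0.1, 2000, seed = 67)
  expect_lt(tight$ci_high - tight$ci_low, 1e-6)
  expect_equal(tight$ci_low, exp(0.003), tolerance = 1e-5)

  undef <- mediate_two_step(0.05, 0.01, 0.06, 0.02, 0, 500, seed = 68)
  expect_false(undef$proportion_defined)
  expect_true(is.na(undef$proportion_mediated))
})

test_that("the mediation pipeline recovers a null mediator-outcome path", {
  mc <- simulate_mediation_chain(beta_my = 0, theta_direct = -0.0878, seed = 69)
  res <- mediation_pipeline(mc$exposure, mc$mediator, mc$outcome,
                            presso_exclude = FALSE, bootstrap_reps = 500,
                            seed = 70)
  expect_lt(abs(res$beta2), 3 * res$se2)
  expect_lt(abs(res$proportion_mediated), 0.05)
})

test_that("the mediation pipeline is bit-reproducible under a fixed seed", {
  mc <- simulate_mediation_chain(seed = 71)
  a <- mediation_pipeline(mc$exposure, mc$mediator, mc$outcome,
                          presso_sims = 300, bootstrap_reps = 500, seed = 72)
  b <- mediation_pipeline(mc$exposure, mc$mediator, mc$outcome,
                          presso_sims = 300, bootstrap_reps = 500, seed = 72)
  expect_identical(unclass(a), unclass(b))
  expect_identical(attr(a, "extras")$stage2$theta, attr(b, "extras")$stage2$theta)
})

test_that("adjusting a genetically null covariate leaves the exposure estimate unchanged", {
  set.seed(73)
  j <- 80
  gx <- runif(j, 0.02, 0.2)
  gz <- rnorm(j, 0, 0.002)           # covariate with (essentially) no effects
  sy <- runif(j, 0.005, 0.02)
  gy <- -0.0877 * gx + rnorm(j, 0, sy)
  uni <- mvmr_ivw(cbind(x = gx), gy, sy)
  adj <- mvmr_ivw(cbind(x = gx, z = gz), gy, sy)
  expect_equal(unname(adj$theta["x"]), unname(uni$theta["x"]),
               tolerance = 3 * unname(uni$se["x"]))
})

test_that("mediation results serialize to JSON", {
  res <- mediate_two_step(0.0504, 0.0194, 0.0601, 0.0267, 0.0878, 500, seed = 74)
  path <- withr::local_tempfile(fileext = ".json")
  mediation_json(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$indirect, res$indirect, tolerance = 1e-12)
  expect_equal(back$proportion_mediated, res$proportion_mediated,
               tolerance = 1e-12)
})
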