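# A clean PRESSO-sized fixture: proportional effects plus noise at the
# reported SEs, with an optional planted pleiotropic offset.
presso_sim <- function(j = 50, theta = -0.0877, outlier_scale = 0,
                       seed = 1) {
  sim <- simulate_two_sample(sim_config(
    n_snps = j, theta = theta, n_outliers = if (outlier_scale > 0) 1 else 0,
    outlier_scale = outlier_scale, seed = seed))
  list(set = harmonize(sim$exposure, sim$outcome), truth = sim$truth)
}

test_that("noise-free proportional data give zero RSS and a null global p", {
  gx <- seq(0.05, 0.3, length.out = 6)
  s <- make_set(gx, 0.01, 0.4 * gx, 0.02)
  g <- presso_global(s, n_simulations = 200, seed = 5)
  expect_equal(g$rss_obs, 0)
  expect_equal(g$global_p, 1)
})

test_that("a gross planted outlier drives the global p to its minimum", {
  ps <- presso_sim(j = 30, outlier_scale = 10, seed = 6)
  g <- presso_global(ps$set, n_simulations = 300, seed = 7)
  expect_equal(g$global_p, 1 / 301)
})

test_that("the outlier test flags the planted SNP and spares clean data", {
  ps <- presso_sim(j = 50, outlier_scale = 10, seed = 8)
  res <- mr_presso(ps$set, n_simulations = 1000, seed = 9)
  expect_identical(res$outlier_ids, ps$truth$outlier_ids)
  expect_true(abs(res$theta_corrected$theta - ps$truth$theta) <
                abs(res$theta_raw$theta - ps$truth$theta) + 0.05)

  clean <- presso_sim(j = 50, seed = 10)
  res0 <- mr_presso(clean$set, n_simulations = 1000, seed = 11)
  expect_length(res0$outlier_ids, 0)
  expect_null(res0$theta_corrected)
  expect_true(is.na(res0$distortion_p))
})

test_that("global p and outlier p are invariant to SNP ordering", {
  ps <- presso_sim(j = 20, outlier_scale = 10, seed = 12)
  shuffled <- ps$set
  perm <- sample(seq_len(20))
  shuffled$snps <- shuffled$snps[perm, ]
  a <- presso_global(ps$set, 300, seed = 13)
  b <- presso_global(shuffled, 300, seed = 13)
  expect_identical(a$global_p, b$global_p)
  expect_identical(a$r2_obs, b$r2_obs)
  oa <- presso_outlier(ps$set, a)
  ob <- presso_outlier(shuffled, b)
  expect_identical(oa$outlier_p, ob$outlier_p)
})

test_that("the full procedure is bit-reproducible under a fixed seed", {
  ps <- presso_sim(j = 25, outlier_scale = 8, seed = 14)
  a <- mr_presso(ps$set, n_simulations = 400, seed = 15)
  b <- mr_presso(ps$set, n_simulations = 400, seed = 15)
  a$r2_sim <- b$r2_sim <- NULL
  expect_identical(a, b)
})

test_that("distortion is null when outliers do not move the estimate, and sign-symmetric", {
  # two 'outliers' lying exactly on the common slope: removing them changes nothing
  gx <- seq(0.05, 0.5, length.out = 10)
  s <- make_set(gx, 0.005, 0.3 * gx, 0.02)
  d <- presso_distortion(s, outlier_ids = s$snps$variant_id[1:2],
                         n_resamples = 200, seed = 16)
  expect_equal(d$distortion, 0)
  expect_gt(d$distortion_p, 0.9)

  # planted directional offsets: distortion flips sign with the offsets
  ps <- presso_sim(j = 30, seed = 17)
  up <- ps$set; down <- ps$set
  ids <- up$snps$variant_id[1:3]
  shift <- 8 * up$snps$se_outcome[1:3]
  up$snps$beta_outcome[1:3] <- up$snps$beta_outcome[1:3] + shift
  down$snps$beta_outcome[1:3] <- down$snps$beta_outcome[1:3] - shift
  du <- presso_distortion(up, ids, n_resamples = 200, seed = 18)
  dd <- presso_distortion(down, ids, n_resamples = 200, seed = 18)
  expect_false(sign(du$distortion) == sign(dd$distortion))

  na <- presso_distortion(ps$set, character(0), n_resamples = 100, seed = 19)
  expect_false(na$applicable)
})

test_that("rss_obs is the sum of the per-SNP observed residuals", {
  ps <- presso_sim(j = 15, seed = 20)
  g <- presso_global(ps$set, 200, seed = 21)
  expect_equal(g$rss_obs, sum(g$r2_obs))
})

test_that("the PRESSO result serializes with an exclusion list", {
  ps <- presso_sim(j = 20, outlier_scale = 10, seed = 22)
  res <- mr_presso(ps$set, n_simulations = 500, seed = 23)
  jp <- withr::local_tempfile(fileext = ".json")
  ep <- withr::local_tempfile(fileext = ".txt")
  presso_json(res, jp, exclusion_path = ep)
  expect_identical(readLines(ep), res$outlier_ids)
  expect_equal(jsonlite::read_json(jp)$global_p, res$global_p)
})

test_that("degenerate inputs are refused with clear errors", {
  s <- make_set(c(0.1, 0.2, 0.3), 0.01, c(0.05, 0.1, 0.15), 0.02)
  expect_error(presso_global(s, 200, seed = 1), "at least 4")
  s4 <- make_set(seq(0.1, 0.4, 0.1), 0.01, seq(0.1, 0.4, 0.1), 0.02)
  expect_error(presso_global(s4, 50, seed = 1), "at least 100")
})
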