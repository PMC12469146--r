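test_that("bias and standard error follow their definitions", {
  expect_equal(sim_bias(c(0.4, 0.6), 0.5), 0)
  expect_equal(sim_bias(rep(0.465, 10), 0.3), 0.165)
  expect_equal(sim_bias(0.7, 0.45), 0.25)
  expect_error(sim_bias(numeric(0), 0.5), "nonempty")

  expect_equal(sim_se(c(0.4, 0.6)), sqrt(((-0.1)^2 + 0.1^2) / 1))
  expect_equal(sim_se(rep(0.3, 5)), 0)
  expect_error(sim_se(0.5), "length >= 2")

  # two-pass brute-force variance oracle
  set.seed(61)
  for (i in 1:10) {
    x <- runif(sample(3:30, 1))
    m <- sum(x) / length(x)
    brute <- sqrt(sum((x - m)^2) / (length(x) - 1))
    expect_equal(sim_se(x), brute, tolerance = 1e-12)
  }
})

test_that("pooled resample SD equals the SD of the pooled values", {
  set.seed(62)
  b <- 20
  groups <- replicate(15, rnorm(b, mean = runif(1), sd = runif(1, 0.1, 1)),
                      simplify = FALSE)
  means <- vapply(groups, mean, 0)
  wv <- vapply(groups, var, 0)
  expect_equal(sipw:::pooled_resample_sd(means, wv, b),
               sd(unlist(groups)), tolerance = 1e-12)
})

test_that("run_scenario aggregates per-method performance rows", {
  res <- run_scenario(0.4, 0.3, 0.6, 300, methods = c("fda", "cca", "bg"),
                      B = 30, seed = 63)
  expect_equal(nrow(res), 3)
  expect_setequal(res$method, c("fda", "cca", "bg"))
  expect_equal(res$bias_sn, res$mean_sn - 0.3, tolerance = 1e-12)
  expect_equal(res$bias_sp, res$mean_sp - 0.6, tolerance = 1e-12)
  expect_true(all(res$se_sn >= 0))
  # the benchmark estimator is unbiased up to Monte Carlo noise
  fda <- res[res$method == "fda", ]
  expect_lt(abs(fda$bias_sn), 4 * fda$se_sn / sqrt(30))
  # no methods requested -> empty result with the full schema
  empty <- run_scenario(0.4, 0.3, 0.6, 300, methods = character(0), B = 5)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("method", "bias_sn", "se_sp", "note") %in% names(empty)))
})

test_that("run_grid preserves schema, cardinality and determinism", {
  grid <- default_grid()
  expect_equal(nrow(grid), 24) # 12 combinations x 2 sample sizes
  small <- grid[c(1, 13), ]
  r1 <- run_grid(small, methods = c("cca", "bg"), B = 8, seed = 64)
  r2 <- run_grid(small, methods = c("cca", "bg"), B = 8, seed = 64)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4)
  expect_true(all(c("p", "sn_true", "sp_true", "n", "B", "method",
                    "mean_sn", "bias_sn", "se_sn", "mean_sp", "bias_sp",
                    "se_sp", "note") %in% names(r1)))
})

test_that("a failing scenario is reported as a note row, not an abort", {
  bad <- tibble::tibble(p = c(0.4, 0.001), sn = c(0.3, 0.3),
                        sp = c(0.6, 0.6), n = c(200L, 20L))
  res <- suppressWarnings(
    run_grid(bad, methods = "cca", B = 3, seed = 65)
  )
  expect_equal(nrow(res), 2)
  expect_true(any(!is.na(res$note)))
  expect_true(any(is.na(res$mean_sn)))
})

test_that("clinical analysis reports per-method estimates with intervals", {
  set.seed(66)
  d <- make_clinical_fixture(clinical_profiles()$scintigraphy)
  res <- analyze_clinical(d, methods = c("cca", "bg", "ipwe", "ipb", "sipw"),
                          b = 200, R = 100, seed = 66)
  expect_equal(attr(res, "n"), 650)
  expect_equal(attr(res, "n1"), 344)
  expect_equal(round(attr(res, "pct_unverified"), 1), 47.1)
  # BG and IPWE coincide on any dataset
  bg <- res[res$method == "bg", ]
  ipwe <- res[res$method == "ipwe", ]
  expect_equal(bg$estimate, ipwe$estimate, tolerance = 1e-12)
  expect_true(all(res$conf.low <= res$estimate + 1e-9))
  expect_true(all(res$estimate <= res$conf.high + 1e-9))
  # reconstructed fixture reproduces the uncorrected estimates it encodes
  cca <- res[res$method == "cca", ]
  expect_equal(round(cca$estimate, 3), c(0.895, 0.628))
  expect_equal(round(bg$estimate, 3), c(0.836, 0.738))
})

test_that("analyze_clinical on fully verified data returns the plain estimate", {
  set.seed(67)
  d <- simulate_complete(300, 0.4, 0.7, 0.8)
  fda <- estimate_fda(d)$estimates
  res <- analyze_clinical(d, methods = c("bg", "mi"), b = 50, R = 50, m = 5,
                          seed = 67)
  expect_equal(res$estimate[res$method == "bg"], unname(fda),
               tolerance = 1e-12)
  expect_equal(res$estimate[res$method == "mi"], unname(fda),
               tolerance = 1e-12)
})

test_that("autoplot methods return ggplot objects", {
  res <- run_scenario(0.4, 0.3, 0.6, 200, methods = c("fda", "cca"),
                      B = 5, seed = 68)
  expect_s3_class(autoplot(res, "bias"), "ggplot")
  set.seed(68)
  fit <- estimate_sipw(simulate_pvb_pair(150, 0.4, 0.6, 0.6)$pvb, b = 50)
  expect_s3_class(autoplot(fit), "ggplot")
})
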