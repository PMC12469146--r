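# Small dataset whose verified subjects occupy all four cells with unequal
# weights; used for the enumeration oracle.
oracle_data <- function() {
  tibble::tibble(
    test = c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    disease = c(1L, 1L, 0L, 0L, 1L, NA, NA, NA, NA, NA),
    verified = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  )
}

test_that("mean resample sensitivity matches brute-force tuple enumeration", {
  d <- sipw_weights(oracle_data())
  size <- 5L
  expected <- enumerate_expected_sn(d, size) # oracle over 5^5 tuples

  # table-level engine (what the estimators use)
  set.seed(21)
  q <- sapply(1:4, function(k) {
    idx <- 1L + (1L - d$test) + 2L * (1L - d$disease)
    sum(d$sipw[d$verified == 1 & idx == k])
  })
  b <- 40000L
  tabs <- sipw:::draw_valid_tables(q, size = size, b = b)
  sn <- tabs[1, ] / (tabs[1, ] + tabs[2, ])
  mc_se <- sd(sn) / sqrt(b)
  expect_lt(abs(mean(sn) - expected), 4 * mc_se)

  # subject-level engine agrees with the same expectation
  set.seed(22)
  sn_subj <- replicate(3000, {
    rs <- draw_valid_resample(d, size = size)
    unname(estimate_accuracy(cross_tabulate(rs))["sn"])
  })
  expect_lt(abs(mean(sn_subj) - expected), 4 * sd(sn_subj) / sqrt(3000))
})

test_that("resampling estimators return sane pooled estimates and lists", {
  set.seed(23)
  d <- simulate_pvb_pair(300, 0.4, 0.6, 0.6)$pvb
  for (f in list(function(x) estimate_sipw(x, b = 200),
                 function(x) estimate_ipb(x, b = 200),
                 function(x) estimate_sipwb(x, b = 200))) {
    fit <- f(d)
    expect_length(fit$boot$sn, 200)
    expect_length(fit$boot$sp, 200)
    expect_true(all(fit$boot$sn >= 0 & fit$boot$sn <= 1))
    expect_equal(unname(fit$estimates["sn"]), mean(fit$boot$sn))
    expect_equal(unname(fit$estimates["sp"]), mean(fit$boot$sp))
  }
})

test_that("SIPW resamples restore the full sample size, IPB the verified size", {
  set.seed(24)
  d <- simulate_pvb_pair(250, 0.4, 0.6, 0.6)$pvb
  sipw_fit <- estimate_sipw(d, b = 10)
  ipb_fit <- estimate_ipb(d, b = 10)
  expect_equal(sipw_fit$settings$resample_size, 250)
  expect_equal(ipb_fit$settings$resample_size, sum(d$verified))
})

test_that("SIPW-B resamples contain about n/2 diseased subjects at 1:1", {
  set.seed(25)
  d <- simulate_pvb_pair(400, 0.2, 0.6, 0.8)$pvb
  w <- sipwb_weights(d, rel_size = 1)
  q <- sipw:::cell_masses(w)
  expect_equal(unname(q[1] + q[2]), 0.5, tolerance = 1e-12)
  set.seed(26)
  tabs <- sipw:::draw_valid_tables(q, size = 400, b = 500)
  diseased <- colSums(tabs[1:2, ])
  expect_lt(abs(mean(diseased) - 200), 3 * sd(diseased) / sqrt(500) + 1)
  # rel_size = 3 shifts the diseased mass to 1/4
  w3 <- sipwb_weights(d, rel_size = 3)
  q3 <- sipw:::cell_masses(w3)
  expect_equal(unname(q3[1] + q3[2]), 0.25, tolerance = 1e-12)
})

test_that("with everything verified and uniform weights IPB is the plain bootstrap", {
  set.seed(27)
  d <- simulate_complete(300, 0.4, 0.6, 0.7)
  # all verified: PS fitting is impossible (no unverified); inject uniform weights
  w <- d
  w$ps <- 0.5
  fit <- sipw:::resample_estimate(w, "ipb", size = nrow(d), b = 2000,
                                  weights_fn = sipw_weights, settings = list())
  fda <- estimate_fda(d)$estimates
  # bootstrap mean of Sn approximates the plug-in estimate
  expect_lt(abs(unname(fit$estimates["sn"]) - fda[["sn"]]),
            4 * sd(fit$boot$sn) / sqrt(2000) + 0.002)
})

test_that("no-selection verification leaves resampling corrections unbiased", {
  set.seed(28)
  B <- 60
  diff_sipw <- diff_ipb <- diff_sipwb <- numeric(B)
  for (i in seq_len(B)) {
    d <- simulate_pvb_pair(1000, 0.4, 0.6, 0.6, 0.6, 0.6)$pvb
    cca <- estimate_cca(d)$estimates[["sn"]]
    diff_sipw[i] <- estimate_sipw(d, b = 150)$estimates[["sn"]] - cca
    diff_ipb[i] <- estimate_ipb(d, b = 150)$estimates[["sn"]] - cca
    diff_sipwb[i] <- estimate_sipwb(d, b = 150)$estimates[["sn"]] - cca
  }
  expect_lt(abs(mean(diff_sipw)), 0.01)
  expect_lt(abs(mean(diff_ipb)), 0.01)
  expect_lt(abs(mean(diff_sipwb)), 0.01)
})
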