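test_that("propensity fit recovers stratum verification proportions", {
  d <- data_from_counts(tp = 30, fn = 5, fp = 10, tn = 15, u1 = 10, u0 = 30)
  w <- fit_propensity(d)
  expect_equal(unique(w$ps[w$test == 1]), 0.8, tolerance = 1e-6)
  expect_equal(unique(w$ps[w$test == 0]), 0.4, tolerance = 1e-6)

  # equal verification rates -> constant propensity
  d2 <- data_from_counts(tp = 4, fn = 4, fp = 4, tn = 4, u1 = 8, u0 = 8)
  expect_equal(diff(range(fit_propensity(d2)$ps)), 0, tolerance = 1e-6)
})

test_that("propensity fit errors on perfect separation with guidance", {
  all_pos_verified <- data_from_counts(tp = 5, fp = 5, fn = 2, tn = 2, u0 = 4)
  expect_error(fit_propensity(all_pos_verified), "Perfect separation")
  expect_error(fit_propensity(data_from_counts(tp = 2, fn = 2, fp = 2, tn = 2)),
               "verified = 1")
})

test_that("fitted propensities converge to the verification probabilities", {
  set.seed(13)
  d <- simulate_pvb_pair(1e5, 0.4, 0.6, 0.6, 0.8, 0.4)$pvb
  w <- fit_propensity(d)
  for (t in 0:1) {
    lam <- if (t == 1) 0.8 else 0.4
    nt <- sum(d$test == t)
    expect_lt(abs(unique(w$ps[w$test == t]) - lam),
              3 * sqrt(lam * (1 - lam) / nt))
  }
})

test_that("scaled weights normalize the inverse propensities", {
  # 4 verified at PS 0.8 and 2 at PS 0.4: total IPW 10
  d <- data_from_counts(tp = 3, fp = 1, fn = 1, tn = 1, u1 = 1, u0 = 3)
  w <- sipw_weights(d)
  v <- w$verified == 1
  expect_equal(sort(unique(w$ipw[v])), c(1.25, 2.5))
  expect_equal(w$sipw[v & w$test == 1], rep(0.125, 4))
  expect_equal(w$sipw[v & w$test == 0], rep(0.25, 2))
  expect_equal(sum(w$sipw[v]), 1, tolerance = 1e-12)
  expect_true(all(is.na(w$sipw[!v])))
})

test_that("scaled weights sum to one on random datasets", {
  set.seed(14)
  for (i in 1:50) {
    w <- sipw_weights(random_pvb())
    expect_equal(sum(w$sipw[w$verified == 1]), 1, tolerance = 1e-12)
    expect_equal(w$ipw[w$verified == 1], 1 / w$ps[w$verified == 1])
  }
})

test_that("balanced weights follow the rebalancing steps of the algorithm", {
  # verified: 2 diseased and 4 non-diseased; rel_size 1
  d <- tibble::tibble(
    test = c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L),
    disease = c(1L, 1L, 0L, 0L, 0L, 0L, NA, NA),
    verified = c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L)
  )
  w <- sipwb_weights(d, rel_size = 1)
  v <- w$verified == 1
  # RelSizeInit = 4/2 = 2; k rebalances diseased mass to exactly 1/2
  expect_equal(sum(w$sipw[v & w$disease == 1]), 0.5, tolerance = 1e-12)
  expect_equal(sum(w$sipw[v]), 1, tolerance = 1e-12)
})

test_that("balanced weights give diseased mass 1/(1 + rel_size)", {
  set.seed(15)
  for (rel in c(0.5, 1, 3)) {
    for (i in 1:20) {
      w <- sipwb_weights(random_pvb(), rel_size = rel)
      v <- w$verified == 1
      expect_equal(sum(w$sipw[v & w$disease == 1]), 1 / (1 + rel),
                   tolerance = 1e-12)
      expect_equal(sum(w$sipw[v]), 1, tolerance = 1e-12)
    }
  }
})

test_that("balancing at the observed ratio with constant PS is a no-op", {
  d <- tibble::tibble(
    test = rep(c(1L, 0L), 30),
    disease = c(rep(1L, 20), rep(0L, 40)),
    verified = 1L
  )
  # constant propensity: mask five subjects in each test stratum
  drop <- c(1, 2, 13, 14, 25, 26, 37, 38, 49, 50)
  d$verified[drop] <- 0L
  d$disease[drop] <- NA_integer_
  w0 <- sipw_weights(d)
  expect_lt(diff(range(w0$ps)), 1e-10) # construction gives constant PS
  v <- w0$verified == 1
  rel_init <- sum(w0$disease[v] == 0) / sum(w0$disease[v] == 1)
  wb <- sipwb_weights(d, rel_size = rel_init)
  expect_equal(wb$sipw, w0$sipw, tolerance = 1e-10)
})

test_that("draw_valid_resample returns valid restored datasets", {
  set.seed(17)
  w <- sipw_weights(simulate_pvb_pair(120, 0.4, 0.6, 0.6)$pvb)
  for (i in 1:10) {
    rs <- draw_valid_resample(w, size = nrow(w))
    expect_equal(nrow(rs), nrow(w))
    expect_true(is_complete(rs))
    expect_true(is_valid_table(cross_tabulate(rs)))
  }
  # weights degenerate on one cell: no valid resample can exist
  degen <- w
  degen$sipw[degen$verified == 1 & degen$test == 1 & degen$disease == 1] <- 0
  v <- degen$verified == 1
  degen$sipw[v] <- degen$sipw[v] / sum(degen$sipw[v])
  expect_error(draw_valid_resample(degen, size = nrow(w), max_tries = 25),
               "No valid resample")
})

test_that("unconditional inclusion frequencies are proportional to sipw", {
  set.seed(18)
  # one verified subject per (T, D) cell, so cell counts identify subjects
  d <- tibble::tibble(
    test = c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L),
    disease = c(1L, 1L, 0L, 0L, NA, NA, NA, NA),
    verified = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  )
  w <- sipw_weights(d) # PS: T=1 2/3, T=0 2/5 -> unequal weights
  draws <- 4000L
  counts <- numeric(4)
  for (i in seq_len(draws)) {
    rs <- draw_valid_resample(w, size = 6, validate = FALSE)
    cell <- 1L + (1L - rs$test) + 2L * (1L - rs$disease)
    counts <- counts + tabulate(cell, nbins = 4)
  }
  total <- draws * 6
  expected <- w$sipw[w$verified == 1] # rows 1:4 in cell order
  emp <- counts / total
  se <- sqrt(expected * (1 - expected) / total)
  expect_true(all(abs(emp - expected) < 4 * se))
})
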