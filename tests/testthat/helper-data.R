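# Build a subject-level dataset from explicit cell counts.
# verified: named counts tp, fn, fp, tn; unverified: named counts t1, t0.
data_from_counts <- function(tp = 0, fn = 0, fp = 0, tn = 0, u1 = 0, u0 = 0) {
  tibble::tibble(
    test = c(rep(1L, tp), rep(0L, fn), rep(1L, fp), rep(0L, tn),
             rep(1L, u1), rep(0L, u0)),
    disease = c(rep(1L, tp + fn), rep(0L, fp + tn),
                rep(NA_integer_, u1 + u0)),
    verified = c(rep(1L, tp + fn + fp + tn), rep(0L, u1 + u0))
  )
}

# A random valid PVB dataset with randomized scenario parameters, redrawn
# until both test strata are partially verified (so propensity-based
# estimators are well defined).
random_pvb <- function(n = NULL) {
  repeat {
    size <- if (is.null(n)) sample(40:160, 1) else n
    p <- runif(1, 0.15, 0.6)
    sn <- runif(1, 0.3, 0.9)
    sp <- runif(1, 0.4, 0.9)
    d <- simulate_pvb_pair(size, p, sn, sp)$pvb
    part <- vapply(c(0L, 1L), function(t) {
      v <- d$verified[d$test == t]
      length(v) > 0 && any(v == 1L) && any(v == 0L)
    }, logical(1))
    if (all(part)) return(d)
  }
}

# Brute-force oracle: expected sensitivity of a valid weighted resample of
# `size` draws from the verified subjects, enumerating every tuple and
# weighting it by the product of per-subject sipw probabilities,
# conditioned on the resample table having all four cells occupied.
enumerate_expected_sn <- function(data, size) {
  v <- which(data$verified == 1L)
  w <- data$sipw[v]
  cell <- 1L + (1L - data$test[v]) + 2L * (1L - data$disease[v])
  n1 <- length(v)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n1)), size)))
  total <- 0
  mass <- 0
  for (r in seq_len(nrow(grid))) {
    pick <- grid[r, ]
    pr <- prod(w[pick])
    cells <- tabulate(cell[pick], nbins = 4)
    if (all(cells > 0)) {
      sn <- cells[1] / (cells[1] + cells[2])
      total <- total + pr * sn
      mass <- mass + pr
    }
  }
  total / mass
}
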