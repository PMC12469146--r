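#' Multinomial cell probabilities of the test-by-disease table
#'
#' Under the data-generating model, the joint distribution of (test,
#' disease) for one subject is multinomial over the four cells with
#' probabilities driven by prevalence `p`, sensitivity `sn` and specificity
#' `sp`:
#' \deqn{\pi_1 = Sn \cdot p,\quad \pi_2 = (1-Sn)\,p,\quad
#'       \pi_3 = (1-Sp)(1-p),\quad \pi_4 = Sp\,(1-p).}
#'
#' @param p True disease prevalence P(D=1), in (0,1).
#' @param sn True sensitivity P(T=1|D=1), in (0,1).
#' @param sp True specificity P(T=0|D=0), in (0,1).
#' @return Named numeric vector `c(pi1, pi2, pi3, pi4)` summing to 1, in
#'   the cell order TP, FN, FP, TN.
#' @export
#' @examples
#' cell_probabilities(0.4, 0.3, 0.6)
cell_probabilities <- function(p, sn, sp) {
  check_prob(p, "p"); check_prob(sn, "sn"); check_prob(sp, "sp")
  c(pi1 = sn * p, pi2 = (1 - sn) * p,
    pi3 = (1 - sp) * (1 - p), pi4 = sp * (1 - p))
}

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    abort(paste0("`", name, "` must be a single probability strictly in (0, 1)."))
  }
  invisible(x)
}

#' Simulate a complete (fully verified) dataset
#'
#' Draws `n` subjects from the multinomial test-by-disease model: cell
#' labels 1-4 are sampled with probabilities [cell_probabilities()] and
#' mapped to (T, D) as 1 -> (1,1), 2 -> (0,1), 3 -> (1,0), 4 -> (0,0).
#' Every subject is verified.
#'
#' @inheritParams cell_probabilities
#' @param n Number of subjects (>= 4).
#' @return A complete verification dataset tibble.
#' @export
#' @examples
#' set.seed(1)
#' simulate_complete(10, p = 0.4, sn = 0.3, sp = 0.6)
simulate_complete <- function(n, p, sn, sp) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 4 || n != round(n)) {
    abort("`n` must be a single integer >= 4.")
  }
  probs <- cell_probabilities(p, sn, sp)
  cell <- sample.int(4L, size = n, replace = TRUE, prob = probs)
  tibble(
    test = as.integer(cell %in% c(1L, 3L)),
    disease = as.integer(cell %in% c(1L, 2L)),
    verified = 1L
  )
}

#' Mask disease status under MAR verification
#'
#' Applies the missing-at-random verification mechanism: each subject is
#' verified with probability `lambda1` if test-positive and `lambda0` if
#' test-negative, independently of disease status given the test result.
#' Disease status is set to `NA` for unverified subjects; test results are
#' unchanged.
#'
#' @param data A complete verification dataset.
#' @param lambda1 P(V=1 | T=1), in \[0,1\].
#' @param lambda0 P(V=1 | T=0), in \[0,1\].
#' @return A PVB verification dataset tibble.
#' @export
mask_mar <- function(data, lambda1 = 0.8, lambda0 = 0.4) {
  data <- pvb_data(data)
  if (!is_complete(data)) {
    abort("`data` must be a complete dataset (all subjects verified).")
  }
  check_prob(lambda1, "lambda1", open = FALSE)
  check_prob(lambda0, "lambda0", open = FALSE)
  pr <- ifelse(data$test == 1L, lambda1, lambda0)
  v <- rbinom(nrow(data), 1L, pr)
  data$verified <- as.integer(v)
  data$disease[v == 0L] <- NA_integer_
  data
}

#' Simulate a screened (complete, PVB) dataset pair
#'
#' Generates a complete dataset and its MAR-masked PVB counterpart,
#' repeating the whole draw until both the complete table and the
#' verified-only table of the PVB dataset are *valid* (all four
#' test-by-disease cells strictly positive). This mirrors the screening
#' used in the simulation study: invalid datasets are discarded.
#'
#' @inheritParams simulate_complete
#' @inheritParams mask_mar
#' @param max_tries Retry budget before giving up (default 10000).
#' @return A list with elements `complete` and `pvb` (tibbles) and
#'   attribute `attempts` (number of draws used).
#' @export
#' @examples
#' set.seed(1)
#' pair <- simulate_pvb_pair(200, p = 0.4, sn = 0.3, sp = 0.6)
#' cross_tabulate(pair$pvb, verified_only = TRUE)
simulate_pvb_pair <- function(n, p, sn, sp, lambda1 = 0.8, lambda0 = 0.4,
                              max_tries = 10000L) {
  for (attempt in seq_len(max_tries)) {
    complete <- simulate_complete(n, p, sn, sp)
    if (!is_valid_table(cross_tabulate(complete))) next
    pvb <- mask_mar(complete, lambda1, lambda0)
    if (sum(pvb$verified) == 0L) next
    if (!is_valid_table(cross_tabulate(pvb, verified_only = TRUE))) next
    out <- list(complete = complete, pvb = pvb)
    attr(out, "attempts") <- attempt
    return(out)
  }
  abort(paste0(
    "Could not generate a valid dataset pair in ", max_tries, " attempts ",
    "(scenario p = ", p, ", sn = ", sn, ", sp = ", sp, ", n = ", n,
    "); the scenario likely produces empty test-by-disease cells."
  ))
}

#' Expected overall verification rate of a scenario
#'
#' Analytic P(V=1) under the MAR mechanism:
#' `lambda1 * P(T=1) + lambda0 * P(T=0)` with
#' `P(T=1) = sn * p + (1-sp) * (1-p)`.
#'
#' @inheritParams cell_probabilities
#' @inheritParams mask_mar
#' @return Probability of verification for a random subject.
#' @export
#' @examples
#' expected_verification_rate(0.4, 0.3, 0.6) # 0.544
expected_verification_rate <- function(p, sn, sp, lambda1 = 0.8, lambda0 = 0.4) {
  check_prob(p, "p"); check_prob(sn, "sn"); check_prob(sp, "sp")
  check_prob(lambda1, "lambda1", open = FALSE)
  check_prob(lambda0, "lambda0", open = FALSE)
  pt1 <- sn * p + (1 - sp) * (1 - p)
  lambda1 * pt1 + lambda0 * (1 - pt1)
}
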