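#' Fit the verification propensity model
#'
#' Estimates the propensity score PS = P(V=1 | T), the logistic regression
#' of `verified` on `test`. With a single binary covariate the model is
#' saturated, so its maximum-likelihood fit is available in closed form:
#' the fitted propensity in each test stratum is exactly the observed
#' verification proportion of that stratum (the package uses the closed
#' form rather than an iterative fit, so downstream algebraic identities
#' hold to machine precision).
#'
#' @param data A PVB verification dataset.
#' @return The input tibble with an added numeric column `ps` (fitted
#'   propensity per subject, strictly inside (0,1)).
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_pvb_pair(200, 0.4, 0.3, 0.6)$pvb
#' head(fit_propensity(d))
fit_propensity <- function(data) {
  data <- pvb_data(data)
  if (all(data$verified == 1L) || all(data$verified == 0L)) {
    abort(paste0("Cannot fit the verification propensity model: all subjects ",
                 "have verified = ", data$verified[1],
                 ". Both verified and unverified subjects are required."))
  }
  for (t in c(0L, 1L)) {
    stratum <- data$verified[data$test == t]
    if (length(stratum) == 0) {
      abort(paste0("No subjects with test = ", t,
                   "; the propensity P(V=1|T=", t, ") is undefined."))
    }
    if (all(stratum == 1L) || all(stratum == 0L)) {
      abort(paste0(
        "Perfect separation in the propensity model: every subject with ",
        "test = ", t, " has verified = ", stratum[1], ". Inverse-probability ",
        "weighting needs verification probabilities strictly inside (0, 1) in ",
        "both test strata; consider an estimator that does not weight by the ",
        "propensity score."
      ))
    }
  }
  p1 <- mean(data$verified[data$test == 1L])
  p0 <- mean(data$verified[data$test == 0L])
  data$ps <- ifelse(data$test == 1L, p1, p0)
  data
}

#' Scaled inverse probability weights
#'
#' Computes, for each verified subject, the inverse probability weight
#' IPW = 1 / PS and its scaled version SIPW = IPW / sum(IPW over verified),
#' so that the SIPW values form a resampling distribution over the verified
#' subjects (they sum to one). Unverified subjects get `NA` weights.
#'
#' @param data A PVB verification dataset; the propensity column `ps` is
#'   fitted with [fit_propensity()] if absent.
#' @return The input tibble with added columns `ps`, `ipw`, `sipw`.
#' @export
sipw_weights <- function(data) {
  if (!("ps" %in% names(data))) data <- fit_propensity(data)
  if (any(data$ps <= 0 | data$ps >= 1)) {
    abort("Propensity scores must lie strictly inside (0, 1).")
  }
  v <- data$verified == 1L
  data$ipw <- ifelse(v, 1 / data$ps, NA_real_)
  data$sipw <- ifelse(v, data$ipw / sum(data$ipw[v]), NA_real_)
  data
}

#' Class-balanced scaled inverse probability weights
#'
#' The SIPW-B weighting rebalances the probability mass between diseased
#' and non-diseased verified subjects to a chosen control:case ratio before
#' scaling, mimicking a case-control design inside the resampling step:
#'
#' 1. IPW = 1/PS for verified subjects;
#' 2. multiply the IPW of diseased subjects by the observed relative size
#'    `RelSizeInit = n(D=0) / n(D=1)` (counted among verified subjects);
#' 3. compute `k` = sum of IPW over controls / sum of IPW over cases and
#'    multiply the case IPW by `k / rel_size`;
#' 4. scale all weights to sum to one.
#'
#' After these steps the diseased subjects carry total resampling mass
#' exactly `1 / (1 + rel_size)` (0.5 for the default 1:1 ratio).
#'
#' @inheritParams sipw_weights
#' @param rel_size Desired control:case relative size `n(D=0) : n(D=1)`
#'   (positive; default 1 for a 1:1 ratio).
#' @return The input tibble with added columns `ps`, `ipw`, `sipw`, where
#'   `ipw` is the rebalanced weight.
#' @export
sipwb_weights <- function(data, rel_size = 1) {
  if (!is.numeric(rel_size) || length(rel_size) != 1 || is.na(rel_size) ||
      rel_size <= 0) {
    abort("`rel_size` must be a single positive number.")
  }
  if (!("ps" %in% names(data))) data <- fit_propensity(data)
  v <- data$verified == 1L
  case <- v & data$disease == 1L
  ctrl <- v & data$disease == 0L
  if (!any(case) || !any(ctrl)) {
    abort(paste0("SIPW-B needs verified subjects in both disease classes; ",
                 "found ", sum(case), " diseased and ", sum(ctrl),
                 " non-diseased verified subjects."))
  }
  ipw <- ifelse(v, 1 / data$ps, NA_real_)
  rel_init <- sum(ctrl) / sum(case)
  ipw[case] <- ipw[case] * rel_init
  k <- sum(ipw[ctrl]) / sum(ipw[case])
  ipw[case] <- ipw[case] * (k / rel_size)
  data$ipw <- ipw
  data$sipw <- ifelse(v, ipw / sum(ipw[v]), NA_real_)
  data
}

# total SIPW mass in each of the 4 (T,D) cells; names tp, fn, fp, tn
cell_masses <- function(data) {
  idx <- cell_index(data)
  v <- data$verified == 1L
  q <- vapply(1:4, function(k) sum(data$sipw[v & idx == k]), numeric(1))
  setNames(q, c("tp", "fn", "fp", "tn"))
}

#' Draw one valid weighted resample
#'
#' Samples `size` verified subjects with replacement, with per-subject
#' probabilities given by the `sipw` column, and rejects any draw whose
#' test-by-disease table has an empty cell (redrawing until a valid
#' resample is obtained or the budget is exhausted). This is the
#' subject-level resampling step shared by the IPB, SIPW and SIPW-B
#' estimators; it returns a restored complete dataset.
#'
#' @param data A PVB verification dataset carrying `sipw` weights (see
#'   [sipw_weights()] / [sipwb_weights()]).
#' @param size Number of subjects to draw (>= 4).
#' @param max_tries Rejection budget (default 1000 redraws).
#' @param validate If `FALSE`, skip the validity screen and return the
#'   first draw (used to study the unconditional resampling distribution).
#' @return A complete verification dataset tibble of `size` rows.
#' @export
draw_valid_resample <- function(data, size, max_tries = 1000L, validate = TRUE) {
  if (!("sipw" %in% names(data))) {
    abort("`data` must carry a `sipw` column; call sipw_weights() or sipwb_weights() first.")
  }
  if (size < 4) abort("`size` must be at least 4 to allow a valid 2x2 table.")
  v <- which(data$verified == 1L)
  w <- data$sipw[v]
  for (try in seq_len(max_tries)) {
    rows <- v[sample.int(length(v), size, replace = TRUE, prob = w)]
    out <- data[rows, c("test", "disease", "verified")]
    if (!validate || is_valid_table(cross_tabulate(out))) return(out)
  }
  abort(paste0("No valid resample in ", max_tries, " draws; the weighted ",
               "resampling distribution concentrates on fewer than four ",
               "test-by-disease cells."))
}

# Draw b valid 2x2 tables from the resampling distribution.
#
# Because the propensity model conditions on T only (and SIPW-B rebalances
# by D), every subject in the same (T,D) cell carries the same sipw weight;
# the table of a size-`size` weighted resample is therefore exactly
# Multinomial(size, q) with q the per-cell sipw mass. Sampling tables
# directly is equivalent in distribution to subject-level resampling and is
# what the estimators use. Invalid tables (any empty cell) are rejected and
# redrawn, as in the subject-level algorithm.
draw_valid_tables <- function(q, size, b, max_tries = 1000L * b) {
  stopifnot(length(q) == 4)
  if (any(q <= 0)) {
    abort(paste0("Resampling weights put zero mass on ",
                 sum(q <= 0), " test-by-disease cell(s); ",
                 "no valid resample is possible."))
  }
  out <- matrix(0, nrow = 4, ncol = 0)
  tries <- 0L
  while (ncol(out) < b) {
    need <- b - ncol(out)
    batch <- rmultinom(need, size, q)
    tries <- tries + need
    keep <- colSums(batch == 0) == 0
    out <- cbind(out, batch[, keep, drop = FALSE])
    if (ncol(out) < b && tries >= max_tries) {
      abort(paste0("Rejection budget exhausted: only ", ncol(out), " of ", b,
                   " valid resamples after ", tries, " draws."))
    }
  }
  out[, seq_len(b), drop = FALSE]
}
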