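#' Full data analysis (benchmark)
#'
#' Sensitivity and specificity from a complete, fully verified dataset.
#' This is the ideal benchmark an unbiased correction method should match;
#' it cannot be applied to PVB data.
#'
#' @param data A complete verification dataset.
#' @return A `pvb_fit`.
#' @export
#' @examples
#' set.seed(1)
#' estimate_fda(simulate_complete(200, 0.4, 0.3, 0.6))
estimate_fda <- function(data) {
  data <- pvb_data(data)
  if (anyNA(data$disease)) {
    abort(paste0("Full data analysis requires a complete dataset; this one has ",
                 sum(is.na(data$disease)), " unverified subject(s). ",
                 "Use a PVB correction method instead."))
  }
  acc <- estimate_accuracy(cross_tabulate(data))
  new_pvb_fit("fda", acc[["sn"]], acc[["sp"]], nrow(data), sum(data$verified))
}

#' Complete case analysis (uncorrected)
#'
#' Sensitivity and specificity computed from verified subjects only.
#' Under test-dependent verification this is biased: test-positive
#' subjects are over-represented among the verified, inflating Sn and
#' deflating Sp.
#'
#' @param data A PVB verification dataset.
#' @return A `pvb_fit`.
#' @export
estimate_cca <- function(data) {
  data <- pvb_data(data)
  tab <- cross_tabulate(data, verified_only = TRUE)
  acc <- estimate_accuracy(tab)
  new_pvb_fit("cca", acc[["sn"]], acc[["sp"]], nrow(data), sum(data$verified))
}

#' Begg-Greenes correction
#'
#' Corrects PVB by re-expressing Sn and Sp through P(D | T): under MAR the
#' disease rate among verified subjects within a test stratum estimates the
#' stratum's true disease rate, and the test-stratum sizes `s_t` are
#' observed for everyone. With `d_t = P(D=1 | T=t, V=1)`:
#' \deqn{Sn = \frac{s_1 d_1}{s_1 d_1 + s_0 d_0}, \qquad
#'       Sp = \frac{s_0 (1-d_0)}{s_1 (1-d_1) + s_0 (1-d_0)}.}
#'
#' @param data A PVB verification dataset.
#' @return A `pvb_fit`.
#' @export
estimate_bg <- function(data) {
  data <- pvb_data(data)
  s1 <- sum(data$test == 1L)
  s0 <- sum(data$test == 0L)
  if (s1 == 0 || s0 == 0) {
    abort("Both test strata must be nonempty for the Begg-Greenes correction.")
  }
  v <- data$verified == 1L
  if (!any(v & data$test == 1L) || !any(v & data$test == 0L)) {
    abort("Each test stratum needs at least one verified subject to estimate P(D=1|T).")
  }
  d1 <- mean(data$disease[v & data$test == 1L])
  d0 <- mean(data$disease[v & data$test == 0L])
  if (d1 == 0 && d0 == 0) {
    abort("Sensitivity is undefined: no verified subject is diseased.")
  }
  if (d1 == 1 && d0 == 1) {
    abort("Specificity is undefined: every verified subject is diseased.")
  }
  sn <- s1 * d1 / (s1 * d1 + s0 * d0)
  sp <- s0 * (1 - d0) / (s1 * (1 - d1) + s0 * (1 - d0))
  new_pvb_fit("bg", sn, sp, nrow(data), sum(v))
}

#' Inverse probability weighting estimator
#'
#' Weights each verified subject by the inverse of its verification
#' propensity (fitted by logistic regression of V on T) and computes Sn/Sp
#' from the weighted test-by-disease table. For a binary test the
#' propensity model is saturated, and the IPWE point estimates coincide
#' exactly with the Begg-Greenes correction.
#'
#' @param data A PVB verification dataset.
#' @return A `pvb_fit`.
#' @export
estimate_ipwe <- function(data) {
  data <- pvb_data(data)
  w <- sipw_weights(data)
  v <- w$verified == 1L
  idx <- cell_index(w)
  cells <- vapply(1:4, function(k) sum(w$ipw[v & idx == k]), numeric(1))
  acc <- estimate_accuracy(new_xtab(cells))
  new_pvb_fit("ipwe", acc[["sn"]], acc[["sp"]], nrow(data), sum(v))
}
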