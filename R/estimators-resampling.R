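# Shared engine for the three weighted-resampling estimators: build the
# per-cell resampling mass, draw b valid tables, estimate Sn/Sp per table
# and average.
resample_estimate <- function(data, method, size, b, weights_fn, settings) {
  if (b < 1) abort("`b` must be at least 1.")
  w <- weights_fn(pvb_data(data))
  q <- cell_masses(w)
  tabs <- draw_valid_tables(q, size = size, b = b)
  sn <- tabs[1, ] / (tabs[1, ] + tabs[2, ])
  sp <- tabs[4, ] / (tabs[3, ] + tabs[4, ])
  new_pvb_fit(method, mean(sn), mean(sp), nrow(w), sum(w$verified == 1L),
              boot = list(sn = sn, sp = sp),
              settings = c(settings, list(b = b, resample_size = size)))
}

#' Scaled inverse probability weighted resampling (SIPW)
#'
#' Corrects PVB by resampling the verified subjects with replacement, with
#' per-subject probabilities proportional to the inverse of the
#' verification propensity (the scaled weights of [sipw_weights()]). Each
#' of the `b` resamples restores the *full* sample size `n` (verified plus
#' unverified), so downstream analyses see a complete dataset whose
#' distribution is corrected for the verification mechanism. Resamples with
#' an empty test-by-disease cell are rejected and redrawn. The point
#' estimate is the mean of the per-resample Sn/Sp.
#'
#' @param data A PVB verification dataset.
#' @param b Number of valid resamples (default 1000).
#' @return A `pvb_fit` whose `boot` element holds the per-resample Sn and
#'   Sp lists.
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_pvb_pair(200, 0.4, 0.3, 0.6)$pvb
#' estimate_sipw(d, b = 100)
estimate_sipw <- function(data, b = 1000L) {
  resample_estimate(data, "sipw", size = nrow(data), b = b,
                    weights_fn = sipw_weights, settings = list())
}

#' Balanced scaled inverse probability weighted resampling (SIPW-B)
#'
#' As [estimate_sipw()], but the resampling weights are first rebalanced so
#' that diseased subjects carry probability mass `1 / (1 + rel_size)`
#' (see [sipwb_weights()]), mimicking a case-control design with
#' control:case ratio `rel_size`. This trades specificity precision for
#' sensitivity precision, which pays off when prevalence is low.
#'
#' @inheritParams estimate_sipw
#' @param rel_size Desired control:case relative size (default 1).
#' @return A `pvb_fit` with per-resample lists in `boot`.
#' @export
estimate_sipwb <- function(data, b = 1000L, rel_size = 1) {
  resample_estimate(data, "sipwb", size = nrow(data), b = b,
                    weights_fn = function(d) sipwb_weights(d, rel_size),
                    settings = list(rel_size = rel_size))
}

#' Inverse probability bootstrap (IPB)
#'
#' The precursor of SIPW: bootstrap samples of the *verified* subjects only
#' (size `n1`), drawn with the same scaled inverse-probability weights, each
#' screened for a valid test-by-disease table. Because resamples match the
#' original verified size they are genuine bootstrap samples, so the
#' retained per-resample lists can be used directly for percentile
#' confidence intervals ([ci_ipb_native()]). Its standard error exceeds
#' SIPW's because only the verified fraction of the data is restored.
#'
#' @inheritParams estimate_sipw
#' @return A `pvb_fit` with per-resample lists in `boot`.
#' @export
estimate_ipb <- function(data, b = 1000L) {
  data <- pvb_data(data)
  resample_estimate(data, "ipb", size = sum(data$verified == 1L), b = b,
                    weights_fn = sipw_weights, settings = list())
}
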