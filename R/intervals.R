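new_interval <- function(term, lower, upper, level, ci_method, replicates = NA_integer_) {
  tibble(term = term,
         conf.low = pmin(pmax(lower, 0), 1),
         conf.high = pmin(pmax(upper, 0), 1),
         level = level, ci_method = ci_method,
         replicates = as.integer(replicates))
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number strictly inside (0, 1).")
  }
}

#' Wald confidence interval for a proportion
#'
#' The normal-approximation interval `p +/- z * sqrt(p(1-p)/denom)`,
#' truncated to \[0, 1\].
#'
#' @param p_hat Estimated proportion.
#' @param denom Effective denominator (number of subjects the proportion
#'   was computed from).
#' @param level Confidence level (default 0.95).
#' @param term Label for the output row (default `"estimate"`).
#' @return A one-row interval tibble with columns `term`, `conf.low`,
#'   `conf.high`, `level`, `ci_method`.
#' @export
#' @examples
#' ci_wald(0.5, 100)
ci_wald <- function(p_hat, denom, level = 0.95, term = "estimate") {
  check_level(level)
  if (!is.numeric(denom) || length(denom) != 1 || is.na(denom) || denom <= 0) {
    abort("`denom` must be a positive count.")
  }
  if (p_hat < 0 || p_hat > 1) abort("`p_hat` must lie in [0, 1].")
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / denom)
  new_interval(term, p_hat - half, p_hat + half, level, "wald")
}

#' Bootstrap percentile confidence interval
#'
#' Nonparametric bootstrap of whole subject records: `R` resamples of the
#' full dataset (size n, with replacement, so the missingness pattern is
#' resampled together with the data), re-applying the estimator to each.
#' Resamples on which the estimator fails (for example, an empty verified
#' cell) are redrawn under a budget. The interval is the pair of empirical
#' quantiles at `(1 - level)/2` and `(1 + level)/2`, using linear
#' interpolation (R's default quantile type 7).
#'
#' @param data A PVB verification dataset.
#' @param estimator A function `data -> pvb_fit` (for example
#'   `estimate_ipwe`, or `\(d) estimate_sipw(d, b = 200)`).
#' @param R Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param max_tries Total resampling budget (default `10 * R`).
#' @return A two-row interval tibble (terms `sn`, `sp`).
#' @export
ci_boot_percentile <- function(data, estimator, R = 1000L, level = 0.95,
                               max_tries = 10L * R) {
  check_level(level)
  data <- pvb_data(data)
  # the estimator must succeed on the original data
  estimator(data)
  n <- nrow(data)
  sn <- numeric(0); sp <- numeric(0)
  tries <- 0L
  while (length(sn) < R) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(paste0("Bootstrap budget exhausted: only ", length(sn), " of ", R,
                   " replicates succeeded after ", max_tries, " draws."))
    }
    boot <- data[sample.int(n, n, replace = TRUE), ]
    fit <- tryCatch(estimator(boot), error = function(e) NULL)
    if (is.null(fit)) next
    sn <- c(sn, fit$estimates[["sn"]])
    sp <- c(sp, fit$estimates[["sp"]])
  }
  probs <- c((1 - level) / 2, (1 + level) / 2)
  qs_sn <- quantile(sn, probs, names = FALSE, type = 7)
  qs_sp <- quantile(sp, probs, names = FALSE, type = 7)
  bind_rows(
    new_interval("sn", qs_sn[1], qs_sn[2], level, "bootstrap percentile", R),
    new_interval("sp", qs_sp[1], qs_sp[2], level, "bootstrap percentile", R)
  )
}

#' Native percentile interval from IPB resamples
#'
#' The IPB resamples are valid bootstrap samples of the verified subset, so
#' its confidence interval needs no extra resampling: the interval is read
#' off the empirical quantiles of the stored per-resample estimates.
#'
#' @param fit A `pvb_fit` from [estimate_ipb()] with at least 100 resamples.
#' @param level Confidence level (default 0.95).
#' @return A two-row interval tibble (terms `sn`, `sp`).
#' @export
ci_ipb_native <- function(fit, level = 0.95) {
  check_level(level)
  if (is.null(fit$boot)) {
    abort("`fit` carries no per-resample estimates; run estimate_ipb() first.")
  }
  b <- length(fit$boot$sn)
  if (b < 100) {
    abort(paste0("At least 100 resamples are needed for a percentile ",
                 "interval; this fit has ", b, "."))
  }
  probs <- c((1 - level) / 2, (1 + level) / 2)
  qs_sn <- quantile(fit$boot$sn, probs, names = FALSE, type = 7)
  qs_sp <- quantile(fit$boot$sp, probs, names = FALSE, type = 7)
  bind_rows(
    new_interval("sn", qs_sn[1], qs_sn[2], level, "IPB percentile", b),
    new_interval("sp", qs_sp[1], qs_sp[2], level, "IPB percentile", b)
  )
}

# Rubin's rules for one pooled proportion
rubin_pool <- function(est, within, level, term) {
  m <- length(est)
  qbar <- mean(est)
  wbar <- mean(within)
  bv <- if (m > 1) sum((est - qbar)^2) / (m - 1) else 0
  total <- wbar + (1 + 1 / m) * bv
  if (total == 0) {
    return(new_interval(term, qbar, qbar, level, "Rubin", m))
  }
  if (bv == 0) {
    half <- qnorm((1 + level) / 2) * sqrt(total)
  } else {
    df <- (m - 1) * (1 + wbar / ((1 + 1 / m) * bv))^2
    half <- qt((1 + level) / 2, df = df) * sqrt(total)
  }
  new_interval(term, qbar - half, qbar + half, level, "Rubin", m)
}

#' Rubin's rules confidence interval for multiple imputation
#'
#' Pools the per-imputation estimates and their within-imputation Wald
#' variances: total variance `W + (1 + 1/m) B` with `W` the mean within
#' variance and `B` the between-imputation variance, and a t interval on
#' Rubin's degrees of freedom `(m-1) (1 + W / ((1+1/m) B))^2`. When the
#' imputations are identical (`B = 0`) this collapses to the Wald interval
#' of a single completed dataset.
#'
#' @param fit A `pvb_fit` from [estimate_mi()].
#' @param level Confidence level (default 0.95).
#' @return A two-row interval tibble (terms `sn`, `sp`).
#' @export
ci_rubin <- function(fit, level = 0.95) {
  check_level(level)
  if (is.null(fit$imputations)) {
    abort("`fit` carries no imputation draws; run estimate_mi() first.")
  }
  d <- fit$imputations
  if (nrow(d) < 2) abort("Rubin's rules need at least 2 imputations.")
  bind_rows(
    rubin_pool(d$sn, d$var_sn, level, "sn"),
    rubin_pool(d$sp, d$var_sp, level, "sp")
  )
}
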