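#' Correct partial verification bias with a chosen method
#'
#' One front door to all estimators in the package. Dispatches on `method`,
#' optionally attaches a 95% (or other level) confidence interval, and
#' returns a `pvb_fit` that [tidy()] turns into a tibble.
#'
#' Interval choices: `"wald"` (normal approximation on the verified
#' denominators; natural for CCA), `"boot"` (nonparametric bootstrap
#' percentile, re-running the estimator on `R` resamples of the full
#' dataset), `"rubin"` (Rubin's rules; MI only), `"native"` (percentile of
#' the stored IPB resamples; IPB only), or `"none"`.
#'
#' @param data A verification dataset (see [pvb_data()]).
#' @param method One of `"fda"`, `"cca"`, `"bg"`, `"ipwe"`, `"mi"`,
#'   `"ipb"`, `"sipw"`, `"sipwb"`.
#' @param ci Interval type: `"none"`, `"wald"`, `"boot"`, `"rubin"`,
#'   `"native"`.
#' @param b Resamples for IPB/SIPW/SIPW-B (default 1000).
#' @param m Imputations for MI (default 100).
#' @param rel_size Control:case relative size for SIPW-B (default 1).
#' @param R Bootstrap replicates when `ci = "boot"` (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed set before any random draws.
#' @return A `pvb_fit`.
#' @export
#' @examples
#' set.seed(7)
#' d <- simulate_pvb_pair(300, 0.4, 0.6, 0.9)$pvb
#' tidy(pvb_correct(d, "bg"))
pvb_correct <- function(data,
                        method = c("sipw", "sipwb", "ipb", "bg", "ipwe",
                                   "mi", "cca", "fda"),
                        ci = c("none", "wald", "boot", "rubin", "native"),
                        b = 1000L, m = 100L, rel_size = 1, R = 1000L,
                        level = 0.95, seed = NULL) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  if (!is.null(seed)) set.seed(seed)
  data <- pvb_data(data)

  estimator <- switch(
    method,
    fda = estimate_fda,
    cca = estimate_cca,
    bg = estimate_bg,
    ipwe = estimate_ipwe,
    mi = function(d) estimate_mi(d, m = m),
    ipb = function(d) estimate_ipb(d, b = b),
    sipw = function(d) estimate_sipw(d, b = b),
    sipwb = function(d) estimate_sipwb(d, b = b, rel_size = rel_size)
  )
  fit <- estimator(data)

  fit$intervals <- switch(
    ci,
    none = NULL,
    wald = {
      v <- data[data$verified == 1L, ]
      bind_rows(
        ci_wald(fit$estimates[["sn"]], sum(v$disease == 1L), level, term = "sn"),
        ci_wald(fit$estimates[["sp"]], sum(v$disease == 0L), level, term = "sp")
      )
    },
    boot = ci_boot_percentile(data, estimator, R = R, level = level),
    rubin = {
      if (method != "mi") abort("`ci = \"rubin\"` is only available for method = \"mi\".")
      ci_rubin(fit, level = level)
    },
    native = {
      if (method != "ipb") abort("`ci = \"native\"` is only available for method = \"ipb\".")
      ci_ipb_native(fit, level = level)
    }
  )
  if (!is.null(fit$intervals)) {
    contained <- fit$intervals$conf.low <= fit$estimates &
      fit$estimates <= fit$intervals$conf.high
    if (!all(contained)) {
      warn(paste0("Percentile interval does not contain the point estimate ",
                  "for: ", paste(fit$intervals$term[!contained], collapse = ", "),
                  " (degenerate resamples); reported as-is."))
    }
  }
  fit
}
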