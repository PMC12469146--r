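#' Monte Carlo bias of an estimator
#'
#' Mean of the replicate estimates minus the true value.
#'
#' @param estimates Numeric vector of per-replication estimates.
#' @param truth True parameter value.
#' @return `mean(estimates) - truth`.
#' @export
sim_bias <- function(estimates, truth) {
  if (length(estimates) == 0) abort("`estimates` must be nonempty.")
  mean(estimates) - truth
}

#' Monte Carlo standard error of an estimator
#'
#' Between-replication sample standard deviation (denominator B - 1).
#'
#' @param estimates Numeric vector of per-replication estimates (length >= 2).
#' @return Sample standard deviation.
#' @export
sim_se <- function(estimates) {
  if (length(estimates) < 2) abort("`estimates` must have length >= 2.")
  sd(estimates)
}

# Pooled standard deviation of the individual per-resample estimates across
# replications, from per-replication means and within-replication variances
# (each over b resamples). Exact SD of the B*b pooled per-resample values:
#   SS_total = sum_i (b-1) s_i^2 + b * sum_i (m_i - grand)^2, over (B*b - 1).
pooled_resample_sd <- function(means, within_var, b) {
  B <- length(means)
  grand <- mean(means)
  ss <- sum((b - 1) * within_var) + b * sum((means - grand)^2)
  sqrt(ss / (B * b - 1))
}

all_methods <- function() c("fda", "cca", "bg", "ipwe", "mi", "ipb", "sipw", "sipwb")

#' Run one simulation scenario
#'
#' Generates `B` screened (complete, PVB) dataset pairs for one scenario and
#' applies the requested methods: full data analysis to the complete
#' datasets, every other method to the PVB datasets. Returns per-method
#' mean, bias and standard error for sensitivity and specificity.
#'
#' A method that fails on a particular dataset (for example, perfect
#' separation) contributes nothing for that replication; the count of such
#' failures is reported in the `note` column and the summary uses the
#' replications that succeeded.
#'
#' For the resampling estimators (IPB, SIPW, SIPW-B) the reported standard
#' error is the dispersion of the *individual* valid-resample estimates
#' pooled over the `B` replications (exact pooled-variance formula from the
#' per-replication means and within-replication variances), so it includes
#' the per-resample sampling noise on top of the between-dataset spread.
#' This is the quantity the study design tracks for these methods; the bias
#' column always uses the b-averaged point estimates. For all other methods
#' the standard error is the plain between-replication standard deviation.
#'
#' @param p,sn,sp True prevalence, sensitivity and specificity.
#' @param n Sample size per dataset.
#' @param methods Character vector of methods (see [pvb_correct()]);
#'   default all eight.
#' @param B Number of simulation replications (default 500).
#' @param b Resamples for IPB/SIPW/SIPW-B (default 1000).
#' @param m Imputations for MI (default 100).
#' @param rel_size Control:case relative size for SIPW-B (default 1).
#' @param lambda1,lambda0 Verification probabilities P(V=1|T=1), P(V=1|T=0).
#' @param seed Optional integer seed.
#' @return A tibble with one row per method: scenario columns (`p`,
#'   `sn_true`, `sp_true`, `n`, `B`), `method`, `mean_sn`, `bias_sn`,
#'   `se_sn`, `mean_sp`, `bias_sp`, `se_sp`, `note`.
#' @export
#' @examples
#' run_scenario(0.4, 0.3, 0.6, n = 200, methods = c("fda", "cca", "bg"),
#'              B = 20, seed = 1)
run_scenario <- function(p, sn, sp, n, methods = all_methods(), B = 500L,
                         b = 1000L, m = 100L, rel_size = 1,
                         lambda1 = 0.8, lambda0 = 0.4, seed = NULL) {
  if (length(methods) == 0 || B < 1) {
    return(empty_performance())
  }
  methods <- match.arg(methods, all_methods(), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)

  resampling <- c("ipb", "sipw", "sipwb")
  acc <- lapply(setNames(methods, methods), function(mth) {
    list(sn = rep(NA_real_, B), sp = rep(NA_real_, B),
         wv_sn = rep(NA_real_, B), wv_sp = rep(NA_real_, B))
  })
  failures <- setNames(integer(length(methods)), methods)

  for (i in seq_len(B)) {
    pair <- simulate_pvb_pair(n, p, sn, sp, lambda1, lambda0)
    for (mth in methods) {
      fit <- tryCatch(
        switch(mth,
               fda = estimate_fda(pair$complete),
               cca = estimate_cca(pair$pvb),
               bg = estimate_bg(pair$pvb),
               ipwe = estimate_ipwe(pair$pvb),
               mi = estimate_mi(pair$pvb, m = m),
               ipb = estimate_ipb(pair$pvb, b = b),
               sipw = estimate_sipw(pair$pvb, b = b),
               sipwb = estimate_sipwb(pair$pvb, b = b, rel_size = rel_size)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        failures[[mth]] <- failures[[mth]] + 1L
      } else {
        acc[[mth]]$sn[i] <- fit$estimates[["sn"]]
        acc[[mth]]$sp[i] <- fit$estimates[["sp"]]
        if (mth %in% resampling) {
          acc[[mth]]$wv_sn[i] <- stats::var(fit$boot$sn)
          acc[[mth]]$wv_sp[i] <- stats::var(fit$boot$sp)
        }
      }
    }
  }

  purrr::imap(acc, function(lists, mth) {
    keep <- !is.na(lists$sn)
    sn_est <- lists$sn[keep]
    sp_est <- lists$sp[keep]
    ok <- length(sn_est) >= 2
    pool <- mth %in% resampling && b > 1
    tibble(
      p = p, sn_true = sn, sp_true = sp, n = n, B = B, method = mth,
      mean_sn = if (ok) mean(sn_est) else NA_real_,
      bias_sn = if (ok) sim_bias(sn_est, sn) else NA_real_,
      se_sn = if (!ok) NA_real_ else if (pool) {
        pooled_resample_sd(sn_est, lists$wv_sn[keep], b)
      } else sim_se(sn_est),
      mean_sp = if (ok) mean(sp_est) else NA_real_,
      bias_sp = if (ok) sim_bias(sp_est, sp) else NA_real_,
      se_sp = if (!ok) NA_real_ else if (pool) {
        pooled_resample_sd(sp_est, lists$wv_sp[keep], b)
      } else sim_se(sp_est),
      note = if (failures[[mth]] > 0) {
        paste0(failures[[mth]], " of ", B, " replications failed")
      } else NA_character_
    )
  }) |>
    purrr::list_rbind() |>
    structure(class = c("pvb_performance", "tbl_df", "tbl", "data.frame"))
}

empty_performance <- function() {
  structure(
    tibble(p = double(), sn_true = double(), sp_true = double(),
           n = integer(), B = integer(), method = character(),
           mean_sn = double(), bias_sn = double(), se_sn = double(),
           mean_sp = double(), bias_sp = double(), se_sp = double(),
           note = character()),
    class = c("pvb_performance", "tbl_df", "tbl", "data.frame")
  )
}

#' The default simulation grid
#'
#' Twelve parameter combinations (prevalence 0.4 and 0.1 crossed with six
#' (Sn, Sp) pairs) at two sample sizes, 24 scenarios in total.
#'
#' @return A tibble with columns `p`, `sn`, `sp`, `n`.
#' @export
default_grid <- function() {
  pairs <- tibble(sn = rep(c(0.3, 0.3, 0.6, 0.6, 0.9, 0.9), 1),
                  sp = rep(c(0.6, 0.9), 3))
  tidyr::expand_grid(p = c(0.4, 0.1), pairs, n = c(200L, 1000L)) |>
    arrange(.data$p == 0.1, .data$sn, .data$sp, .data$n)
}

#' Run a grid of simulation scenarios
#'
#' Maps [run_scenario()] over the rows of a scenario grid. Each scenario
#' gets its own seed derived from the master seed, so the full grid is
#' reproducible. A scenario that fails outright is reported as a `note`
#' row with `NA` results rather than aborting the grid.
#'
#' @param grid A tibble with columns `p`, `sn`, `sp`, `n` (default
#'   [default_grid()]).
#' @inheritParams run_scenario
#' @return A `pvb_performance` tibble (one row per scenario x method).
#' @export
run_grid <- function(grid = default_grid(), methods = all_methods(),
                     B = 500L, b = 1000L, m = 100L, rel_size = 1,
                     lambda1 = 0.8, lambda0 = 0.4, seed = NULL) {
  stopifnot(all(c("p", "sn", "sp", "n") %in% names(grid)))
  if (!is.null(seed)) set.seed(seed)
  scenario_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  out <- purrr::pmap(
    list(grid$p, grid$sn, grid$sp, grid$n, scenario_seeds),
    function(p, sn, sp, n, sseed) {
      tryCatch(
        run_scenario(p, sn, sp, n, methods = methods, B = B, b = b, m = m,
                     rel_size = rel_size, lambda1 = lambda1,
                     lambda0 = lambda0, seed = sseed),
        error = function(e) {
          tibble(p = p, sn_true = sn, sp_true = sp, n = as.integer(n),
                 B = as.integer(B), method = NA_character_,
                 mean_sn = NA_real_, bias_sn = NA_real_, se_sn = NA_real_,
                 mean_sp = NA_real_, bias_sp = NA_real_, se_sp = NA_real_,
                 note = conditionMessage(e))
        }
      )
    }
  ) |> purrr::list_rbind()
  structure(out, class = c("pvb_performance", "tbl_df", "tbl", "data.frame"))
}

#' Analyze a clinical PVB dataset with every correction method
#'
#' Produces the point estimates and 95% confidence intervals of the
#' requested methods on one subject-level dataset, each with its natural
#' interval: Wald for CCA, bootstrap percentile for BG, IPWE, SIPW and
#' SIPW-B, Rubin's rules for MI, and the native percentile interval for
#' IPB. The number of imputations defaults to the rounded percentage of
#' incomplete (unverified) cases.
#'
#' @param data A PVB verification dataset.
#' @param methods Methods to apply (default all except FDA).
#' @param b Resamples for IPB/SIPW/SIPW-B (default 1000).
#' @param R Bootstrap replicates for percentile intervals (default 1000).
#' @param m Imputations for MI; default `round(100 * fraction unverified)`.
#' @param rel_size Control:case relative size for SIPW-B (default 1).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A tibble with columns `method`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `ci_method`, `level`, plus attributes `n`, `n1` and
#'   `pct_unverified`. Methods that fail are reported with `NA` estimates
#'   and the error message in a `note` column.
#' @export
analyze_clinical <- function(data,
                             methods = c("cca", "bg", "ipwe", "mi", "ipb",
                                         "sipw", "sipwb"),
                             b = 1000L, R = 1000L, m = NULL, rel_size = 1,
                             level = 0.95, seed = NULL) {
  data <- pvb_data(data)
  methods <- match.arg(methods, all_methods(), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  pct_unverified <- 100 * mean(data$verified == 0L)
  if (is.null(m)) m <- max(2L, round(pct_unverified))

  ci_for <- c(fda = "wald", cca = "wald", bg = "boot", ipwe = "boot",
              mi = "rubin", ipb = "native", sipw = "boot", sipwb = "boot")

  rows <- purrr::map(methods, function(mth) {
    fit <- tryCatch(
      pvb_correct(data, method = mth, ci = ci_for[[mth]], b = b, m = m,
                  rel_size = rel_size, R = R, level = level),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      tibble(method = mth, term = c("sensitivity", "specificity"),
             estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
             ci_method = NA_character_, level = level,
             note = conditionMessage(fit))
    } else {
      mutate(tidy(fit), note = NA_character_)
    }
  }) |> purrr::list_rbind()

  structure(rows, n = nrow(data), n1 = sum(data$verified == 1L),
            pct_unverified = pct_unverified)
}
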