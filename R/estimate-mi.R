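# Fit the disease model D ~ T on verified subjects; shared by the
# imputation functions. Errors on separation (a stratum disease rate of
# exactly 0 or 1 among verified subjects), where the logistic MLE diverges.
#
# The fit augments the verified records with four weighted pseudo-
# observations -- both outcomes at test = mean(T) +/- 0.5 sd(T), total
# weight p + 1 = 2 -- the perfect-prediction safeguard standard in MI
# software (White, Royston and Daniel's data augmentation). With sparse
# strata this regularizes the coefficient draws; with ample data its
# effect is negligible.
fit_disease_model <- function(data) {
  v <- data$verified == 1L
  if (!any(v)) abort("No verified subjects; cannot fit the disease model.")
  for (t in c(0L, 1L)) {
    d <- data$disease[v & data$test == t]
    if (length(d) == 0) {
      abort(paste0("No verified subjects with test = ", t,
                   "; P(D=1|T=", t, ") cannot be estimated."))
    }
    if (all(d == 1L) || all(d == 0L)) {
      abort(paste0(
        "Perfect separation in the disease model: all verified subjects with ",
        "test = ", t, " have disease = ", d[1], ". Proper imputation draws ",
        "are undefined; consider the Begg-Greenes or IPWE correction instead."
      ))
    }
  }
  xv <- data$test[v]
  yv <- data$disease[v]
  mx <- mean(xv)
  sx <- sd(xv)
  xa <- pmin(max(xv), pmax(min(xv), mx + c(0.5, -0.5, 0.5, -0.5) * sx))
  df <- data.frame(y = c(yv, 0, 0, 1, 1), x = c(xv, xa))
  wts <- c(rep(1, length(xv)), rep(0.5, 4))
  suppressWarnings(
    glm(y ~ x, family = binomial(), data = df, weights = wts)
  )
}

#' Single proper imputation of missing disease status
#'
#' Fits a logistic regression of disease on test among verified subjects,
#' draws one coefficient vector from the asymptotic normal distribution of
#' the fit (a *proper* imputation, propagating estimation uncertainty), and
#' imputes each missing disease status as Bernoulli with the drawn
#' test-stratum probability. Datasets without missing values are returned
#' unchanged.
#'
#' @param data A PVB verification dataset.
#' @return A complete verification dataset tibble (all `verified` set to 1).
#' @export
impute_once <- function(data) {
  data <- pvb_data(data)
  if (!anyNA(data$disease)) return(data)
  fit <- fit_disease_model(data)
  beta <- MASS::mvrnorm(1, mu = coef(fit), Sigma = vcov(fit))
  miss <- is.na(data$disease)
  pr <- plogis(beta[1] + beta[2] * data$test[miss])
  data$disease[miss] <- rbinom(sum(miss), 1L, pr)
  data$verified <- 1L
  data
}

#' Multiple imputation correction
#'
#' Runs `m` proper logistic imputations of the missing disease statuses
#' (one coefficient draw per imputation from the asymptotic normal of the
#' verified-data fit of D on T), estimates Sn/Sp on each completed dataset,
#' and pools by averaging. Per-imputation estimates and their
#' within-imputation Wald variances are retained for Rubin's rules
#' ([ci_rubin()]).
#'
#' @param data A PVB verification dataset.
#' @param m Number of imputations (>= 2; default 100).
#' @return A `pvb_fit` whose `imputations` element is a tibble with columns
#'   `sn`, `sp`, `var_sn`, `var_sp`.
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_pvb_pair(200, 0.4, 0.3, 0.6)$pvb
#' estimate_mi(d, m = 20)
estimate_mi <- function(data, m = 100L) {
  if (!is.numeric(m) || length(m) != 1 || m < 2) {
    abort("`m` must be at least 2 for Rubin pooling.")
  }
  data <- pvb_data(data)
  n <- nrow(data)
  miss <- is.na(data$disease)

  if (!any(miss)) {
    # degenerate but allowed: every "imputation" is the observed data
    acc <- estimate_accuracy(cross_tabulate(data))
    draws <- tibble(
      sn = rep(acc[["sn"]], m), sp = rep(acc[["sp"]], m),
      var_sn = rep(wald_var(acc[["sn"]], sum(data$disease == 1L)), m),
      var_sp = rep(wald_var(acc[["sp"]], sum(data$disease == 0L)), m)
    )
    return(new_pvb_fit("mi", acc[["sn"]], acc[["sp"]], n, n,
                       imputations = draws, settings = list(m = m)))
  }

  fit <- fit_disease_model(data)
  betas <- MASS::mvrnorm(m, mu = coef(fit), Sigma = vcov(fit))
  betas <- matrix(betas, ncol = 2)

  # observed (verified) cells are fixed across imputations
  obs <- cross_tabulate(data, verified_only = TRUE)
  miss1 <- sum(miss & data$test == 1L)
  miss0 <- sum(miss & data$test == 0L)

  p1 <- plogis(betas[, 1] + betas[, 2])
  p0 <- plogis(betas[, 1])
  d1 <- rbinom(m, miss1, p1) # imputed diseased among missing test-positives
  d0 <- rbinom(m, miss0, p0)
  tp <- obs[["tp"]] + d1
  fn <- obs[["fn"]] + d0
  fp <- obs[["fp"]] + miss1 - d1
  tn <- obs[["tn"]] + miss0 - d0
  sn_i <- tp / (tp + fn)
  sp_i <- tn / (fp + tn)
  draws <- tibble(sn = sn_i, sp = sp_i,
                  var_sn = wald_var(sn_i, tp + fn),
                  var_sp = wald_var(sp_i, fp + tn))

  new_pvb_fit("mi", mean(draws$sn), mean(draws$sp), n, sum(!miss),
              imputations = draws, settings = list(m = m))
}

wald_var <- function(p, denom) p * (1 - p) / denom
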