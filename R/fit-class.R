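# Internal constructor for fitted accuracy objects. All estimators return a
# `pvb_fit`: point estimates of Sn/Sp plus whatever replicate material the
# method produced (resample lists, imputation draws), so interval methods
# and broom verbs can work from one shape.
new_pvb_fit <- function(method, sn, sp, n, n1,
                        boot = NULL, imputations = NULL, settings = list()) {
  stopifnot(sn >= 0, sn <= 1, sp >= 0, sp <= 1)
  structure(
    list(
      method = method,
      estimates = c(sn = unname(sn), sp = unname(sp)),
      n = as.integer(n),
      n1 = as.integer(n1),
      boot = boot,               # list(sn = , sp = ) per-resample estimates
      imputations = imputations, # tibble of per-imputation estimates/variances
      settings = settings,
      intervals = NULL           # filled by pvb_correct()/add_interval()
    ),
    class = "pvb_fit"
  )
}

method_labels <- c(
  fda = "Full data analysis",
  cca = "Complete case analysis",
  bg = "Begg-Greenes",
  ipwe = "Inverse probability weighting estimator",
  mi = "Multiple imputation",
  ipb = "Inverse probability bootstrap",
  sipw = "Scaled inverse probability weighted resampling",
  sipwb = "Balanced scaled inverse probability weighted resampling"
)

#' @export
print.pvb_fit <- function(x, digits = 3, ...) {
  cat(method_labels[[x$method]], sprintf("(%s)\n", toupper(x$method)))
  cat(sprintf("  n = %d subjects, %d verified\n", x$n, x$n1))
  est <- x$estimates
  if (!is.null(x$intervals)) {
    ci <- x$intervals
    for (term in c("sn", "sp")) {
      row <- ci[ci$term == term, ]
      cat(sprintf("  %s = %.*f  [%.*f, %.*f] (%s, %d%%)\n",
                  toupper(term), digits, est[[term]],
                  digits, row$conf.low, digits, row$conf.high,
                  row$ci_method, round(100 * row$level)))
    }
  } else {
    cat(sprintf("  Sn = %.*f, Sp = %.*f\n",
                digits, est[["sn"]], digits, est[["sp"]]))
  }
  invisible(x)
}

#' Tidy a fitted accuracy object
#'
#' @param x A `pvb_fit` as returned by the `estimate_*()` functions or
#'   [pvb_correct()].
#' @param ... Unused.
#' @return A tibble with one row per accuracy measure: `term`
#'   (`"sensitivity"`, `"specificity"`), `estimate`, and when an interval
#'   was requested `conf.low`, `conf.high`, `ci_method`, `level`.
#' @export
tidy.pvb_fit <- function(x, ...) {
  out <- tibble(
    method = x$method,
    term = c("sensitivity", "specificity"),
    estimate = unname(x$estimates[c("sn", "sp")])
  )
  if (!is.null(x$intervals)) {
    ci <- x$intervals
    out$conf.low <- ci$conf.low[match(c("sn", "sp"), ci$term)]
    out$conf.high <- ci$conf.high[match(c("sn", "sp"), ci$term)]
    out$ci_method <- ci$ci_method[match(c("sn", "sp"), ci$term)]
    out$level <- ci$level[match(c("sn", "sp"), ci$term)]
  }
  out
}

#' One-row summary of a fitted accuracy object
#'
#' @inheritParams tidy.pvb_fit
#' @return A one-row tibble with the method label, sample sizes, point
#'   estimates and the replicate counts the method used (`b` resamples,
#'   `m` imputations, where applicable).
#' @export
glance.pvb_fit <- function(x, ...) {
  tibble(
    method = x$method,
    n = x$n,
    n1 = x$n1,
    sn = unname(x$estimates[["sn"]]),
    sp = unname(x$estimates[["sp"]]),
    b = x$settings$b %||% NA_integer_,
    m = x$settings$m %||% NA_integer_,
    rel_size = x$settings$rel_size %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot the resampling distribution of a fitted accuracy object
#'
#' For resampling-based fits (IPB, SIPW, SIPW-B) and multiple imputation,
#' shows the distribution of per-replicate sensitivity and specificity
#' estimates with the pooled point estimate marked.
#'
#' @param object A `pvb_fit` carrying replicate estimates.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvb_fit <- function(object, ...) {
  reps <- if (!is.null(object$boot)) {
    tibble(term = rep(c("sensitivity", "specificity"),
                      times = c(length(object$boot$sn), length(object$boot$sp))),
           estimate = c(object$boot$sn, object$boot$sp))
  } else if (!is.null(object$imputations)) {
    tibble(term = rep(c("sensitivity", "specificity"),
                      each = nrow(object$imputations)),
           estimate = c(object$imputations$sn, object$imputations$sp))
  } else {
    abort("This fit carries no replicate estimates to plot.")
  }
  points <- tibble(term = c("sensitivity", "specificity"),
                   estimate = unname(object$estimates))
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey55", colour = "white") +
    ggplot2::geom_vline(data = points,
                        ggplot2::aes(xintercept = .data$estimate),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(
      x = "Per-replicate estimate", y = "Count",
      title = method_labels[[object$method]],
      subtitle = "Replicate distribution with pooled estimate"
    )
}
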