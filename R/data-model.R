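#' Construct and validate a verification dataset
#'
#' A verification dataset is a subject-level tibble with one row per patient
#' and three binary columns: `test` (index test result, 1 positive / 0
#' negative), `disease` (gold-standard disease status, 1 / 0, `NA` when the
#' patient was not verified) and `verified` (1 if the gold standard was
#' applied, 0 otherwise). Partial verification bias (PVB) data have
#' `disease` missing exactly where `verified == 0`; a *complete* dataset has
#' `verified == 1` everywhere and no missing `disease`.
#'
#' @param data A data frame with columns `test`, `disease`, `verified`.
#'
#' @return A validated tibble with integer columns `test`, `disease`,
#'   `verified`.
#' @export
#' @examples
#' pvb_data(data.frame(test = c(1, 0, 1), disease = c(1, NA, 0),
#'                     verified = c(1, 0, 1)))
pvb_data <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `test`, `disease`, `verified`.")
  }
  missing_cols <- setdiff(c("test", "disease", "verified"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(data) == 0) {
    abort("`data` has no rows; at least one subject is required.")
  }
  out <- as_tibble(data)
  out$test <- check_binary(out$test, "test", allow_na = FALSE)
  out$verified <- check_binary(out$verified, "verified", allow_na = FALSE)
  out$disease <- check_binary(out$disease, "disease", allow_na = TRUE)

  bad_missing <- which(out$verified == 1L & is.na(out$disease))
  if (length(bad_missing) > 0) {
    abort(paste0("`disease` is missing for verified subject(s) at row(s) ",
                 format_rows(bad_missing),
                 "; verified subjects must have observed disease status."))
  }
  bad_present <- which(out$verified == 0L & !is.na(out$disease))
  if (length(bad_present) > 0) {
    abort(paste0("`disease` is recorded for unverified subject(s) at row(s) ",
                 format_rows(bad_present),
                 "; disease status must be missing exactly when verified = 0."))
  }
  out
}

check_binary <- function(x, name, allow_na) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x)) {
    abort(paste0("Column `", name, "` must be numeric 0/1."))
  }
  bad <- !is.na(x) & !(x %in% c(0, 1))
  if (any(bad)) {
    abort(paste0("Column `", name, "` contains value(s) other than 0/1 at row(s) ",
                 format_rows(which(bad)), "."))
  }
  if (!allow_na && anyNA(x)) {
    abort(paste0("Column `", name, "` must not contain missing values."))
  }
  as.integer(x)
}

format_rows <- function(idx, max = 5L) {
  shown <- utils::head(idx, max)
  txt <- paste(shown, collapse = ", ")
  if (length(idx) > max) txt <- paste0(txt, ", ... (", length(idx), " total)")
  txt
}

#' Is the dataset complete (fully verified)?
#'
#' @param data A verification dataset (see [pvb_data()]).
#' @return `TRUE` if every subject is verified and no disease status is
#'   missing.
#' @export
is_complete <- function(data) {
  data <- pvb_data(data)
  all(data$verified == 1L) && !anyNA(data$disease)
}

#' Cross-tabulate test result against disease status
#'
#' Builds the 2x2 table of test versus disease used by every estimator in
#' the package. The four cells are kept in the fixed order TP = (T=1, D=1),
#' FN = (T=0, D=1), FP = (T=1, D=0), TN = (T=0, D=0), matching the
#' multinomial cell probabilities of the simulation engine. Cells may be
#' real-valued when built from weighted counts (see [estimate_ipwe()]).
#'
#' @param data A verification dataset.
#' @param verified_only If `TRUE`, tabulate only subjects with
#'   `verified == 1` (the only option that makes sense for PVB data). If
#'   `FALSE` the dataset must be complete.
#' @return A `pvb_xtab`: a named numeric vector of length 4 with names
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' d <- simulate_complete(50, p = 0.4, sn = 0.8, sp = 0.7)
#' cross_tabulate(d)
cross_tabulate <- function(data, verified_only = FALSE) {
  data <- pvb_data(data)
  if (!verified_only && anyNA(data$disease)) {
    abort(paste0("Dataset contains unverified subjects with missing disease ",
                 "status (PVB data) but `verified_only = FALSE`; use ",
                 "`verified_only = TRUE` or a complete dataset."))
  }
  sub <- if (verified_only) data[data$verified == 1L, ] else data
  if (nrow(sub) == 0) {
    abort("No verified subjects to tabulate.")
  }
  new_xtab(c(
    tp = sum(sub$test == 1L & sub$disease == 1L),
    fn = sum(sub$test == 0L & sub$disease == 1L),
    fp = sum(sub$test == 1L & sub$disease == 0L),
    tn = sum(sub$test == 0L & sub$disease == 0L)
  ))
}

new_xtab <- function(cells) {
  stopifnot(length(cells) == 4, all(cells >= 0))
  if (sum(cells) <= 0) abort("Cross table has zero total count.")
  structure(as.double(cells), names = c("tp", "fn", "fp", "tn"),
            class = "pvb_xtab")
}

#' @export
print.pvb_xtab <- function(x, ...) {
  m <- matrix(unclass(x)[c("tp", "fp", "fn", "tn")], nrow = 2, byrow = TRUE,
              dimnames = list(test = c("T=1", "T=0"),
                              disease = c("D=1", "D=0")))
  cat("2x2 test-by-disease table\n")
  print(m[, , drop = FALSE])
  invisible(x)
}

#' Validity of a 2x2 cross table
#'
#' A table is *valid* when all four test-by-disease cells are strictly
#' positive, i.e. the cross-classification has full dimension 4. Simulated
#' datasets are screened with this predicate and weighted resamples are
#' rejected when they fail it.
#'
#' @param table A `pvb_xtab` (or numeric vector of 4 nonnegative cells).
#' @return Logical scalar.
#' @export
is_valid_table <- function(table) {
  cells <- as.double(table)
  stopifnot(length(cells) == 4)
  all(cells > 0)
}

#' Sensitivity and specificity from a 2x2 table
#'
#' Computes the empirical sensitivity Sn = P(T=1 | D=1) and specificity
#' Sp = P(T=0 | D=0) from a test-by-disease cross table. Cells may be
#' weighted (real-valued); only the positivity of the two denominators is
#' required.
#'
#' @param table A `pvb_xtab` from [cross_tabulate()] (or a numeric vector
#'   `c(tp, fn, fp, tn)`).
#' @return A named numeric vector `c(sn = ..., sp = ...)`.
#' @export
#' @examples
#' estimate_accuracy(c(tp = 3, fn = 7, fp = 4, tn = 6))
estimate_accuracy <- function(table) {
  cells <- as.double(table)
  stopifnot(length(cells) == 4)
  if (any(cells < 0)) abort("Cross table cells must be nonnegative.")
  diseased <- cells[1] + cells[2]
  healthy <- cells[3] + cells[4]
  if (diseased <= 0) {
    abort("Sensitivity is undefined: no diseased subjects in the table.")
  }
  if (healthy <= 0) {
    abort("Specificity is undefined: no disease-free subjects in the table.")
  }
  c(sn = cells[1] / diseased, sp = cells[4] / healthy)
}

# cell index 1..4 (tp, fn, fp, tn) per subject; NA for unverified rows
cell_index <- function(data) {
  idx <- rep(NA_integer_, nrow(data))
  v <- data$verified == 1L
  idx[v] <- 1L + (1L - data$test[v]) + 2L * (1L - data$disease[v])
  idx
}
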