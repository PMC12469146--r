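#' Read a subject-level verification dataset from CSV
#'
#' Expects a header row and the three columns `test`, `disease`,
#' `verified`, all coded 0/1 with `disease` empty (missing) exactly for
#' unverified rows. The file is validated with [pvb_data()]; coding
#' violations are reported with row numbers.
#'
#' @param path Path to a CSV file.
#' @param quiet If `FALSE` (default), print a one-line summary (n, verified
#'   count, percent unverified).
#' @return A validated verification dataset tibble.
#' @export
read_pvb_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    test = readr::col_integer(),
    disease = readr::col_integer(),
    verified = readr::col_integer()
  ), progress = FALSE)
  data <- pvb_data(raw)
  if (!quiet) {
    n1 <- sum(data$verified == 1L)
    message(sprintf("Read %d subjects: %d verified, %.1f%% unverified.",
                    nrow(data), n1, 100 * (1 - n1 / nrow(data))))
  }
  data
}

#' Write a verification dataset to CSV
#'
#' Comma-separated, UTF-8, header row; missing disease status is written
#' as an empty field. Round-trips exactly through [read_pvb_csv()].
#'
#' @param data A verification dataset.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_pvb_csv <- function(data, path) {
  data <- pvb_data(data)
  readr::write_csv(data, path, na = "")
  invisible(data)
}

#' Clinical fixture profiles
#'
#' Margins and verified-cell counts for building subject-level datasets
#' shaped like the two classical PVB case studies: a hepatic scintigraphy
#' study of liver-cancer detection (650 patients, 344 verified by
#' pathology) and a diaphanography study of breast-cancer detection (900
#' patients, only 88 verified by biopsy). The published cross-tables are
#' not machine-readable, so these cell counts are a reconstruction: they
#' were solved from the published margins together with the reported
#' complete-case and corrected accuracy estimates, and datasets built from
#' them are synthetic stand-ins for the original data.
#'
#' A profile is a list with fields `name`, `verified` (named counts `tp`,
#' `fn`, `fp`, `tn`) and `unverified` (named counts `t1`, `t0`).
#'
#' @return A named list of the two built-in profiles.
#' @export
#' @examples
#' clinical_profiles()$scintigraphy
clinical_profiles <- function() {
  list(
    scintigraphy = list(
      name = "scintigraphy",
      verified = c(tp = 231, fn = 27, fp = 32, tn = 54),
      unverified = c(t1 = 166, t0 = 140)
    ),
    diaphanography = list(
      name = "diaphanography",
      verified = c(tp = 26, fn = 7, fp = 11, tn = 44),
      unverified = c(t1 = 30, t0 = 782)
    )
  )
}

#' Build a subject-level dataset from a fixture profile
#'
#' Expands a profile's cell counts into one row per subject, so the margins
#' match the profile *exactly* (deterministic counts, not sampling), then
#' shuffles the row order.
#'
#' @param profile A profile list (see [clinical_profiles()]) with fields
#'   `verified` (counts `tp`, `fn`, `fp`, `tn`) and `unverified` (counts
#'   `t1`, `t0`).
#' @return A verification dataset tibble.
#' @export
#' @examples
#' set.seed(1)
#' d <- make_clinical_fixture(clinical_profiles()$diaphanography)
#' nrow(d); sum(d$verified)
make_clinical_fixture <- function(profile) {
  need <- c("verified", "unverified")
  if (!is.list(profile) || !all(need %in% names(profile))) {
    abort("`profile` must be a list with fields `verified` and `unverified`.")
  }
  vc <- profile$verified[c("tp", "fn", "fp", "tn")]
  uc <- profile$unverified[c("t1", "t0")]
  if (anyNA(vc) || anyNA(uc) || any(c(vc, uc) < 0) ||
      any(c(vc, uc) != round(c(vc, uc)))) {
    abort("Profile counts must be nonnegative integers named tp/fn/fp/tn and t1/t0.")
  }
  if (sum(vc) == 0) abort("Profile has no verified subjects.")
  out <- tibble(
    test = c(rep(c(1L, 0L, 1L, 0L), times = vc), rep(c(1L, 0L), times = uc)),
    disease = c(rep(c(1L, 1L, 0L, 0L), times = vc),
                rep(NA_integer_, sum(uc))),
    verified = c(rep(1L, sum(vc)), rep(0L, sum(uc)))
  )
  out[sample.int(nrow(out)), ]
}
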