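#' Convert IC50 (micromolar) to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration expressed in molar units, so an IC50 of 1 uM maps to a
#' pIC50 of 6 and more potent compounds get larger values.  Some reports
#' instead take minus log10 of the micromolar number directly; set
#' `molar = FALSE` for that literal convention.
#'
#' @param ic50_um positive numeric vector, IC50 in micromolar.
#' @param molar logical; if `TRUE` (default) convert the concentration to
#'   molar before taking the log, i.e. `6 - log10(ic50_um)`.  If `FALSE`
#'   return the literal `-log10(ic50_um)`.
#' @return numeric vector of pIC50 values.
#' @examples
#' ic50_to_pic50(1)      # 6
#' ic50_to_pic50(0.001)  # 9
#' @seealso [pic50_to_ic50()] for the inverse.
#' @export
ic50_to_pic50 <- function(ic50_um, molar = TRUE) {
  check_that(is.numeric(ic50_um) && length(ic50_um) >= 1L,
             "`ic50_um` must be numeric")
  check_that(all(is.finite(ic50_um)) && all(ic50_um > 0),
             "`ic50_um` must be finite and strictly positive (micromolar)")
  if (molar) 6 - log10(ic50_um) else -log10(ic50_um)
}

#' Convert pIC50 back to IC50 (micromolar)
#'
#' @param pic50 numeric vector of pIC50 values.
#' @inheritParams ic50_to_pic50
#' @return positive numeric vector, IC50 in micromolar.
#' @export
pic50_to_ic50 <- function(pic50, molar = TRUE) {
  check_that(is.numeric(pic50) && all(is.finite(pic50)),
             "`pic50` must be finite numeric")
  if (molar) 10^(6 - pic50) else 10^(-pic50)
}

#' Read an activity table
#'
#' Reads a CSV with columns `compound_id`, and at least one of `ic50_um`
#' (micromolar) and `pic50`; an optional `role` column assigns each
#' compound to `train`, `test` or `screen`.  Missing pIC50 values are
#' filled from IC50 via [ic50_to_pic50()]; if both are present they must
#' agree to 1e-9.
#'
#' @param path path to the CSV file.
#' @param molar passed to [ic50_to_pic50()] when pIC50 must be derived.
#' @return data.frame with columns `compound_id`, `ic50_um`, `pic50`,
#'   `role`.
#' @export
read_activities <- function(path, molar = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that("compound_id" %in% names(d), "activity CSV needs a compound_id column")
  check_that(any(c("ic50_um", "pic50") %in% names(d)),
             "activity CSV needs an ic50_um and/or pic50 column")
  if (!"ic50_um" %in% names(d)) d$ic50_um <- NA_real_
  if (!"pic50" %in% names(d)) d$pic50 <- NA_real_
  if (!"role" %in% names(d)) d$role <- "train"
  d$compound_id <- as.character(d$compound_id)
  check_that(!anyDuplicated(d$compound_id), "duplicate compound ids in activity CSV")
  check_that(all(d$role %in% c("train", "test", "screen")),
             "role must be one of train, test, screen")
  has_ic <- !is.na(d$ic50_um)
  has_p <- !is.na(d$pic50)
  check_that(all(has_ic | has_p),
             "every compound needs ic50_um or pic50")
  check_that(all(d$ic50_um[has_ic] > 0), "ic50_um must be positive")
  both <- has_ic & has_p
  if (any(both)) {
    conv <- ic50_to_pic50(d$ic50_um[both], molar = molar)
    check_that(all(abs(conv - d$pic50[both]) <= 1e-9),
               "ic50_um and pic50 disagree beyond 1e-9 for: %s",
               paste(d$compound_id[both][abs(conv - d$pic50[both]) > 1e-9],
                     collapse = ", "))
  }
  fill <- has_ic & !has_p
  if (any(fill)) d$pic50[fill] <- ic50_to_pic50(d$ic50_um[fill], molar = molar)
  d[, c("compound_id", "ic50_um", "pic50", "role")]
}
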