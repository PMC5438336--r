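#' Lipinski rule-of-five filter
#'
#' Flags oral-bioavailability violations: molecular weight above 500
#' g/mol, LogP above 5, more than 5 hydrogen-bond donors, more than 10
#' acceptors.  Values exactly at a cutoff pass.  When polar surface
#' area and rotatable-bond counts are supplied, the Veber criteria
#' (PSA > 140 A^2, rotatable bonds > 10) are reported separately and do
#' not affect the Lipinski verdict.
#'
#' @param mw molecular weight, g/mol.
#' @param logp octanol-water partition coefficient.
#' @param hbd,hba hydrogen-bond donor and acceptor counts.
#' @param psa polar surface area in A^2 (optional).
#' @param rotb rotatable-bond count (optional).
#' @return data.frame with one row per compound: `pass` (logical),
#'   `violations` (comma-separated, `""` if none), and — when provided —
#'   `veber_psa`, `veber_rotb` flags.
#' @examples
#' lipinski(mw = c(300, 600), logp = c(2, 6), hbd = c(2, 1), hba = c(5, 3))
#' @export
lipinski <- function(mw, logp, hbd, hba, psa = NULL, rotb = NULL) {
  for (nm in c("mw", "logp", "hbd", "hba")) {
    v <- get(nm)
    check_that(!is.null(v) && is.numeric(v) && all(is.finite(v)),
               "required property `%s` is missing or non-numeric", nm)
  }
  n <- length(mw)
  check_that(all(lengths(list(logp, hbd, hba)) == n),
             "property vectors must have equal length")
  flags <- cbind(MW = mw > 500, LogP = logp > 5, HBD = hbd > 5, HBA = hba > 10)
  violations <- apply(flags, 1L, function(f)
    paste(colnames(flags)[f], collapse = ","))
  out <- data.frame(pass = rowSums(flags) == 0L, violations = violations,
                    stringsAsFactors = FALSE)
  if (!is.null(psa)) out$veber_psa <- psa > 140
  if (!is.null(rotb)) out$veber_rotb <- rotb > 10
  out
}

#' Screen candidate compounds through a QSAR model
#'
#' Predicts the activity of each candidate, computes (or passes
#' through) its leverage in the training descriptor space, and flags the
#' prediction as reliable only when the candidate falls inside the
#' applicability domain (`h <= h*`).  Candidates carrying the standard
#' molecular properties are additionally run through the Lipinski
#' filter.
#'
#' Candidates arrive as a data.frame whose first column (or `id_col`)
#' is the identifier.  If the model's descriptor columns are present,
#' predictions and leverages are computed; otherwise a `leverage`
#' column must be supplied (as for literature candidates whose
#' descriptors were never published) and an optional `pred` column is
#' passed through.
#'
#' @param object a fitted [qsar_mlr] model, or a [qsar_equation]
#'   (in which case leverages must be precomputed and `h_star` given).
#' @param candidates data.frame of candidates (see Details).
#' @param h_star leverage threshold; defaults to the model's own
#'   `3(k+1)/n`.
#' @param id_col name or index of the identifier column (default 1).
#' @return object of class `"screening_report"`: `table` (per-candidate
#'   id, pred, leverage, reliable, plus Lipinski columns when
#'   available), `counts` (n, reliable, unreliable, lipinski_pass),
#'   `h_star`.
#' @export
screen_candidates <- function(object, candidates, h_star = NULL, id_col = 1L) {
  check_that(is.data.frame(candidates), "`candidates` must be a data.frame")
  is_fit <- inherits(object, "qsar_mlr")
  check_that(is_fit || inherits(object, "qsar_equation"),
             "`object` must be a qsar_mlr fit or a qsar_equation")
  eq <- if (is_fit) object$equation else object
  if (is.null(h_star) && is_fit) h_star <- object$ad$h_star
  check_that(!is.null(h_star), "`h_star` required when `object` has no training context")

  ids <- as.character(candidates[[id_col]])
  n <- nrow(candidates)
  if (n == 0L) {
    tab <- data.frame(candidate_id = character(), pred = numeric(),
                      leverage = numeric(), reliable = logical(),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab,
                          counts = list(n = 0L, reliable = 0L, unreliable = 0L,
                                        lipinski_pass = 0L),
                          h_star = h_star), class = "screening_report"))
  }

  have_desc <- all(names(eq$coefficients) %in% names(candidates))
  if (have_desc) {
    pred <- predict(eq, candidates)
    lev <- if (is_fit) leverage(object, candidates) else candidates$leverage
    check_that(!is.null(lev),
               "leverage column required when screening through a bare equation")
  } else {
    check_that("leverage" %in% names(candidates),
               "candidates need either the model's descriptor columns or a `leverage` column")
    lev <- as.numeric(candidates$leverage)
    pred <- if ("pred" %in% names(candidates))
      as.numeric(candidates$pred) else rep(NA_real_, n)
  }
  check_that(all(is.finite(lev)), "non-finite leverage for some candidates")

  tab <- data.frame(candidate_id = ids, pred = pred, leverage = lev,
                    reliable = lev <= h_star, stringsAsFactors = FALSE)
  props <- c("mw", "logp", "hbd", "hba")
  if (all(props %in% names(candidates))) {
    lip <- lipinski(candidates$mw, candidates$logp, candidates$hbd,
                    candidates$hba,
                    psa = candidates$psa, rotb = candidates$rotb)
    names(lip)[names(lip) == "pass"] <- "lipinski_pass"
    names(lip)[names(lip) == "violations"] <- "lipinski_violations"
    tab <- cbind(tab, lip)
  }
  structure(list(
    table = tab,
    counts = list(n = n,
                  reliable = sum(tab$reliable),
                  unreliable = sum(!tab$reliable),
                  lipinski_pass = if ("lipinski_pass" %in% names(tab))
                    sum(tab$lipinski_pass) else NA_integer_),
    h_star = h_star
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, digits = 4, ...) {
  cat(sprintf("Screening report: %d candidates, h* = %.4f\n",
              x$counts$n, x$h_star))
  cat(sprintf("reliable (h <= h*): %d; out of domain: %d\n",
              x$counts$reliable, x$counts$unreliable))
  if (!is.na(x$counts$lipinski_pass))
    cat(sprintf("Lipinski pass: %d\n", x$counts$lipinski_pass))
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}
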