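#' Leverage threshold for the applicability domain
#'
#' The warning leverage `h* = 3(k+1)/n`, where `k` is the number of
#' descriptors in the model and `n` the number of training compounds.
#' A compound whose leverage exceeds `h*` sits far enough from the
#' training descriptor centroid that its prediction is an extrapolation.
#'
#' @param k number of descriptors in the model (non-negative integer).
#' @param n number of training compounds (positive integer).
#' @return numeric scalar `3 * (k + 1) / n`.
#' @examples
#' hat_threshold(3, 19)  # 0.6316, printed as 0.63
#' @export
hat_threshold <- function(k, n) {
  check_that(is.numeric(k) && length(k) == 1L && k >= 0 && k == floor(k),
             "`k` must be a non-negative integer")
  check_that(is_count(n), "`n` must be a positive integer")
  3 * (k + 1) / n
}

#' Build an applicability-domain context from a training design
#'
#' Captures everything needed to judge whether a (new) compound lies in
#' the model's applicability domain: the inverse cross-product of the
#' intercept-augmented training design (for leverages
#' `h = x' (X'X)^-1 x`), the threshold `h* = 3(k+1)/n`, the training
#' leverages and standardized residuals, and the residual scale
#' `sqrt(SSE/(n-k-1))`.
#'
#' @param x_train numeric training descriptor matrix (n by k), full rank
#'   together with the intercept.
#' @param residuals numeric vector of training residuals (length n).
#' @return object of class `"ad_context"`: a list with `xtx_inv`,
#'   `descriptors`, `k`, `n`, `h_star`, `leverages`, `residual_scale`,
#'   `std_residuals`.
#' @export
ad_context <- function(x_train, residuals) {
  if (is.data.frame(x_train)) x_train <- as.matrix(x_train)
  check_that(is.matrix(x_train) && is.numeric(x_train), "`x_train` must be numeric matrix")
  n <- nrow(x_train)
  k <- ncol(x_train)
  check_that(length(residuals) == n, "residuals must have one entry per training row")
  check_that(n > k + 1L, "need n > k + 1 training compounds")
  z <- cbind(`(Intercept)` = 1, x_train)
  qz <- qr(z)
  check_that(qz$rank == k + 1L, "training design is rank deficient")
  xtx_inv <- chol2inv(qr.R(qz))
  h <- unname(rowSums((z %*% xtx_inv) * z))
  sse <- sum(residuals^2)
  scale <- sqrt(sse / (n - k - 1))
  structure(list(
    xtx_inv = xtx_inv,
    descriptors = colnames(x_train),
    k = k, n = n,
    h_star = hat_threshold(k, n),
    leverages = h,
    residual_scale = scale,
    std_residuals = if (scale > 0) residuals / scale else residuals * 0
  ), class = "ad_context")
}

#' @export
print.ad_context <- function(x, ...) {
  cat(sprintf("Applicability domain: k = %d, n = %d, h* = %.4f, residual scale = %.4f\n",
              x$k, x$n, x$h_star, x$residual_scale))
  invisible(x)
}

#' Leverage (hat value) of compounds
#'
#' Computes `h = x' (X'X)^-1 x` for intercept-augmented descriptor rows
#' against a training design.  With `newdata = NULL` the training
#' leverages (hat-matrix diagonal) are returned; they lie in
#' `[1/n, 1]` and sum to `k + 1`.
#'
#' @param object an [ad_context] or a fitted [qsar_mlr] model.
#' @param newdata optional data.frame/matrix of descriptor rows.
#' @param ... unused.
#' @return numeric vector of leverages.
#' @export
leverage <- function(object, newdata = NULL, ...) UseMethod("leverage")

#' @export
leverage.ad_context <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$leverages)
  x <- descriptor_matrix(newdata, object$descriptors)
  z <- cbind(1, x)
  unname(rowSums((z %*% object$xtx_inv) * z))
}

#' @export
leverage.qsar_mlr <- function(object, newdata = NULL, ...) {
  leverage(object$ad, newdata = newdata, ...)
}

# internal alias used where `leverage` would shadow an argument name
leverage_of <- function(object, newdata = NULL) leverage(object, newdata)

#' Williams-plot data and applicability-domain classification
#'
#' Classifies each compound against the applicability domain: training
#' compounds by both leverage (`h > h*`) and standardized residual
#' (`|r| > 2`); new (test/screen) compounds, for which no training
#' residual exists, by leverage only.  Values exactly at a boundary are
#' in-domain.  Leverage-corrected (internally studentized) residuals are
#' reported as an extra column for the training set but play no part in
#' the classification.
#'
#' @param object a fitted [qsar_mlr] model.
#' @param newdata optional descriptor rows for non-training compounds.
#' @param ids,newdata_ids optional compound ids for the training rows and
#'   `newdata` rows (defaults: row names, else positions).
#' @param residual_limit half-width of the residual band (default 2).
#' @return data.frame with columns `compound_id`, `set`, `leverage`,
#'   `std_residual`, `studentized`, `status`, with attribute `h_star`;
#'   class `"williams_data"`.  `status` is one of `in_domain`,
#'   `leverage_outlier`, `response_outlier`, `both`.
#' @export
williams <- function(object, newdata = NULL, ids = NULL, newdata_ids = NULL,
                     residual_limit = 2) {
  stopifnot(inherits(object, "qsar_mlr"))
  ad <- object$ad
  if (is.null(ids)) ids <- rownames(object$x)
  if (is.null(ids)) ids <- sprintf("train_%02d", seq_len(ad$n))
  h <- ad$leverages
  r <- ad$std_residuals
  stud <- ifelse(h < 1, object$residuals / (ad$residual_scale * sqrt(1 - h)), NA_real_)
  out <- data.frame(compound_id = as.character(ids), set = "train",
                    leverage = h, std_residual = r, studentized = stud,
                    stringsAsFactors = FALSE)
  if (!is.null(newdata)) {
    hn <- leverage(ad, newdata)
    idn <- newdata_ids
    if (is.null(idn)) idn <- rownames(as.data.frame(newdata))
    if (is.null(idn)) idn <- sprintf("new_%02d", seq_along(hn))
    out <- rbind(out, data.frame(compound_id = as.character(idn), set = "new",
                                 leverage = hn, std_residual = NA_real_,
                                 studentized = NA_real_,
                                 stringsAsFactors = FALSE))
  }
  lev_out <- out$leverage > ad$h_star
  res_out <- !is.na(out$std_residual) & abs(out$std_residual) > residual_limit
  out$status <- ifelse(lev_out & res_out, "both",
                       ifelse(lev_out, "leverage_outlier",
                              ifelse(res_out, "response_outlier", "in_domain")))
  rownames(out) <- NULL
  attr(out, "h_star") <- ad$h_star
  attr(out, "residual_limit") <- residual_limit
  class(out) <- c("williams_data", "data.frame")
  out
}

#' Write Williams-plot data to a tab-separated file
#'
#' The file carries the leverage threshold and residual band in `#`
#' comment lines so a plot can be reconstructed from it alone;
#' [read_williams()] round-trips it.
#'
#' @param x a [williams()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_williams <- function(x, path) {
  stopifnot(inherits(x, "williams_data"), nrow(x) >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# h_star = %.17g", attr(x, "h_star")),
               sprintf("# residual_limit = %.17g", attr(x, "residual_limit"))),
             con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read Williams-plot data written by [write_williams()]
#'
#' @param path path to the TSV file.
#' @return a `williams_data` data.frame with `h_star` and
#'   `residual_limit` attributes restored.
#' @export
read_williams <- function(path) {
  header <- readLines(path, n = 2L)
  num <- function(line) as.numeric(sub("^#.*= *", "", line))
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out$compound_id <- as.character(out$compound_id)
  attr(out, "h_star") <- num(header[1L])
  attr(out, "residual_limit") <- num(header[2L])
  class(out) <- c("williams_data", "data.frame")
  out
}
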