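#' Construct a linear QSAR equation
#'
#' A `qsar_equation` is the minimal published form of a linear QSAR
#' model: an intercept plus named descriptor coefficients,
#' `pIC50 = a0 + sum_i a_i x_i`.  Fitted [qsar_mlr] objects contain one;
#' literature models can be entered directly and used for prediction and
#' screening without the training data.
#'
#' @param intercept numeric scalar `a0`.
#' @param coefficients named numeric vector of descriptor coefficients.
#' @param note optional free-text provenance note.
#' @return object of class `"qsar_equation"`.
#' @examples
#' eq <- qsar_equation(6.92, c(AATS0p = -5.84, maxHBint8 = -0.27, GATS8v = 1.072))
#' predict(eq, data.frame(AATS0p = 0, maxHBint8 = 0, GATS8v = 0))
#' @export
qsar_equation <- function(intercept, coefficients, note = NULL) {
  check_that(is.numeric(intercept) && length(intercept) == 1L && is.finite(intercept),
             "`intercept` must be a finite scalar")
  check_that(is.numeric(coefficients) && length(coefficients) >= 1L &&
               all(is.finite(coefficients)),
             "`coefficients` must be finite numeric")
  check_that(!is.null(names(coefficients)) && all(nzchar(names(coefficients))) &&
               !anyDuplicated(names(coefficients)),
             "`coefficients` must have unique non-empty names")
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 note = note),
            class = "qsar_equation")
}

#' @export
print.qsar_equation <- function(x, digits = 4, ...) {
  terms <- sprintf("%s %s x %s",
                   ifelse(x$coefficients < 0, "-", "+"),
                   format(abs(x$coefficients), digits = digits, trim = TRUE),
                   names(x$coefficients))
  cat("pIC50 =", format(x$intercept, digits = digits), paste(terms, collapse = " "), "\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.qsar_equation <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

# Extract the model's descriptor columns from a data.frame or matrix,
# erroring on any that are absent.
descriptor_matrix <- function(newdata, descriptors) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  }
  missing <- setdiff(descriptors, colnames(newdata))
  check_that(length(missing) == 0L, "missing descriptor column(s): %s",
             paste(missing, collapse = ", "))
  m <- as.matrix(as.data.frame(newdata)[, descriptors, drop = FALSE])
  storage.mode(m) <- "double"
  check_that(!anyNA(m), "descriptor values contain NA")
  m
}

#' Predict activity from a QSAR equation
#'
#' @param object a [qsar_equation].
#' @param newdata data.frame or matrix containing the model's descriptor
#'   columns (extra columns are ignored).
#' @param ... unused.
#' @return numeric vector of predicted pIC50 values.
#' @export
predict.qsar_equation <- function(object, newdata, ...) {
  x <- descriptor_matrix(newdata, names(object$coefficients))
  drop(object$intercept + x %*% object$coefficients)
}
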