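#' Fit a multiple linear regression QSAR model (matrix interface)
#'
#' Ordinary least squares of an activity vector on a set of descriptor
#' columns plus an intercept.  Beyond the coefficients, the fit carries
#' everything the rest of the workflow needs: training statistics
#' (R, R-squared, mean squared error under both the `SSE/n` and
#' `SSE/(n-k-1)` conventions, the F statistic and its p value),
#' per-descriptor variance inflation factors, the leave-one-out
#' cross-validated Q-squared, and the applicability-domain context
#' (leverages, the threshold `h* = 3(k+1)/n`, standardized residuals).
#'
#' @param x numeric matrix or data.frame of descriptor values
#'   (n compounds by k descriptors), column names required.
#' @param y numeric activity vector (e.g. pIC50) of length n.
#' @param descriptors optional character vector restricting the fit to a
#'   subset of columns of `x`.
#' @return object of class `"qsar_mlr"`; see Details.
#' @details The returned object is a list with components `equation`
#'   (a [qsar_equation]), `coefficients`, `fitted`, `residuals`, `y`,
#'   `x` (the training descriptor matrix), `stats` (n, k, R, R2, mse,
#'   mse_df, F, p_value, sse, sst), `coef_table` (per-coefficient
#'   estimates, standard errors, t and p values), `vif` (a data.frame,
#'   `NULL` when k < 2), `q2` (leave-one-out Q-squared) and `ad` (an
#'   [ad_context]).  Requires `n >= k + 2` and a full-rank design;
#'   collinear columns are named in the error.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(57), 19, 3, dimnames = list(NULL, c("D1", "D2", "D3")))
#' y <- 7 + x %*% c(1.5, -1.2, 0.8) + rnorm(19, sd = 0.5)
#' fit <- fit_mlr(x, y)
#' fit
#' @seealso [qsar_mlr()] for the formula interface, [compute_vif()],
#'   [loo_q2()], [ad_context()].
#' @export
fit_mlr <- function(x, y, descriptors = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  check_that(is.matrix(x) && is.numeric(x), "`x` must be a numeric matrix")
  check_that(!is.null(colnames(x)) && !anyDuplicated(colnames(x)),
             "`x` needs unique column names")
  if (!is.null(descriptors)) x <- descriptor_matrix(x, descriptors)
  y <- as.numeric(y)
  n <- length(y)
  k <- ncol(x)
  check_that(nrow(x) == n, "nrow(x) must equal length(y)")
  check_that(n >= k + 2L,
             "need n >= k + 2 observations (n = %d, k = %d)", n, k)
  check_that(all(is.finite(x)) && all(is.finite(y)), "non-finite values in x or y")

  dat <- data.frame(.y = y, as.data.frame(x), check.names = FALSE)
  lmfit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(lmfit)
  if (anyNA(cf)) {
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }

  fitted <- as.numeric(stats::fitted(lmfit))
  res <- as.numeric(stats::residuals(lmfit))
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  stats <- list(
    n = n, k = k,
    R = sqrt(max(r2, 0)),
    R2 = r2,
    mse = sse / n,
    mse_df = sse / (n - k - 1),
    F = fstat,
    p_value = stats::pf(fstat, k, n - k - 1, lower.tail = FALSE),
    sse = sse, sst = sst
  )

  fit <- structure(list(
    equation = qsar_equation(unname(cf[1L]), cf[-1L]),
    coefficients = cf,
    descriptors = colnames(x),
    fitted = fitted,
    residuals = res,
    y = y,
    x = x,
    stats = stats,
    # summary.lm warns on interpolating (zero-residual) fits; the table is
    # still well defined, so keep it quiet
    coef_table = suppressWarnings(stats::coef(summary(lmfit))),
    vif = if (k >= 2L) compute_vif(x) else NULL,
    ad = ad_context(x, res),
    call = match.call()
  ), class = "qsar_mlr")
  # leave-one-out needs n >= k + 3; undefined otherwise
  fit$q2 <- tryCatch(loo_q2(fit), error = function(e) NA_real_)
  fit
}

#' Fit a QSAR model by formula, optionally with descriptor selection
#'
#' Formula front end to [fit_mlr()].  With `select = k`, a genetic
#' function algorithm ([gfa_select()]) first picks the best `k`-descriptor
#' subset of the right-hand-side variables by lack-of-fit, and the model
#' is then fitted on that subset.
#'
#' @param formula model formula, e.g. `pic50 ~ .` or
#'   `pic50 ~ AATS0p + maxHBint8 + GATS8v`.
#' @param data data.frame holding the response and descriptor columns.
#' @param select optional integer: subset size for GFA descriptor
#'   selection over the formula's right-hand side.
#' @param control a [gfa_control()] list, used when `select` is given.
#' @return object of class `"qsar_mlr"` (see [fit_mlr()]); when
#'   selection ran, component `selection` holds the [gfa_select()] result.
#' @examples
#' set.seed(1)
#' d <- data.frame(matrix(rnorm(250), 25, 10))
#' names(d) <- sprintf("D%02d", 1:10)
#' d$pic50 <- 7 + 1.5 * d$D01 - 1.2 * d$D04 + 0.8 * d$D07 + rnorm(25, sd = 0.1)
#' fit <- qsar_mlr(pic50 ~ ., d, select = 3, control = gfa_control(seed = 1))
#' fit$descriptors
#' @export
qsar_mlr <- function(formula, data, select = NULL, control = gfa_control()) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  sel <- NULL
  if (!is.null(select)) {
    check_that(is_count(select), "`select` must be a positive integer")
    sel <- gfa_select(x, y, k = select, control = control)
    x <- x[, sel$best_subset, drop = FALSE]
  }
  fit <- fit_mlr(x, y)
  fit$selection <- sel
  fit$call <- match.call()
  fit
}

#' @export
print.qsar_mlr <- function(x, digits = 4, ...) {
  cat("QSAR multiple linear regression\n")
  print(x$equation, digits = digits)
  s <- x$stats
  cat(sprintf("N = %d, R = %.3f, R2 = %.3f, Q2 = %.3f, MSE = %.3f, F = %.2f, P = %.3g\n",
              s$n, s$R, s$R2, x$q2, s$mse, s$F, s$p_value))
  invisible(x)
}

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
residuals.qsar_mlr <- function(object,
                               type = c("raw", "standardized"), ...) {
  type <- match.arg(type)
  if (type == "raw") object$residuals else object$ad$std_residuals
}

#' @export
fitted.qsar_mlr <- function(object, ...) object$fitted

#' Predict activities from a fitted QSAR model
#'
#' @param object a [qsar_mlr] fit.
#' @param newdata data.frame or matrix containing the model's descriptor
#'   columns; defaults to the training data.
#' @param leverage logical; if `TRUE` return a data.frame with the
#'   prediction and the leverage of each query point in the training
#'   descriptor space.
#' @param ... unused.
#' @return numeric vector of predictions, or a data.frame when
#'   `leverage = TRUE`.
#' @export
predict.qsar_mlr <- function(object, newdata = NULL, leverage = FALSE, ...) {
  if (is.null(newdata)) newdata <- object$x
  pred <- predict(object$equation, newdata)
  if (!leverage) return(pred)
  data.frame(pred = pred, leverage = leverage_of(object, newdata))
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  structure(list(fit = object), class = "summary.qsar_mlr")
}

#' @export
print.summary.qsar_mlr <- function(x, digits = 4, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  cat("\nCoefficients:\n")
  stats::printCoefmat(fit$coef_table, digits = digits)
  cat(sprintf("\nMSE (SSE/n) = %.4f;  MSE (SSE/(n-k-1)) = %.4f\n",
              fit$stats$mse, fit$stats$mse_df))
  if (!is.null(fit$vif)) {
    cat("\nMulticollinearity (VIF):\n")
    print(fit$vif, digits = digits, row.names = FALSE)
  }
  cat(sprintf("\nApplicability domain: h* = 3(k+1)/n = %.4f; %d/%d training compounds with h > h*\n",
              fit$ad$h_star, sum(fit$ad$leverages > fit$ad$h_star), fit$stats$n))
  invisible(x)
}

#' Simulate responses from a fitted QSAR model
#'
#' Draws new activity vectors from the fitted linear predictor plus
#' Gaussian noise at the residual scale `sqrt(SSE/(n-k-1))`.
#'
#' @param object a [qsar_mlr] fit.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed (caller's stream is preserved).
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated responses.
#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$stats$n
  sims <- with_seed(seed, {
    replicate(nsim, object$fitted +
                stats::rnorm(n, sd = object$ad$residual_scale),
              simplify = FALSE)
  })
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Williams plot of a fitted QSAR model
#'
#' Plots standardized residuals against leverage for the training
#' compounds (and, optionally, leverage of new compounds at residual 0
#' on a rug), with the leverage threshold `h*` and the +/-2 standard
#' deviation bands that delimit the applicability domain.
#'
#' @param x a [qsar_mlr] fit.
#' @param newdata optional descriptor rows for additional (test/screen)
#'   compounds, shown by leverage only.
#' @param ... passed to [graphics::plot()].
#' @return the [williams()] data.frame, invisibly.
#' @export
plot.qsar_mlr <- function(x, newdata = NULL, ...) {
  w <- williams(x, newdata = newdata)
  h_star <- attr(w, "h_star")
  xlim <- range(c(w$leverage, h_star * 1.1))
  ylim <- range(c(w$std_residual, -2.5, 2.5), na.rm = TRUE)
  tr <- w$set == "train"
  graphics::plot(w$leverage[tr], w$std_residual[tr],
                 xlab = "leverage (h)", ylab = "standardized residual",
                 xlim = xlim, ylim = ylim, pch = 19,
                 main = "Williams plot", ...)
  if (any(!tr)) graphics::rug(w$leverage[!tr], col = "red")
  graphics::abline(h = c(-2, 2), lty = 2)
  graphics::abline(v = h_star, lty = 3)
  graphics::mtext(sprintf("h* = %.3f", h_star), side = 3, adj = 1, cex = 0.8)
  invisible(w)
}

#' Variance inflation factors
#'
#' For each descriptor column, VIF = 1/(1 - R_j^2) where R_j^2 comes
#' from regressing that column on all the others (with intercept).  The
#' conventional QSAR reading is applied as a verdict: between 1 and 4
#' the model is acceptable, above 5 it is unstable, in between it is
#' flagged for caution.
#'
#' @param x numeric matrix or data.frame of descriptor values, at least
#'   two columns, more rows than columns.
#' @return data.frame with columns `descriptor`, `r2`, `vif`, `verdict`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' compute_vif(x)
#' @export
compute_vif <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  check_that(is.matrix(x) && is.numeric(x), "`x` must be a numeric matrix")
  k <- ncol(x)
  check_that(k >= 2L, "VIF is undefined for fewer than 2 descriptors")
  check_that(nrow(x) > k, "need more rows than columns")
  r2 <- vapply(seq_len(k), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
  }, numeric(1L))
  vif <- 1 / (1 - r2)
  verdict <- ifelse(vif > 5, "unstable", ifelse(vif > 4, "caution", "acceptable"))
  data.frame(descriptor = colnames(x), r2 = r2, vif = vif,
             verdict = verdict, stringsAsFactors = FALSE)
}
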