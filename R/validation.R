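#' Leave-one-out cross-validated Q-squared
#'
#' `Q2 = 1 - PRESS/SST`, with `PRESS = sum (y_i - yhat_(-i))^2` over
#' deleted predictions and SST taken about the full-sample mean of `y`.
#' The default path uses the hat-matrix shortcut for OLS, where the
#' deleted residual is `e_i / (1 - h_ii)`; `method = "refit"` refits the
#' model n times with one compound left out each time, which is the
#' slow-but-transparent route the shortcut is verified against.
#'
#' @param object a fitted [qsar_mlr] model, or a descriptor matrix (in
#'   which case `y` is required).
#' @param y activity vector when `object` is a matrix.
#' @param method `"hat"` (shortcut, default) or `"refit"`.
#' @return Q-squared (at most 1; can be negative for models worse than
#'   the mean).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(57), 19, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 7 + x %*% c(1.5, -1.2, 0.8) + rnorm(19, sd = 0.5)
#' loo_q2(x, y)
#' @export
loo_q2 <- function(object, y = NULL, method = c("hat", "refit")) {
  method <- match.arg(method)
  if (inherits(object, "qsar_mlr")) {
    x <- object$x
    y <- object$y
    h <- object$ad$leverages
    e <- object$residuals
  } else {
    if (is.data.frame(object)) object <- as.matrix(object)
    check_that(is.matrix(object) && !is.null(y), "supply a qsar_mlr fit or (matrix, y)")
    x <- object
    y <- as.numeric(y)
    z <- cbind(1, x)
    fit <- stats::lm.fit(z, y)
    check_that(fit$rank == ncol(z), "design is rank deficient")
    e <- fit$residuals
    q1 <- qr.Q(fit$qr)
    h <- rowSums(q1^2)
  }
  n <- length(y)
  check_that(n >= ncol(x) + 3L, "need n >= k + 3 for leave-one-out")
  sst <- sum((y - mean(y))^2)
  if (method == "hat") {
    check_that(all(h < 1 - 1e-12),
               "a training leverage equals 1; deleted residual undefined")
    press <- sum((e / (1 - h))^2)
  } else {
    pred <- vapply(seq_len(n), function(i) {
      f <- stats::lm.fit(cbind(1, x[-i, , drop = FALSE]), y[-i])
      sum(c(1, x[i, ]) * f$coefficients)
    }, numeric(1L))
    press <- sum((y - pred)^2)
  }
  1 - press / sst
}

#' External determination coefficient on a test set
#'
#' Agreement between observed and predicted activities of held-out
#' compounds.  Two conventions circulate in the QSAR literature and can
#' differ materially; both are available: `"pearson"` (default) is the
#' squared Pearson correlation of observed vs predicted, `"ss"` is
#' `1 - SSE/SST` with SST about the observed test mean.
#'
#' @param observed numeric vector of observed activities (>= 3 values).
#' @param predicted numeric vector of predictions, same length.
#' @param method `"pearson"` or `"ss"`.
#' @return numeric scalar.
#' @examples
#' external_r2(c(1, 2, 3), c(1, 2, 4))  # 27/28 = 0.9643
#' @export
external_r2 <- function(observed, predicted, method = c("pearson", "ss")) {
  method <- match.arg(method)
  check_that(length(observed) == length(predicted) && length(observed) >= 3L,
             "need >= 3 paired observations")
  check_that(all(is.finite(observed)) && all(is.finite(predicted)),
             "non-finite values")
  check_that(stats::sd(observed) > 0 && stats::sd(predicted) > 0,
             "correlation undefined: constant observations or predictions")
  if (method == "pearson") {
    stats::cor(observed, predicted)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' Y-randomization (response-scrambling) test
#'
#' Repeatedly permutes the activity vector, refits the model after each
#' shuffle, and records the training R-squared and leave-one-out
#' Q-squared.  A real structure-activity relationship should collapse
#' under scrambling; shuffled models rivalling the original indicate
#' chance correlation.  By default the model's own descriptor subset is
#' refitted; with `reselect = TRUE` (and a full descriptor table) the
#' GFA selection is rerun on every shuffle, the stricter protocol.
#'
#' @param object a fitted [qsar_mlr] model.
#' @param n_iter number of random shuffles (default 10).
#' @param seed optional RNG seed (caller's stream preserved).
#' @param reselect rerun descriptor selection on each shuffle.
#' @param descriptors full descriptor matrix, required when
#'   `reselect = TRUE`.
#' @param control [gfa_control()] for reselection.
#' @param permutations optional list of index vectors overriding the
#'   random shuffles (e.g. `list(seq_along(y))` for the identity
#'   permutation); its length overrides `n_iter`.
#' @return object of class `"qsar_yrand"`: data.frame `iterations`
#'   (iteration, R2, Q2), `original_R2`, `original_Q2`, and
#'   `chance_correlation` — `TRUE` if any shuffled R-squared reaches the
#'   original or the mean shuffled R-squared exceeds 0.5.
#' @export
y_randomize <- function(object, n_iter = 10, seed = NULL, reselect = FALSE,
                        descriptors = NULL, control = gfa_control(),
                        permutations = NULL) {
  stopifnot(inherits(object, "qsar_mlr"))
  check_that(is_count(n_iter), "`n_iter` must be a positive integer")
  if (reselect) {
    check_that(!is.null(descriptors),
               "`descriptors` (full table) is required when reselect = TRUE")
  }
  y <- object$y
  n <- length(y)
  if (is.null(permutations)) {
    permutations <- with_seed(seed, {
      replicate(n_iter, sample.int(n), simplify = FALSE)
    })
  }
  rows <- lapply(seq_along(permutations), function(i) {
    yp <- y[permutations[[i]]]
    if (reselect) {
      ctl <- control
      if (!is.null(seed)) ctl$seed <- seed + i
      sel <- gfa_select(descriptors, yp, k = object$stats$k, control = ctl)
      fit <- fit_mlr(descriptors[, sel$best_subset, drop = FALSE], yp)
    } else {
      fit <- fit_mlr(object$x, yp)
    }
    data.frame(iteration = i, R2 = fit$stats$R2, Q2 = fit$q2)
  })
  iters <- do.call(rbind, rows)
  structure(list(
    iterations = iters,
    original_R2 = object$stats$R2,
    original_Q2 = object$q2,
    chance_correlation = any(iters$R2 >= object$stats$R2) || mean(iters$R2) > 0.5
  ), class = "qsar_yrand")
}

#' @export
print.qsar_yrand <- function(x, digits = 3, ...) {
  cat(sprintf("Y-randomization: %d shuffles (original R2 = %.3f, Q2 = %.3f)\n",
              nrow(x$iterations), x$original_R2, x$original_Q2))
  print(x$iterations, digits = digits, row.names = FALSE)
  cat(if (x$chance_correlation)
    "WARNING: shuffled models rival the original (possible chance correlation)\n"
    else "no evidence of chance correlation\n")
  invisible(x)
}

#' Validate a QSAR model against the standard acceptance rules
#'
#' Combines internal, external and collinearity checks: the model is
#' internally predictive if the leave-one-out Q-squared exceeds 0.5
#' (strictly), stable if no descriptor's VIF exceeds 5, and overall
#' valid only if both hold.  When test-set data are supplied the
#' external R-squared is reported under both conventions of
#' [external_r2()].
#'
#' @param object a fitted [qsar_mlr] model.
#' @param newdata,y_test optional test-set descriptors and observed
#'   activities for external validation.
#' @param q2_threshold validity cut-off for Q-squared (default 0.5).
#' @param vif_limit instability cut-off for VIF (default 5).
#' @return object of class `"qsar_validation"`: `Q2`, `R2_train`,
#'   `MSE_train`, `R2_test` / `R2_test_ss` (or `NA`), `q2_pass`,
#'   `vif_pass`, `overall_valid`.
#' @export
qsar_validate <- function(object, newdata = NULL, y_test = NULL,
                          q2_threshold = 0.5, vif_limit = 5) {
  stopifnot(inherits(object, "qsar_mlr"))
  r2_test <- r2_test_ss <- NA_real_
  if (!is.null(newdata)) {
    check_that(!is.null(y_test), "`y_test` required with `newdata`")
    pred <- predict(object, newdata)
    r2_test <- external_r2(y_test, pred, method = "pearson")
    r2_test_ss <- external_r2(y_test, pred, method = "ss")
  }
  q2_pass <- isTRUE(object$q2 > q2_threshold)
  vif_pass <- is.null(object$vif) || all(object$vif$vif <= vif_limit)
  structure(list(
    Q2 = object$q2,
    R2_train = object$stats$R2,
    MSE_train = object$stats$mse,
    R2_test = r2_test,
    R2_test_ss = r2_test_ss,
    q2_pass = q2_pass,
    vif_pass = vif_pass,
    overall_valid = q2_pass && vif_pass
  ), class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat(sprintf("Q2 = %.3f (pass: %s), R2_train = %.3f, MSE = %.3f\n",
              x$Q2, x$q2_pass, x$R2_train, x$MSE_train))
  if (!is.na(x$R2_test))
    cat(sprintf("R2_test (Pearson) = %.3f, R2_test (1-SSE/SST) = %.3f\n",
                x$R2_test, x$R2_test_ss))
  cat(sprintf("VIF pass: %s; overall valid: %s\n", x$vif_pass, x$overall_valid))
  invisible(x)
}
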