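test_that("leave-one-out Q2 is exact for noiseless data and bounded by R2", {
  inst <- rand_instance(n = 19, k = 3, noise_sd = 0, seed = 1)
  expect_equal(loo_q2(inst$x, inst$y), 1, tolerance = 1e-10)

  for (s in 1:10) {
    inst <- rand_instance(n = 19, k = 3, noise_sd = 1, seed = s)
    fit <- fit_mlr(inst$x, inst$y)
    expect_lte(fit$q2, fit$stats$R2)  # PRESS >= SSE
  }
})

test_that("hat-matrix shortcut equals brute-force refitting", {
  for (s in 1:10) {
    inst <- rand_instance(n = 19, k = 3, noise_sd = 1.5, seed = 100 + s)
    expect_equal(loo_q2(inst$x, inst$y, method = "hat"),
                 loo_q2(inst$x, inst$y, method = "refit"),
                 tolerance = 1e-10)
  }
})

test_that("Q2 collapses when the response carries no signal", {
  set.seed(19)
  x <- matrix(rnorm(19 * 3), 19, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(19)
  expect_lt(loo_q2(x, y), 0.5)
})

test_that("external R2 matches hand computation under both conventions", {
  expect_equal(external_r2(c(1, 2, 3), c(1, 2, 4)), 27 / 28, tolerance = 1e-12)
  expect_equal(external_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  # Pearson form is shift-invariant, the SS form is not
  obs <- c(5.5, 6.1, 7.3, 8.0)
  expect_equal(external_r2(obs, obs + 2), 1, tolerance = 1e-12)
  expect_lt(external_r2(obs, obs + 2, method = "ss"), 0)
  expect_equal(external_r2(obs, obs, method = "ss"), 1)
  expect_error(external_r2(obs, rep(1, 4)), "undefined")
  expect_error(external_r2(obs[1:2], obs[1:2]), ">= 3")
})

test_that("Y-randomization records shuffles and flags honestly", {
  sim <- study_fixture()
  tr <- match(sim$split$train, rownames(sim$descriptors))
  y <- sim$activities$pic50[match(rownames(sim$descriptors),
                                  sim$activities$compound_id)]
  fit <- fit_mlr(sim$descriptors[tr, ], y[tr],
                 descriptors = names(sim$truth$coefficients))
  yr <- y_randomize(fit, n_iter = 10, seed = 77)
  expect_equal(nrow(yr$iterations), 10L)
  expect_equal(yr$original_R2, fit$stats$R2)
  # strong planted signal: no shuffle should rival the original model
  expect_true(all(yr$iterations$R2 < yr$original_R2))
  expect_false(yr$chance_correlation)

  # identity permutation reproduces the original fit exactly
  yr_id <- y_randomize(fit, permutations = list(seq_along(fit$y)))
  expect_identical(yr_id$iterations$R2, fit$stats$R2)
  expect_identical(yr_id$iterations$Q2, fit$q2)
})

test_that("random shuffles preserve the response multiset and respond to seed", {
  inst <- rand_instance(n = 19, k = 3, seed = 21)
  fit <- fit_mlr(inst$x, inst$y)
  # same seed -> same shuffles, different seed -> different
  a <- y_randomize(fit, n_iter = 5, seed = 1)
  b <- y_randomize(fit, n_iter = 5, seed = 1)
  d <- y_randomize(fit, n_iter = 5, seed = 2)
  expect_identical(a$iterations, b$iterations)
  expect_false(identical(a$iterations, d$iterations))
})

test_that("pure-noise responses rarely fit by chance at this sample size", {
  set.seed(31)
  x <- matrix(rnorm(19 * 3), 19, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fit_mlr(x, rnorm(19))
  yr <- y_randomize(fit, n_iter = 200, seed = 8)
  expect_lt(mean(yr$iterations$R2), 0.35)
})

test_that("validation verdicts follow the thresholds strictly", {
  sim <- study_fixture()
  tr <- match(sim$split$train, rownames(sim$descriptors))
  te <- match(sim$split$test, rownames(sim$descriptors))
  y <- sim$activities$pic50[match(rownames(sim$descriptors),
                                  sim$activities$compound_id)]
  fit <- fit_mlr(sim$descriptors[tr, ], y[tr],
                 descriptors = names(sim$truth$coefficients))
  val <- qsar_validate(fit, newdata = sim$descriptors[te, ], y_test = y[te])
  expect_true(val$q2_pass)
  expect_true(val$vif_pass)
  expect_true(val$overall_valid)
  expect_false(is.na(val$R2_test))

  # Q2 exactly at the threshold does not pass (strict inequality)
  fake <- fit
  fake$q2 <- 0.5
  expect_false(qsar_validate(fake)$q2_pass)
  fake$q2 <- 0.60
  expect_true(qsar_validate(fake)$q2_pass)
  # any VIF above 5 invalidates
  fake$vif$vif[1] <- 5.5
  v <- qsar_validate(fake)
  expect_false(v$vif_pass)
  expect_false(v$overall_valid)
})
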