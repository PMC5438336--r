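test_that("OLS fit recovers closed-form and noiseless cases", {
  # exact simple regression: y = x through collinear points
  x3 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "x"))
  fit <- fit_mlr(x3, c(0, 1, 2))
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-12)

  inst <- rand_instance(n = 19, k = 3, noise_sd = 0, seed = 3)
  fit0 <- fit_mlr(inst$x, inst$y)
  expect_equal(unname(fit0$coefficients),
               c(inst$intercept, inst$beta), tolerance = 1e-8)
  expect_equal(fit0$stats$R2, 1, tolerance = 1e-12)
  expect_equal(fit0$stats$mse, 0, tolerance = 1e-16)
})

test_that("fit statistics agree with the reference implementation", {
  for (s in 1:5) {
    inst <- rand_instance(n = 19, k = 3, noise_sd = 1, seed = s)
    fit <- fit_mlr(inst$x, inst$y)
    ref <- summary(lm(inst$y ~ inst$x))
    expect_equal(fit$stats$R2, ref$r.squared, tolerance = 1e-10)
    expect_equal(fit$stats$F, unname(ref$fstatistic[1L]), tolerance = 1e-8)
    refp <- pf(ref$fstatistic[1L], ref$fstatistic[2L], ref$fstatistic[3L],
               lower.tail = FALSE)
    expect_equal(fit$stats$p_value, unname(refp), tolerance = 1e-8)
    expect_equal(fit$stats$mse_df, ref$sigma^2, tolerance = 1e-10)
  }
})

test_that("OLS invariants hold", {
  inst <- rand_instance(n = 25, k = 4, noise_sd = 0.8, seed = 6)
  fit <- fit_mlr(inst$x, inst$y)
  expect_equal(mean(fit$fitted), mean(inst$y), tolerance = 1e-10)
  expect_lt(abs(sum(fit$residuals)), 1e-8)
  expect_equal(fit$stats$R2, cor(inst$y, fit$fitted)^2, tolerance = 1e-10)
  expect_equal(fit$stats$R^2, fit$stats$R2, tolerance = 1e-12)
  expect_equal(unname(predict(fit)), fit$fitted, tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the collinear column", {
  inst <- rand_instance(n = 15, k = 2, seed = 7)
  x <- cbind(inst$x, V3 = inst$x[, 1] + inst$x[, 2])
  expect_error(fit_mlr(x, inst$y), "rank deficient.*V3")
  expect_error(fit_mlr(inst$x[1:3, ], inst$y[1:3]), "n >= k \\+ 2")
})

test_that("published equations predict at the intercept on zero descriptors", {
  zero <- data.frame(AATS0p = 0, maxHBint8 = 0, GATS8v = 0, AATS3i = 0,
                     VR1_Dzm = 0)
  expect_equal(predict(pim_model("pim1"), zero), 6.92)
  expect_equal(predict(pim_model("pim2"), zero), -32.31)

  # all-zero coefficients give a constant prediction
  const <- qsar_equation(4.2, c(a = 0, b = 0))
  expect_equal(predict(const, data.frame(a = rnorm(5), b = rnorm(5))),
               rep(4.2, 5))
  expect_error(predict(pim_model("pim1"), data.frame(AATS0p = 1)),
               "missing descriptor")
})

test_that("formula interface matches the matrix interface and can select", {
  inst <- rand_instance(n = 20, k = 3, seed = 9)
  d <- data.frame(y = inst$y, inst$x)
  f1 <- qsar_mlr(y ~ V1 + V2 + V3, d)
  f2 <- fit_mlr(inst$x, inst$y)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)

  sim <- synthetic_qsar(synth_spec(n_descriptors = 10, block_size = 3,
                                   noise_sd = 0.1, seed = 12))
  dd <- data.frame(pic50 = sim$activities$pic50, sim$descriptors)
  fs <- qsar_mlr(pic50 ~ ., dd, select = 3, control = gfa_control(seed = 2))
  expect_setequal(fs$descriptors, names(sim$truth$coefficients))
  expect_s3_class(fs$selection, "gfa_fit")
})

test_that("VIF matches its closed form and verdict bands", {
  # exactly orthogonal centered columns -> VIF 1
  x <- qr.Q(qr(cbind(1, matrix(rnorm(40), 20, 2))))[, 2:3]
  colnames(x) <- c("a", "b")
  v <- compute_vif(x)
  expect_equal(v$vif, c(1, 1), tolerance = 1e-9)
  expect_equal(v$verdict, c("acceptable", "acceptable"))

  # r = 0.9 -> VIF = 1/(1 - 0.81) = 5.263, unstable
  v9 <- compute_vif(corr_pair(n = 20, r = 0.9))
  expect_equal(v9$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
  expect_equal(v9$verdict, rep("unstable", 2))

  # VIF 2.376 (a published multicollinearity value) is acceptable
  r <- sqrt(1 - 1 / 2.376)
  v2 <- compute_vif(corr_pair(n = 20, r = r))
  expect_equal(v2$vif, rep(2.376, 2), tolerance = 1e-9)
  expect_equal(v2$verdict, rep("acceptable", 2))

  # caution band between 4 and 5
  r45 <- sqrt(1 - 1 / 4.5)
  expect_equal(compute_vif(corr_pair(n = 20, r = r45))$verdict,
               rep("caution", 2))

  expect_error(compute_vif(matrix(rnorm(10), 10, 1)), "fewer than 2")
})

test_that("VIF is never below 1", {
  for (s in 1:10) {
    x <- matrix(rnorm(19 * 3), 19, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_true(all(compute_vif(x)$vif >= 1 - 1e-9))
  }
})

test_that("simulate draws at the residual scale and is seed-stable", {
  inst <- rand_instance(n = 19, k = 3, noise_sd = 0.5, seed = 10)
  fit <- fit_mlr(inst$x, inst$y)
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(19L, 3L))
  big <- simulate(fit, nsim = 200, seed = 6)
  sds <- apply(big - fit$fitted, 2, sd)
  expect_equal(mean(sds), fit$ad$residual_scale, tolerance = 0.15)
})
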