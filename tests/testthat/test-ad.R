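test_that("the leverage threshold follows 3(k+1)/n", {
  expect_equal(hat_threshold(3, 19), 3 * 4 / 19)
  expect_equal(round(hat_threshold(3, 19), 2), 0.63)
  expect_equal(hat_threshold(0, 3), 1)
})

test_that("training leverages have hat-matrix structure", {
  for (s in 1:5) {
    inst <- rand_instance(n = 19, k = 3, noise_sd = 1, seed = 200 + s)
    fit <- fit_mlr(inst$x, inst$y)
    h <- leverage(fit)
    expect_equal(sum(h), 4, tolerance = 1e-8)          # trace = k + 1
    expect_true(all(h >= 1 / 19 - 1e-12 & h <= 1 + 1e-12))
    # agreement with an independent explicit-inverse computation
    z <- cbind(1, inst$x)
    h_ref <- diag(z %*% solve(crossprod(z)) %*% t(z))
    expect_equal(h, unname(h_ref), tolerance = 1e-10)
  }
})

test_that("leverage of query points behaves geometrically", {
  inst <- rand_instance(n = 19, k = 3, noise_sd = 1, seed = 5)
  fit <- fit_mlr(inst$x, inst$y)
  # the training centroid attains the minimum hat value 1/n
  centroid <- as.data.frame(t(colMeans(inst$x)))
  expect_equal(leverage(fit, centroid), 1 / 19, tolerance = 1e-12)
  # a point far outside the cloud exceeds h*
  far <- as.data.frame(t(colMeans(inst$x) + 50 * apply(inst$x, 2, sd)))
  expect_gt(leverage(fit, far), fit$ad$h_star)
  expect_error(leverage(fit, data.frame(V1 = 1)), "missing descriptor")

  # duplicating every training row halves every leverage
  x2 <- rbind(inst$x, inst$x)
  ctx2 <- ad_context(x2, rep(0, 38))
  expect_equal(leverage(ctx2)[1:19], leverage(fit) / 2, tolerance = 1e-10)
})

test_that("Williams classification applies the band rules with in-domain boundaries", {
  inst <- rand_instance(n = 19, k = 3, noise_sd = 1, seed = 17)
  fit <- fit_mlr(inst$x, inst$y)
  w <- williams(fit)
  h_star <- attr(w, "h_star")
  expect_equal(h_star, 3 * 4 / 19)
  lev_out <- w$leverage > h_star
  res_out <- abs(w$std_residual) > 2
  expect_equal(w$status == "leverage_outlier", lev_out & !res_out)
  expect_equal(w$status == "response_outlier", res_out & !lev_out)
  expect_equal(w$status == "in_domain", !lev_out & !res_out)

  # constructed outliers: a remote x-point on the regression line is a
  # leverage outlier only; a gross response error in the cluster is a
  # response outlier only
  x1 <- matrix(c(seq(0, 1, length.out = 9), 8), ncol = 1,
               dimnames = list(NULL, "d"))
  y1 <- 2 * x1[, 1]
  y1[5] <- y1[5] + 3
  w1 <- williams(fit_mlr(x1, y1))
  expect_equal(w1$status[10], "leverage_outlier")
  expect_equal(w1$status[5], "response_outlier")
  expect_true(all(w1$status[-c(5, 10)] == "in_domain"))
})

test_that("classification is order-invariant and new compounds are leverage-only", {
  sim <- study_fixture()
  tr <- match(sim$split$train, rownames(sim$descriptors))
  te <- match(sim$split$test, rownames(sim$descriptors))
  y <- sim$activities$pic50[match(rownames(sim$descriptors),
                                  sim$activities$compound_id)]
  fit <- fit_mlr(sim$descriptors[tr, ], y[tr],
                 descriptors = names(sim$truth$coefficients))
  w <- williams(fit, newdata = sim$descriptors[te, ])
  expect_equal(nrow(w), 25L)
  expect_true(all(is.na(w$std_residual[w$set == "new"])))
  expect_true(all(w$status[w$set == "new"] %in% c("in_domain", "leverage_outlier")))

  # permuting the test compounds permutes, but does not change, statuses
  perm <- c(3, 1, 2, 6, 5, 4)
  w2 <- williams(fit, newdata = sim$descriptors[te[perm], ])
  expect_equal(w2$status[w2$set == "new"],
               w$status[w$set == "new"][perm])
})

test_that("Williams export round-trips with its thresholds", {
  inst <- rand_instance(n = 19, k = 3, noise_sd = 1, seed = 23)
  fit <- fit_mlr(inst$x, inst$y)
  extra <- matrix(rnorm(18), 6, 3, dimnames = list(sprintf("t%d", 1:6),
                                                   colnames(inst$x)))
  w <- williams(fit, newdata = extra)
  expect_equal(nrow(w), 25L)
  path <- tempfile(fileext = ".tsv")
  write_williams(w, path)
  header <- readLines(path, n = 1L)
  expect_match(header, "h_star")
  expect_equal(as.numeric(sub(".*= ", "", header)), attr(w, "h_star"),
               tolerance = 1e-9)
  w2 <- read_williams(path)
  expect_equal(as.data.frame(w2), as.data.frame(w), tolerance = 1e-9)
  expect_equal(attr(w2, "h_star"), attr(w, "h_star"), tolerance = 1e-12)
})
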