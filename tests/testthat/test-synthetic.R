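test_that("descriptor generation is deterministic and respects its generating parameters", {
  sp <- synth_spec(n_compounds = 25, n_descriptors = 15, seed = 11)
  m1 <- generate_descriptors(sp)
  m2 <- generate_descriptors(sp)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(25L, 15L))
  expect_equal(colnames(m1)[1:3], c("D001", "D002", "D003"))

  # single-column table
  sp1 <- synth_spec(n_descriptors = 1, true_subset_size = 1,
                    true_coefficients = 1, seed = 1)
  expect_equal(ncol(generate_descriptors(sp1)), 1L)
})

test_that("block correlation shapes the descriptor covariance", {
  # independent descriptors: average |r| between distinct columns stays small
  mean_abs_r <- sapply(1:10, function(s) {
    m <- generate_descriptors(synth_spec(n_descriptors = 10, block_correlation = 0,
                                         block_size = 1, seed = s))
    cm <- abs(cor(m))
    mean(cm[upper.tri(cm)])
  })
  expect_lt(mean(mean_abs_r), 0.5)

  # correlated blocks: mean within-block correlation near the population value
  within_r <- sapply(1:30, function(s) {
    m <- generate_descriptors(synth_spec(n_descriptors = 10, block_correlation = 0.5,
                                         block_size = 5, seed = s))
    c1 <- cor(m[, 1:5]); c2 <- cor(m[, 6:10])
    mean(c(c1[upper.tri(c1)], c2[upper.tri(c2)]))
  })
  expect_equal(mean(within_r), 0.5, tolerance = 0.12)
  # across blocks ~ independent
  across_r <- sapply(1:30, function(s) {
    m <- generate_descriptors(synth_spec(n_descriptors = 10, block_correlation = 0.5,
                                         block_size = 5, seed = s))
    mean(cor(m[, 1:5], m[, 6:10]))
  })
  expect_lt(abs(mean(across_r)), 0.15)
})

test_that("activities follow the generating model exactly at zero noise", {
  sp <- synth_spec(n_descriptors = 15, noise_sd = 0, seed = 5)
  sim <- synthetic_qsar(sp)
  mu <- predict(sim$truth, sim$descriptors)
  expect_equal(sim$activities$pic50, unname(mu), tolerance = 1e-12)

  # refitting the true subset recovers the coefficients
  fit <- fit_mlr(sim$descriptors, sim$activities$pic50,
                 descriptors = names(sim$truth$coefficients))
  expect_equal(unname(fit$coefficients[-1]),
               unname(sim$truth$coefficients), tolerance = 1e-8)
  expect_equal(fit$stats$R2, 1, tolerance = 1e-10)

  # unknown descriptor in the truth rejected
  bad <- qsar_equation(0, c(NOPE = 1))
  expect_error(generate_activities(sim$descriptors, bad, 0), "missing descriptor")
})

test_that("parameter recovery holds across seeds at vanishing noise", {
  errs <- sapply(1:20, function(s) {
    sim <- synthetic_qsar(synth_spec(n_descriptors = 15, noise_sd = 0, seed = s))
    fit <- fit_mlr(sim$descriptors, sim$activities$pic50,
                   descriptors = names(sim$truth$coefficients))
    max(abs(fit$coefficients[-1] - sim$truth$coefficients))
  })
  expect_lt(max(errs), 1e-6)
})

test_that("noise monotonically erodes the training fit", {
  mean_r2 <- sapply(c(0.2, 0.9, 2.5), function(ns) {
    mean(sapply(1:20, function(s) {
      sim <- synthetic_qsar(synth_spec(n_descriptors = 15, noise_sd = ns, seed = s))
      tr <- sim$activities$role == "train"
      fit_mlr(sim$descriptors[tr, ], sim$activities$pic50[tr],
              descriptors = names(sim$truth$coefficients))$stats$R2
    }))
  })
  expect_true(all(diff(mean_r2) < 0))
})

test_that("the study-scale dataset matches the published design", {
  sim <- study_dataset(seed = 1)
  expect_equal(sim$spec$n_compounds, 25L)
  expect_equal(sim$spec$n_descriptors, 200L)
  expect_length(sim$split$train, 19L)
  expect_length(sim$split$test, 6L)
  expect_length(sim$truth$coefficients, 3L)
  tr <- match(sim$split$train, rownames(sim$descriptors))
  fit <- fit_mlr(sim$descriptors[tr, ], sim$activities$pic50[tr],
                 descriptors = names(sim$truth$coefficients))
  expect_gt(fit$stats$R2, 0.6)
  expect_lt(fit$stats$R2, 0.95)
})

test_that("the pinned fixture loads and is internally consistent", {
  fx <- study_fixture()
  expect_equal(nrow(fx$descriptors), 25L)
  expect_length(fx$split$train, 19L)
  expect_length(fx$split$test, 6L)
  # recorded truth + noise structure: residuals from the truth have roughly
  # the recorded noise scale
  res <- fx$activities$pic50 - predict(fx$truth, fx$descriptors)
  expect_lt(abs(sd(res) - fx$spec$noise_sd), 0.45)
})
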