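#' Specification of a synthetic QSAR dataset
#'
#' Defines the generating conditions for a descriptor matrix with a
#' planted sparse linear signal, mirroring the scale of a typical
#' small-n QSAR study: 25 compounds, a few hundred correlated
#' descriptors, a 3-descriptor true model, a 19/6 train/test split.
#' Descriptors are standard normal, organised in blocks with a common
#' within-block correlation (via a shared latent factor); the true
#' descriptors sit in distinct blocks so each carries correlated decoys.
#' Activities follow `pic50 = a0 + sum a_j x_j + eps`,
#' `eps ~ N(0, noise_sd^2)`.
#'
#' Default effect sizes (intercept 7, coefficients 1.5, -1.2, 0.8 on a
#' pIC50 scale) and `noise_sd = 0.9` put the population training
#' R-squared near 0.84, so that small-sample fits land inside the
#' 0.6-0.95 band typical of published small-n models.
#'
#' @param n_compounds number of compounds (default 25).
#' @param n_descriptors number of descriptor columns (default 200).
#' @param true_subset_size number of descriptors carrying signal
#'   (default 3).
#' @param true_intercept,true_coefficients generating model parameters;
#'   `true_coefficients` must have length `true_subset_size`.
#' @param noise_sd Gaussian noise standard deviation (pIC50 units).
#' @param block_correlation within-block descriptor correlation in
#'   `[0, 1)`.
#' @param block_size descriptors per correlated block.
#' @param n_test number of held-out test compounds.
#' @param seed RNG seed for the whole dataset.
#' @return list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_compounds = 25, n_descriptors = 200,
                       true_subset_size = 3, true_intercept = 7,
                       true_coefficients = c(1.5, -1.2, 0.8),
                       noise_sd = 0.9, block_correlation = 0.5,
                       block_size = 5, n_test = 6, seed = 1) {
  check_that(is_count(n_compounds) && is_count(n_descriptors) &&
               is_count(true_subset_size) && is_count(block_size),
             "sizes must be positive integers")
  check_that(true_subset_size <= n_descriptors,
             "true_subset_size must not exceed n_descriptors")
  check_that(length(true_coefficients) == true_subset_size,
             "true_coefficients must have length true_subset_size")
  check_that(is.numeric(n_test) && n_test >= 0 && n_test == floor(n_test) &&
               n_test < n_compounds, "need 0 <= n_test < n_compounds")
  check_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  check_that(is.numeric(block_correlation) && block_correlation >= 0 &&
               block_correlation < 1, "block_correlation must lie in [0, 1)")
  structure(list(n_compounds = n_compounds, n_descriptors = n_descriptors,
                 true_subset_size = true_subset_size,
                 true_intercept = true_intercept,
                 true_coefficients = true_coefficients,
                 noise_sd = noise_sd, block_correlation = block_correlation,
                 block_size = block_size, n_test = n_test, seed = seed),
            class = "synth_spec")
}

# descriptor names and the planted subset (first member of each of the
# first true_subset_size blocks, so every true descriptor has decoys)
synth_names <- function(p) sprintf("D%03d", seq_len(p))

planted_descriptors <- function(spec) {
  idx <- 1L + (seq_len(spec$true_subset_size) - 1L) * spec$block_size
  check_that(all(idx <= spec$n_descriptors),
             "not enough descriptors to place the planted subset in distinct blocks")
  synth_names(spec$n_descriptors)[idx]
}

#' Generate a block-correlated synthetic descriptor matrix
#'
#' Each block of `block_size` consecutive columns shares a latent
#' standard-normal factor: column `j` in a block is
#' `sqrt(rho) * z_block + sqrt(1 - rho) * e_j`, giving unit-variance
#' columns with population within-block correlation `rho` and
#' independence across blocks.
#'
#' @param spec a [synth_spec()].
#' @return numeric matrix (`n_compounds` by `n_descriptors`), columns
#'   `D001`, `D002`, ..., rows `C01`, `C02`, ...
#' @export
generate_descriptors <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_compounds
  p <- spec$n_descriptors
  rho <- spec$block_correlation
  with_seed(spec$seed, {
    m <- matrix(NA_real_, n, p)
    j <- 1L
    while (j <= p) {
      width <- min(spec$block_size, p - j + 1L)
      z <- stats::rnorm(n)
      for (col in j:(j + width - 1L)) {
        m[, col] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      }
      j <- j + width
    }
    dimnames(m) <- list(sprintf("C%02d", seq_len(n)), synth_names(p))
    m
  })
}

#' Generate activities from a linear generating model plus noise
#'
#' @param table descriptor matrix containing the truth's descriptor
#'   columns.
#' @param truth a [qsar_equation] (the generating model).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed (caller's stream preserved).
#' @return data.frame with columns `compound_id`, `pic50`.
#' @export
generate_activities <- function(table, truth, noise_sd, seed = NULL) {
  stopifnot(inherits(truth, "qsar_equation"))
  check_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  mu <- predict(truth, table)
  eps <- with_seed(seed, stats::rnorm(length(mu), sd = noise_sd))
  ids <- rownames(table)
  if (is.null(ids)) ids <- sprintf("C%02d", seq_along(mu))
  data.frame(compound_id = ids, pic50 = as.numeric(mu + eps),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic QSAR dataset
#'
#' Descriptors, activities, a random train/test split and the
#' generating model, all deterministic under `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return list of class `"qsar_sim"`: `descriptors` (matrix),
#'   `activities` (data.frame with `compound_id`, `pic50`, `role`),
#'   `split` (a [split_compounds()] result, `NULL` if `n_test = 0`),
#'   `truth` (a [qsar_equation]), `spec`.
#' @examples
#' sim <- synthetic_qsar(synth_spec(n_descriptors = 20, seed = 7))
#' fit_mlr(sim$descriptors[sim$split$train, ],
#'         sim$activities$pic50[match(sim$split$train,
#'                                    sim$activities$compound_id)],
#'         descriptors = names(sim$truth$coefficients))
#' @export
synthetic_qsar <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  desc <- generate_descriptors(spec)
  beta <- spec$true_coefficients
  names(beta) <- planted_descriptors(spec)
  truth <- qsar_equation(spec$true_intercept, beta, note = "synthetic generating model")
  acts <- generate_activities(desc, truth, spec$noise_sd, seed = spec$seed + 1L)
  split <- NULL
  acts$role <- "train"
  if (spec$n_test > 0) {
    test_ids <- with_seed(spec$seed + 2L,
                          sample(rownames(desc), spec$n_test))
    split <- split_compounds(rownames(desc), test_ids)
    acts$role[acts$compound_id %in% split$test] <- "test"
  }
  structure(list(descriptors = desc, activities = acts, split = split,
                 truth = truth, spec = spec), class = "qsar_sim")
}

#' @export
print.qsar_sim <- function(x, ...) {
  cat(sprintf("Synthetic QSAR dataset: %d compounds x %d descriptors (seed %d)\n",
              x$spec$n_compounds, x$spec$n_descriptors, x$spec$seed))
  cat("planted subset:", paste(names(x$truth$coefficients), collapse = ", "),
      sprintf("; noise sd = %.2f\n", x$spec$noise_sd))
  if (!is.null(x$split))
    cat(sprintf("split: %d train / %d test\n",
                length(x$split$train), length(x$split$test)))
  invisible(x)
}

#' Study-scale synthetic dataset
#'
#' Convenience wrapper for the default study-like conditions: 25
#' compounds, 200 descriptors in correlated blocks, a planted
#' 3-descriptor model, 19/6 train/test split.
#'
#' @param seed RNG seed.
#' @param n_descriptors number of descriptors (default 200).
#' @return a [synthetic_qsar()] dataset.
#' @export
study_dataset <- function(seed = 1, n_descriptors = 200) {
  synthetic_qsar(synth_spec(n_descriptors = n_descriptors, seed = seed))
}

#' Pinned study-like fixture
#'
#' A frozen copy of one study-scale synthetic dataset (60 descriptors,
#' seed 20170519) shipped as plain CSV/JSON so that downstream examples
#' and checks do not move when the generator evolves.
#'
#' @return a list shaped like a [synthetic_qsar()] result.
#' @export
study_fixture <- function() {
  dir <- system.file("extdata", package = "qsarlm")
  desc <- read_descriptors(file.path(dir, "synth_study_descriptors.csv"))
  acts <- read_activities(file.path(dir, "synth_study_activities.csv"))
  truth_raw <- jsonlite::read_json(file.path(dir, "synth_study_truth.json"),
                                   simplifyVector = TRUE)
  truth <- qsar_equation(truth_raw$intercept,
                         unlist(truth_raw$coefficients),
                         note = truth_raw$note)
  split <- split_compounds(acts$compound_id,
                           acts$compound_id[acts$role == "test"])
  structure(list(descriptors = desc, activities = acts, split = split,
                 truth = truth,
                 spec = do.call(synth_spec, truth_raw$spec)),
            class = "qsar_sim")
}
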