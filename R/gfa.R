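#' Friedman lack-of-fit score
#'
#' The fitness used for descriptor-subset selection:
#' `LOF = (SSE/n) / (1 - lambda * (p + 1 + d*p) / n)^2`, where SSE is
#' the residual sum of squares of the OLS fit of `y` on the `p` columns
#' of `x` plus an intercept, `d` is the smoothing parameter and `lambda`
#' a scaling factor.  The denominator inflates the error as the model
#' grows relative to the sample, so LOF trades fit quality against
#' parsimony.
#'
#' @param y numeric activity vector, length n.
#' @param x numeric matrix of the candidate descriptor subset (n by p).
#' @param d smoothing parameter (default 1).
#' @param lambda penalty scaling (default 1).
#' @return non-negative LOF score.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(57), 19, 3)
#' y <- x %*% c(1, -1, 0.5) + rnorm(19, sd = 0.2)
#' lof_score(y, x)
#' @export
lof_score <- function(y, x, d = 1, lambda = 1) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(x)
  check_that(nrow(x) == n, "nrow(x) must equal length(y)")
  check_that(n > p + 1L, "need n > p + 1")
  check_that(d >= 0 && lambda > 0, "need d >= 0 and lambda > 0")
  denom <- 1 - lambda * (p + 1 + d * p) / n
  check_that(denom > 0, "model too large for sample size (penalty denominator <= 0)")
  sse <- sum(stats::.lm.fit(cbind(1, x), y)$residuals^2)
  (sse / n) / denom^2
}

#' Control parameters for GFA descriptor selection
#'
#' Defaults follow common genetic-function-approximation practice:
#' mutation probability 0.5, crossover probability 1, smoothing
#' parameter 1.  Population size, generation count, elitism and the
#' stagnation stop are search-budget choices.
#'
#' @param pop_size population size.
#' @param n_generations maximum number of generations.
#' @param mutation_prob per-individual probability of a single-gene
#'   mutation (replace one descriptor with a random non-member).
#' @param crossover_prob probability that a child is produced by
#'   uniform-exchange crossover rather than copied from a parent.
#' @param d smoothing parameter of the LOF score.
#' @param lambda LOF penalty scaling.
#' @param elitism number of best individuals copied unchanged into the
#'   next generation (must be < `pop_size`).
#' @param stagnation stop after this many generations without
#'   improvement of the best score.
#' @param hall_of_fame number of distinct top subsets to report.
#' @param seed optional RNG seed; the caller's random stream is
#'   preserved.
#' @return list of class `"gfa_control"`.
#' @export
gfa_control <- function(pop_size = 100, n_generations = 200,
                        mutation_prob = 0.5, crossover_prob = 1,
                        d = 1, lambda = 1, elitism = 1, stagnation = 30,
                        hall_of_fame = 10, seed = NULL) {
  check_that(is_count(pop_size) && is_count(n_generations) &&
               is_count(hall_of_fame) && is_count(stagnation),
             "population, generations, stagnation and hall_of_fame must be positive integers")
  check_that(is_prob(mutation_prob) && is_prob(crossover_prob),
             "probabilities must lie in [0, 1]")
  check_that(is.numeric(elitism) && elitism >= 0 && elitism == floor(elitism) &&
               elitism < pop_size, "need 0 <= elitism < pop_size")
  check_that(d >= 0 && lambda > 0, "need d >= 0 and lambda > 0")
  structure(list(pop_size = pop_size, n_generations = n_generations,
                 mutation_prob = mutation_prob, crossover_prob = crossover_prob,
                 d = d, lambda = lambda, elitism = elitism,
                 stagnation = stagnation, hall_of_fame = hall_of_fame,
                 seed = seed), class = "gfa_control")
}

subset_key <- function(idx) paste(idx, collapse = ",")

# sample one element of a vector (safe for length-1 vectors, unlike sample())
pick_one <- function(v) v[sample.int(length(v), 1L)]

#' Genetic function algorithm for descriptor-subset selection
#'
#' Evolves fixed-size descriptor subsets to minimize the Friedman
#' lack-of-fit score ([lof_score()]) of the OLS fit on the subset.
#' Individuals are `k`-subsets of descriptor names; selection is by
#' size-2 tournament, children are formed by uniform-exchange crossover
#' (duplicate genes repaired by random replacement) and single-gene
#' mutation, and elitism keeps the best subsets across generations, so
#' the best score is non-increasing.  The search stops after
#' `n_generations` or once the best score has stagnated.
#'
#' @param x descriptor matrix or data.frame (named columns).
#' @param y numeric activity vector.
#' @param k subset size (default 3).
#' @param control a [gfa_control()] list.
#' @return object of class `"gfa_fit"`: `best_subset` (descriptor
#'   names), `best_lof`, `hall_of_fame` (data.frame of top subsets),
#'   `history` (per-generation best and mean LOF), `evaluations`,
#'   `k`, `seed`.
#' @seealso [exhaustive_subset()] for the enumeration oracle on small
#'   problems.
#' @export
gfa_select <- function(x, y, k = 3, control = gfa_control()) {
  if (is.data.frame(x)) x <- as.matrix(x)
  check_that(is.matrix(x) && !is.null(colnames(x)), "`x` must be a matrix with column names")
  check_that(is_count(k), "`k` must be a positive integer")
  p <- ncol(x)
  n <- length(y)
  check_that(p >= k, "fewer descriptors (%d) than subset size k = %d", p, k)
  check_that(n > k + 1L, "need more than k + 1 training compounds")
  if (n < 5 * k) {
    warning(sprintf("fewer than 5 compounds per descriptor (n = %d, k = %d); model may overfit",
                    n, k), call. = FALSE)
  }

  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fitness <- function(idx) {
    key <- subset_key(idx)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    evals <<- evals + 1L
    val <- lof_score(y, x[, idx, drop = FALSE], d = control$d,
                     lambda = control$lambda)
    cache[[key]] <- val
    val
  }

  result <- with_seed(control$seed, {
    if (p == k) {
      idx <- seq_len(p)
      history <- data.frame(generation = 1L, best = fitness(idx), mean = fitness(idx))
      list(pop = list(idx), scores = fitness(idx), history = history)
    } else {
      pop <- replicate(control$pop_size, sort(sample.int(p, k)), simplify = FALSE)
      scores <- vapply(pop, fitness, numeric(1L))
      history <- matrix(NA_real_, control$n_generations, 2L)
      best_so_far <- Inf
      stagnant <- 0L
      gens <- 0L
      for (g in seq_len(control$n_generations)) {
        ord <- order(scores)
        pop <- pop[ord]; scores <- scores[ord]
        history[g, ] <- c(scores[1L], mean(scores))
        gens <- g
        if (scores[1L] < best_so_far - 1e-15) {
          best_so_far <- scores[1L]
          stagnant <- 0L
        } else stagnant <- stagnant + 1L
        if (stagnant >= control$stagnation || g == control$n_generations) break

        tournament <- function() {
          ij <- sample.int(control$pop_size, 2L)
          pop[[ij[which.min(scores[ij])]]]
        }
        children <- vector("list", control$pop_size - control$elitism)
        for (i in seq_along(children)) {
          p1 <- tournament(); p2 <- tournament()
          if (stats::runif(1) < control$crossover_prob) {
            pick <- stats::runif(k) < 0.5
            child <- ifelse(pick, p1, p2)
            # repair duplicate genes by random replacement
            child <- unique(child)
            while (length(child) < k) {
              child <- c(child, pick_one(setdiff(seq_len(p), child)))
            }
          } else child <- p1
          if (stats::runif(1) < control$mutation_prob) {
            pos <- sample.int(k, 1L)
            child[pos] <- pick_one(setdiff(seq_len(p), child))
          }
          children[[i]] <- sort(child)
        }
        elite <- pop[seq_len(control$elitism)]
        pop <- c(elite, children)
        scores <- vapply(pop, fitness, numeric(1L))
      }
      ord <- order(scores)
      list(pop = pop[ord], scores = scores[ord],
           history = data.frame(generation = seq_len(gens),
                                best = history[seq_len(gens), 1L],
                                mean = history[seq_len(gens), 2L]))
    }
  })

  keys <- vapply(result$pop, subset_key, character(1L))
  first <- !duplicated(keys)
  top <- utils::head(which(first), control$hall_of_fame)
  hof <- data.frame(
    subset = vapply(result$pop[top],
                    function(i) paste(colnames(x)[i], collapse = "+"),
                    character(1L)),
    lof = result$scores[top], stringsAsFactors = FALSE)
  structure(list(
    best_subset = colnames(x)[result$pop[[1L]]],
    best_lof = result$scores[1L],
    hall_of_fame = hof,
    history = result$history,
    evaluations = evals,
    k = k,
    seed = control$seed
  ), class = "gfa_fit")
}

#' @export
print.gfa_fit <- function(x, ...) {
  cat(sprintf("GFA descriptor selection (k = %d): best LOF = %.6g\n",
              x$k, x$best_lof))
  cat("best subset:", paste(x$best_subset, collapse = ", "), "\n")
  cat(sprintf("%d generations, %d unique subsets evaluated\n",
              nrow(x$history), x$evaluations))
  invisible(x)
}

#' Exhaustive best-subset search by lack-of-fit
#'
#' Enumeration oracle for [gfa_select()]: evaluates every `k`-subset of
#' descriptors and returns the global LOF minimizer.  Ties are broken in
#' lexicographic order of the joined descriptor names.  Refuses problems
#' with more than `budget` subsets.
#'
#' @inheritParams gfa_select
#' @param d,lambda LOF parameters, as in [lof_score()].
#' @param budget maximum number of subsets to enumerate.
#' @return list with `subset` (descriptor names) and `lof`.
#' @export
exhaustive_subset <- function(x, y, k = 3, d = 1, lambda = 1, budget = 1e6) {
  if (is.data.frame(x)) x <- as.matrix(x)
  check_that(is.matrix(x) && !is.null(colnames(x)), "`x` must be a matrix with column names")
  p <- ncol(x)
  check_that(p >= k, "fewer descriptors than k")
  check_that(choose(p, k) <= budget,
             "combinatorial budget exceeded: C(%d, %d) > %g", p, k, budget)
  combos <- utils::combn(p, k)
  lofs <- apply(combos, 2L, function(idx)
    lof_score(y, x[, idx, drop = FALSE], d = d, lambda = lambda))
  best <- min(lofs)
  tied <- which(lofs <= best)
  labels <- vapply(tied, function(j)
    paste(sort(colnames(x)[combos[, j]]), collapse = "+"), character(1L))
  pick <- tied[order(labels)[1L]]
  list(subset = colnames(x)[combos[, pick]], lof = lofs[pick])
}
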