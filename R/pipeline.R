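#' Run the full QSAR workflow
#'
#' Orchestrates data loading (or synthetic generation), train/test
#' splitting, GFA descriptor selection, MLR fitting, internal/external
#' and Y-randomization validation, applicability-domain analysis and
#' (optionally) candidate screening, writing every artifact plus a run
#' manifest to an output directory.  Runs are deterministic: the same
#' configuration and seed produce byte-identical outputs.
#'
#' The configuration is a named list, or the path of a JSON/YAML file
#' holding one, with fields:
#' \describe{
#'   \item{input}{list with `descriptors` and `activities` CSV paths;
#'     test membership is taken from the activity `role` column unless
#'     `test_ids` is given.}
#'   \item{synthetic}{list of [synth_spec()] arguments.  Exactly one of
#'     `input` / `synthetic` must be present.}
#'   \item{test_ids}{optional explicit test-set compound ids.}
#'   \item{gfa}{list of [gfa_control()] arguments plus optional `k`
#'     (default 3).}
#'   \item{validation}{list: `n_iter` (default 10), `reselect`
#'     (default FALSE).}
#'   \item{candidates}{optional candidate CSV path for screening
#'     (columns per [screen_candidates()]).}
#'   \item{seed}{global seed; sub-seeds for selection, shuffling and
#'     simulation derive from it.}
#' }
#'
#' @param config named list or path to a JSON/YAML config file.
#' @param out_dir output directory (created; must not exist or be
#'   empty).  Partial outputs are removed if the run fails.
#' @param seed optional override of `config$seed`.
#' @return (invisibly) list with the fitted model, validation report,
#'   Williams data, screening report (or `NULL`) and the manifest.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "qsar_run")
#' res <- run_pipeline(list(synthetic = list(n_descriptors = 20, seed = 3),
#'                          gfa = list(k = 3, pop_size = 40),
#'                          seed = 3),
#'                     out_dir = out)
#' res$validation$overall_valid
#' }
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  check_that(is.list(config), "`config` must be a list or a config-file path")
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  check_that(xor(has_input, has_synth),
             "config must contain exactly one of `input` and `synthetic`")
  if (is.null(seed)) seed <- config$seed
  check_that(!is.null(seed) && is.numeric(seed), "a `seed` is required")
  seed <- as.integer(seed)

  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE))

  # --- data ----------------------------------------------------------
  if (has_synth) {
    spec_args <- config$synthetic
    if (is.null(spec_args$seed)) spec_args$seed <- seed
    sim <- synthetic_qsar(do.call(synth_spec, spec_args))
    desc <- sim$descriptors
    acts <- sim$activities
    split <- sim$split
  } else {
    check_that(all(c("descriptors", "activities") %in% names(config$input)),
               "config$input needs `descriptors` and `activities` paths")
    check_that(file.exists(config$input$descriptors) &&
                 file.exists(config$input$activities),
               "input file missing")
    desc <- read_descriptors(config$input$descriptors)
    acts <- read_activities(config$input$activities)
    test_ids <- config$test_ids
    if (is.null(test_ids)) test_ids <- acts$compound_id[acts$role == "test"]
    split <- split_compounds(rownames(desc), test_ids)
  }
  check_that(!is.null(split), "a non-empty test set is required")
  y_all <- acts$pic50[match(rownames(desc), acts$compound_id)]
  check_that(!anyNA(y_all), "every compound in the descriptor table needs an activity")
  tr <- rownames(desc) %in% split$train
  x_train <- desc[tr, , drop = FALSE]
  y_train <- y_all[tr]

  # --- selection + fit ----------------------------------------------
  gfa_args <- config$gfa
  k <- gfa_args$k %||% 3L
  gfa_args$k <- NULL
  if (is.null(gfa_args$seed)) gfa_args$seed <- seed + 1L
  ctl <- do.call(gfa_control, gfa_args)
  sel <- gfa_select(x_train, y_train, k = k, control = ctl)
  fit <- fit_mlr(x_train, y_train, descriptors = sel$best_subset)
  fit$selection <- sel

  # --- validation ----------------------------------------------------
  x_test <- desc[!tr, , drop = FALSE]
  y_test <- y_all[!tr]
  val <- qsar_validate(fit, newdata = x_test, y_test = y_test)
  vopts <- config$validation
  yr <- y_randomize(fit, n_iter = vopts$n_iter %||% 10L, seed = seed + 2L,
                    reselect = isTRUE(vopts$reselect), descriptors = x_train,
                    control = ctl)

  # --- applicability domain & screening ------------------------------
  wil <- williams(fit, newdata = x_test, newdata_ids = rownames(x_test))
  screen <- NULL
  if (!is.null(config$candidates)) {
    check_that(file.exists(config$candidates), "candidate file missing")
    cand <- utils::read.csv(config$candidates, stringsAsFactors = FALSE)
    screen <- screen_candidates(fit, cand)
  }

  # --- artifacts -----------------------------------------------------
  wj <- function(x, file) jsonlite::write_json(
    x, file.path(out_dir, file), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")
  utils::write.table(sel$hall_of_fame, file.path(out_dir, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wj(list(intercept = fit$equation$intercept,
          coefficients = as.list(fit$equation$coefficients)), "model.json")
  wj(fit$stats, "fit_stats.json")
  wj(unclass(val), "validation.json")
  utils::write.table(yr$iterations, file.path(out_dir, "yrandomization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_williams(wil, file.path(out_dir, "williams.tsv"))
  if (!is.null(screen)) {
    utils::write.table(screen$table, file.path(out_dir, "screening.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    wj(c(screen$counts, h_star = screen$h_star), "screening_summary.json")
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(package = "qsarlm",
                   version = as.character(utils::packageVersion("qsarlm")),
                   seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   selected = sel$best_subset,
                   overall_valid = val$overall_valid)
  wj(manifest, "manifest.json")

  ok <- TRUE
  invisible(list(fit = fit, validation = val, y_randomization = yr,
                 williams = wil, screening = screen, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_pipeline_config <- function(path) {
  check_that(file.exists(path), "config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
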