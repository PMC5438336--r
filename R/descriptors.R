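#' Read a molecular-descriptor table
#'
#' Reads descriptor output in the common "PaDEL dialect": a CSV whose
#' first column is the compound identifier (whatever its header says,
#' typically `Name`) and whose remaining columns are numeric descriptor
#' values.  Columns that contain missing or unparseable entries, and
#' zero-variance (constant) columns, carry no usable information at this
#' sample size and are dropped with a warning naming each one.
#'
#' @param path path to the CSV file.
#' @return numeric matrix, rows named by compound id, columns by
#'   descriptor name.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Name = c("a", "b", "c"),
#'                      D1 = c(1, 2, 3), D2 = c(0.5, 0.1, 0.9)),
#'           tf, row.names = FALSE)
#' read_descriptors(tf)
#' @export
read_descriptors <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       colClasses = "character")
  check_that(ncol(d) >= 3L, "descriptor CSV needs an id column and >= 2 descriptor columns")
  ids <- as.character(d[[1L]])
  check_that(!anyDuplicated(ids), "duplicate compound ids: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- d[-1L]
  parsed <- lapply(vals, function(col) suppressWarnings(as.numeric(col)))
  bad <- vapply(parsed, function(v) anyNA(v), logical(1L))
  const <- !bad & vapply(parsed, function(v) length(unique(v)) == 1L, logical(1L))
  drop <- bad | const
  if (any(drop)) {
    warning(sprintf(
      "dropping %d descriptor column(s): %s",
      sum(drop),
      paste0(names(vals)[drop], ifelse(bad[drop], " (missing/non-numeric)",
                                       " (constant)"), collapse = ", ")),
      call. = FALSE)
  }
  keep <- names(vals)[!drop]
  check_that(length(keep) >= 2L, "fewer than 2 usable descriptor columns after cleaning")
  m <- do.call(cbind, parsed[keep])
  dimnames(m) <- list(ids, keep)
  m
}

#' Write a descriptor table
#'
#' Inverse of [read_descriptors()]: writes a matrix of descriptor values
#' as a CSV with the compound id in the first column.
#'
#' @param x numeric matrix with row names (compound ids) and column
#'   names (descriptor names).
#' @param path output path.
#' @param id_header header used for the identifier column.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(x, path, id_header = "Name") {
  check_that(is.matrix(x) && !is.null(rownames(x)) && !is.null(colnames(x)),
             "`x` must be a matrix with row and column names")
  out <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1L] <- id_header
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split compounds into training and test sets
#'
#' Given the full roster of compound ids and a designated test set, the
#' remaining compounds form the training set, preserving the original
#' order of the table.
#'
#' @param ids character vector of all compound ids (table order).
#' @param test_ids character vector of ids held out for external
#'   validation; must be a non-empty proper subset of `ids`.
#' @return list with elements `train` and `test` (character vectors),
#'   class `"dataset_split"`.
#' @examples
#' split_compounds(as.character(1:25), as.character(c(1, 5, 8, 9, 23, 24)))
#' @export
split_compounds <- function(ids, test_ids) {
  ids <- as.character(ids)
  test_ids <- as.character(test_ids)
  check_that(!anyDuplicated(ids), "duplicate compound ids")
  check_that(length(test_ids) >= 1L, "test set must be non-empty")
  unknown <- setdiff(test_ids, ids)
  check_that(length(unknown) == 0L, "unknown test id(s): %s",
             paste(unknown, collapse = ", "))
  train <- ids[!ids %in% test_ids]
  check_that(length(train) >= 1L, "training set must be non-empty")
  structure(list(train = train, test = ids[ids %in% test_ids]),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Dataset split: %d training / %d test compounds\n",
              length(x$train), length(x$test)))
  invisible(x)
}
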