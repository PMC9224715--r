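# Canonical tabular data model: one row per patient, named continuous gait
# feature columns (units embedded in the names, e.g. "(m/s)", "(steps/min)"),
# a strictly positive measured walking distance in meters as the learning
# target, and a unique patient identifier.

abort_config <- function(msg) abort(msg, class = "gaitffdb_config_error")
abort_data   <- function(msg) abort(msg, class = "gaitffdb_data_error")
abort_io     <- function(msg) abort(msg, class = "gaitffdb_io_error")

#' Construct a feature table
#'
#' Validates and classes a data frame of per-patient gait features plus a
#' measured walking-distance target (meters). All non-identifier, non-target
#' columns are treated as features and must be numeric; missing feature cells
#' are allowed (they are imputed downstream by [fit_preprocess()]).
#'
#' @param x A data frame or tibble.
#' @param target Name of the target column (measured distance, meters).
#' @param id Name of the patient identifier column, or `NULL` to use an
#'   existing `patient_id` column or, failing that, the 0-based row index.
#' @return A `feature_table`: a tibble with `patient_id` first, feature
#'   columns in their original order, and the target column last.
#' @export
#' @examples
#' tbl <- tibble::tibble(f1 = rnorm(5), f2 = rnorm(5), dist = 100 + rnorm(5))
#' ft <- as_feature_table(tbl, target = "dist")
#' n_features(ft)
as_feature_table <- function(x, target, id = NULL) {
  x <- as_tibble(x)
  if (!is.character(target) || length(target) != 1L) {
    abort_config("`target` must be a single column name")
  }
  if (!target %in% names(x)) {
    abort_config(sprintf("target column '%s' not found in the table", target))
  }
  id <- id %||% (if ("patient_id" %in% names(x)) "patient_id" else NULL)
  if (is.null(id)) {
    x$patient_id <- as.character(seq_len(nrow(x)) - 1L)
    id <- "patient_id"
  } else if (!id %in% names(x)) {
    abort_config(sprintf("id column '%s' not found in the table", id))
  }
  ids <- as.character(x[[id]])
  if (anyDuplicated(ids)) {
    abort_data("patient identifiers are not unique")
  }
  feat <- setdiff(names(x), c(id, target))
  if (anyDuplicated(feat)) {
    abort_data("duplicated feature column names")
  }
  for (f in feat) {
    if (!is.numeric(x[[f]])) {
      abort_data(sprintf("feature column '%s' is not numeric", f))
    }
  }
  tgt <- x[[target]]
  if (!is.numeric(tgt)) abort_data(sprintf("target column '%s' is not numeric", target))
  if (any(tgt[!is.na(tgt)] <= 0)) {
    abort_data("target distances must be strictly positive")
  }
  out <- x[c(id, feat, target)]
  names(out)[1] <- "patient_id"
  out$patient_id <- ids
  structure(out,
            target = target,
            class = c("feature_table", class(out)))
}

#' @rdname as_feature_table
#' @param ft A `feature_table`.
#' @export
feature_names <- function(ft) {
  setdiff(names(ft), c("patient_id", attr(ft, "target")))
}

#' @rdname as_feature_table
#' @export
n_features <- function(ft) length(feature_names(ft))

#' @rdname as_feature_table
#' @export
target_name <- function(ft) attr(ft, "target")

# Feature columns as a plain numeric matrix (rows = patients).
feature_matrix <- function(ft) {
  as.matrix(ft[feature_names(ft)])
}

# Re-class after dplyr operations that may drop attributes.
restore_feature_table <- function(x, template) {
  as_feature_table(x, target = attr(template, "target"))
}

#' Read a feature table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first table ("." decimal
#' separator). Empty strings and `NA` are missing markers. Any other
#' non-numeric cell in a feature or target column is a data error reported
#' with its row and column.
#'
#' @param path Path to the CSV file.
#' @param target Name of the target (measured distance) column.
#' @param id Optional name of the identifier column; default uses
#'   `patient_id` when present, else the 0-based row index.
#' @param na Strings recognised as missing markers.
#' @return A [as_feature_table()] object.
#' @export
read_feature_table <- function(path, target, id = NULL, na = c("", "NA")) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = na, progress = FALSE,
                         show_col_types = FALSE)
  if (!target %in% names(raw)) {
    abort_config(sprintf("target column '%s' not found in %s", target, path))
  }
  id <- id %||% (if ("patient_id" %in% names(raw)) "patient_id" else NULL)
  numeric_cols <- setdiff(names(raw), id)
  for (col in numeric_cols) {
    vals <- raw[[col]]
    conv <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(conv))
    if (length(bad) > 0) {
      abort_data(sprintf(
        "non-numeric value '%s' in column '%s', row %d",
        vals[bad[1]], col, bad[1]))
    }
    raw[[col]] <- conv
  }
  as_feature_table(raw, target = target, id = id)
}

#' Write a feature table to CSV
#'
#' Numeric cells are written with full precision so a read/write/read cycle
#' reproduces the table bit-identically.
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  out <- as.data.frame(ft)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- format_full(out[[col]])
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     na = ""),
    error = function(e) abort_io(sprintf("cannot write %s: %s", path,
                                         conditionMessage(e))))
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features (target: %s)\n",
              nrow(x), n_features(x), attr(x, "target")))
  NextMethod()
}
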