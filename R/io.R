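#' Read a two-class dataset from CSV or ARFF
#'
#' CSV files need a header row; the label column defaults to the last
#' column. ARFF files (detected by the `.arff` extension) are read with
#' \pkg{foreign} and handled identically afterwards. Cells matching
#' `missing_markers` become `NA` and are left for fold-wise imputation.
#' Exactly two distinct labels are required; more raise an explicit
#' multiclass error (the model is binary).
#'
#' @param path file path.
#' @param label_col name of the label column, or `NULL` for the last column.
#' @param positive label to code as class 1 (default: lexicographically
#'   first).
#' @param missing_markers strings treated as missing in CSV input.
#' @return An [mml_data] object (possibly with `NA` cells).
#' @export
read_dataset <- function(path, label_col = NULL, positive = NULL,
                         missing_markers = c("", "NA", "?")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.arff$", path, ignore.case = TRUE)) {
    df <- foreign::read.arff(path)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          na.strings = missing_markers,
                          stringsAsFactors = FALSE)
  }
  if (is.null(label_col)) {
    label_col <- names(df)[ncol(df)]
  }
  if (!label_col %in% names(df)) {
    stop("label column '", label_col, "' not found in ", path)
  }
  y <- df[[label_col]]
  feat <- df[, setdiff(names(df), label_col), drop = FALSE]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      bad <- which(!is.na(feat[[j]]))[1L]
      stop("parse error: non-numeric value '", feat[[bad, j]],
           "' in column '", names(feat)[j], "', row ", bad)
    }
  }
  mml_data(as.matrix(feat), y, positive = positive)
}

MML_MODEL_FORMAT <- "1.0"

#' Serialize a fitted model to JSON
#'
#' Writes a structured JSON record with full double precision so that
#' `read_mml(write_mml(m))` restores the decision-relevant fields bit for
#' bit. Attribute indices are stored 1-based.
#'
#' @param model a fitted [mml] object.
#' @param path output file path.
#' @param seed optional integer recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_mml <- function(model, path, seed = NULL) {
  if (!inherits(model, "mml")) stop("'model' must be a fitted mml object")
  rec <- list(
    format_version = MML_MODEL_FORMAT,
    c1_in = model$c1_in,
    learning_attributes = as.integer(model$learning_attributes),
    boundaries = model$boundaries,
    per_set_errors = as.integer(model$per_set_errors),
    att = model$att,
    bound = model$bound,
    training_error = model$training_error,
    class_names = model$class_names,
    attribute_names = model$attribute_names,
    n_attributes = model$n_attributes,
    provenance = list(
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  # 17 significant digits: the shortest representation guaranteed to
  # round-trip an IEEE double bit for bit
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Deserialize a model written by [write_mml()]
#'
#' @param path JSON file path.
#' @return An object of class [mml].
#' @export
read_mml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("parse error reading model '", path, "': ",
                         conditionMessage(e))
                  })
  if (is.null(rec$format_version) ||
      !identical(as.character(rec$format_version), MML_MODEL_FORMAT)) {
    stop("incompatible model format: found '", rec$format_version,
         "', expected '", MML_MODEL_FORMAT, "'")
  }
  structure(
    list(
      c1_in = rec$c1_in,
      learning_attributes = as.integer(rec$learning_attributes),
      boundaries = as.numeric(rec$boundaries),
      per_set_errors = as.integer(rec$per_set_errors),
      att = as.integer(rec$att),
      bound = as.integer(rec$bound),
      training_error = as.integer(rec$training_error),
      class_names = as.character(rec$class_names),
      attribute_names = as.character(rec$attribute_names),
      n_attributes = as.integer(rec$n_attributes),
      provenance = rec$provenance
    ),
    class = "mml"
  )
}

#' Path to the packaged classifier-benchmark score matrix
#'
#' Balanced-accuracy scores of seven classifiers over thirteen published
#' two-class biomedical datasets, shipped as a plain CSV for the Friedman /
#' Holm comparison functions.
#'
#' @return File path inside the installed package.
#' @examples
#' friedman_ranks(read_score_matrix(benchmark_scores_path()))
#' @export
benchmark_scores_path <- function() {
  system.file("extdata", "balanced_accuracy_benchmark.csv",
              package = "sphereMML", mustWork = TRUE)
}
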