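#' Construct a descriptor matrix
#'
#' A compounds x descriptors numeric matrix aligned to a schema.  Missing
#' values are allowed at construction (and flagged) but rejected by the
#' modelling operations.
#'
#' @param values Numeric matrix, one row per compound; column names must be a
#'   subset of the schema codes if `schema` is given.
#' @param schema A `descriptor_schema`; columns of `values` are re-ordered to
#'   schema order and absent schema columns are added as `NA` (and flagged).
#' @param compound_ids Character vector of compound identifiers; defaults to
#'   `rownames(values)`.
#' @return A `descriptor_matrix` object (list with `values`, `schema`,
#'   `compound_ids`, `missing_columns`).
#' @export
descriptor_matrix <- function(values, schema = NULL, compound_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(compound_ids)) stop("compound_ids required", call. = FALSE)
  compound_ids <- as.character(compound_ids)
  if (length(compound_ids) != nrow(values)) {
    stop("compound_ids length does not match row count", call. = FALSE)
  }
  if (anyDuplicated(compound_ids)) {
    stop("duplicated compound ids: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- character(0)
  if (!is.null(schema)) {
    unknown <- setdiff(colnames(values), schema$code)
    if (length(unknown)) {
      warning("dropping column(s) not in schema: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      values <- values[, setdiff(colnames(values), unknown), drop = FALSE]
    }
    missing_cols <- setdiff(schema$code, colnames(values))
    if (length(missing_cols)) {
      pad <- matrix(NA_real_, nrow(values), length(missing_cols),
                    dimnames = list(NULL, missing_cols))
      values <- cbind(values, pad)
    }
    values <- values[, schema$code, drop = FALSE]
  } else {
    if (is.null(colnames(values))) stop("values must have column names", call. = FALSE)
    schema <- new_descriptor_schema(data.frame(
      code = colnames(values), family = "unspecified",
      column_code = NA_character_, solvent_code = NA_character_,
      parameter_code = NA_character_, stringsAsFactors = FALSE))
  }
  rownames(values) <- compound_ids
  structure(list(values = values, schema = schema,
                 compound_ids = compound_ids,
                 missing_columns = missing_cols),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("descriptor_matrix:", length(x$compound_ids), "compounds x",
      ncol(x$values), "descriptors\n")
  if (length(x$missing_columns)) {
    cat("  missing (flagged) columns:",
        paste(x$missing_columns, collapse = ", "), "\n")
  }
  if (anyNA(x$values)) cat("  contains missing values\n")
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' Read a descriptor matrix from CSV
#'
#' Expects a comma-separated UTF-8 file with `.` decimal separator, a header
#' row of descriptor codes and a first column `compound_id`.  Unknown columns
#' are reported with a warning; schema columns absent from the file are filled
#' with `NA` and flagged in `missing_columns`.
#'
#' @param path CSV file path.
#' @param schema Optional `descriptor_schema` to align to.
#' @return A `descriptor_matrix`.
#' @export
load_descriptor_matrix <- function(path, schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("descriptor CSV is empty or lacks descriptor columns: ", path,
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      col[!nzchar(trimws(col))] <- NA
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row %d, column '%s' in %s",
                     col[bad[1L]], bad[1L], names(vals)[j], path), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  descriptor_matrix(as.matrix(vals), schema = schema, compound_ids = ids)
}

#' Write a descriptor matrix to CSV
#'
#' @param x A `descriptor_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(x, path) {
  df <- data.frame(compound_id = x$compound_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import the supplementary-style Excel descriptor sheet
#'
#' Converts an `.xlsx` sheet laid out like the strict CSV dialect (first
#' column `compound_id`, remaining columns descriptor codes) into a
#' `descriptor_matrix`.  Requires the `readxl` package.
#'
#' @param path `.xlsx` file path.
#' @param sheet Sheet name or index (default 1).
#' @param schema Optional `descriptor_schema` to align to.
#' @return A `descriptor_matrix`.
#' @export
import_descriptor_xlsx <- function(path, sheet = 1, schema = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("the 'readxl' package is required for .xlsx import", call. = FALSE)
  }
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  descriptor_matrix(vals, schema = schema, compound_ids = ids)
}

#' Construct a clearance (CI) replicate table
#'
#' Long-format replicate observations of the clearance index, the regression
#' outcome.  CI is the compound's placental transfer rate divided by the
#' antipyrine transfer rate of the same perfusion, so it is dimensionless and
#' strictly positive (required by the 1/Y and 1/Y^2 weightings).
#'
#' @param compound_id Character vector.
#' @param replicate_id Vector of replicate labels, unique within compound.
#' @param ci Numeric vector of clearance indices, all > 0.
#' @return A `clearance_table` (data frame with those three columns).
#' @export
clearance_table <- function(compound_id, replicate_id, ci) {
  df <- data.frame(compound_id = as.character(compound_id),
                   replicate_id = as.character(replicate_id),
                   ci = as.numeric(ci), stringsAsFactors = FALSE)
  if (anyNA(df$ci)) stop("missing CI values", call. = FALSE)
  if (any(df$ci <= 0)) stop("CI values must be strictly positive", call. = FALSE)
  key <- paste(df$compound_id, df$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("replicate ids must be unique within compound", call. = FALSE)
  }
  structure(df, class = c("clearance_table", "data.frame"))
}

#' Read a clearance table from CSV
#'
#' Long CSV with columns `compound_id`, `replicate_id`, `ci`.
#'
#' @param path CSV file path.
#' @return A `clearance_table`.
#' @export
read_clearance <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "replicate_id", "ci")
  if (!all(need %in% names(df))) {
    stop("clearance CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  clearance_table(df$compound_id, df$replicate_id, df$ci)
}

#' Write a clearance table to CSV
#'
#' @param x A `clearance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clearance <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise a clearance table per compound
#'
#' @param x A `clearance_table`.
#' @return A `ci_summary` data frame with `compound_id`, `mean_ci`, `sd_ci`,
#'   `n_replicates`.
#' @export
ci_summary <- function(x) {
  sp <- split(x$ci, x$compound_id)
  df <- data.frame(
    compound_id = names(sp),
    mean_ci = vapply(sp, mean, numeric(1)),
    sd_ci = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else 0, numeric(1)),
    n_replicates = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(df, class = c("ci_summary", "data.frame"))
}
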