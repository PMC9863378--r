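#' Construct a chromatographic trace
#'
#' A single-compound, single-condition UV trace: strictly increasing time (in
#' minutes) and a signal series of the same length, expected to contain one
#' dominant peak.
#'
#' @param time Numeric vector, strictly increasing, length >= 16.
#' @param signal Numeric vector, same length as `time`.
#' @param compound_id,column_code,solvent_code Metadata strings.
#' @return A `chrom_trace` object.
#' @export
chrom_trace <- function(time, signal, compound_id = NA_character_,
                        column_code = NA_character_, solvent_code = NA_character_) {
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal)) stop("time/signal length mismatch", call. = FALSE)
  if (length(time) < 16L) stop("trace needs at least 16 samples", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  structure(list(time = time, signal = signal,
                 compound_id = as.character(compound_id),
                 column_code = as.character(column_code),
                 solvent_code = as.character(solvent_code)),
            class = "chrom_trace")
}

#' @export
print.chrom_trace <- function(x, ...) {
  cat(sprintf("chrom_trace %s [%s/%s]: %d samples, %.3f-%.3f min\n",
              x$compound_id, x$column_code, x$solvent_code,
              length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Write a trace to CSV
#'
#' Two-column CSV (`time_min`, `signal`) preceded by a metadata comment line
#' `# compound=..., column=..., solvent=...`.
#'
#' @param x A `chrom_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# compound=%s, column=%s, solvent=%s",
                     x$compound_id, x$column_code, x$solvent_code), con)
  utils::write.csv(data.frame(time_min = x$time, signal = x$signal),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' @param path CSV path as written by [write_trace()].
#' @return A `chrom_trace`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- c(compound = NA_character_, column = NA_character_, solvent = NA_character_)
  if (startsWith(first, "#")) {
    fields <- strsplit(sub("^#\\s*", "", first), ",\\s*")[[1L]]
    for (f in fields) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1L]]
      if (length(kv) == 2L && kv[1L] %in% names(meta)) meta[kv[1L]] <- trimws(kv[2L])
    }
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  chrom_trace(df[[1L]], df[[2L]], compound_id = meta[["compound"]],
              column_code = meta[["column"]], solvent_code = meta[["solvent"]])
}

#' Read a batch manifest of trace files
#'
#' The manifest is a CSV with a column `path` (relative paths resolved
#' against the manifest's directory).
#'
#' @param path Manifest CSV path.
#' @return List of `chrom_trace` objects.
#' @export
read_trace_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"path" %in% names(man)) stop("manifest needs a 'path' column", call. = FALSE)
  base <- dirname(normalizePath(path))
  lapply(man$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    read_trace(p)
  })
}

#' Linear baseline subtraction
#'
#' Fits a straight line through the first and last `edge_frac` of samples and
#' subtracts it.  Off by default in the pipeline: traces are assumed
#' baseline-corrected upstream.
#'
#' @param trace A `chrom_trace`.
#' @param edge_frac Fraction of samples at each end used for the fit.
#' @return A baseline-subtracted `chrom_trace`.
#' @export
subtract_baseline <- function(trace, edge_frac = 0.05) {
  n <- length(trace$time)
  k <- max(2L, floor(edge_frac * n))
  idx <- c(seq_len(k), seq(n - k + 1L, n))
  fit <- stats::lm.fit(cbind(1, trace$time[idx]), trace$signal[idx])
  base <- fit$coefficients[1L] + fit$coefficients[2L] * trace$time
  trace$signal <- trace$signal - base
  trace
}
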