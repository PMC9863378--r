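#' Centre and scale a descriptor matrix
#'
#' Per-descriptor z-scores: each column is centred on its mean and divided by
#' its standard deviation (denominator n - 1).  Zero-variance columns are
#' dropped and recorded in `dropped`.
#'
#' @param x A `descriptor_matrix` (or plain numeric matrix with dimnames)
#'   without missing values.
#' @return A `scaled_matrix`: list with `values` (compounds x retained
#'   descriptors), `center`, `scale`, `dropped`.
#' @export
scale_matrix <- function(x) {
  vals <- if (inherits(x, "descriptor_matrix")) x$values else as.matrix(x)
  if (anyNA(vals)) {
    stop("descriptor matrix contains missing values; modelling operations ",
         "require a complete matrix", call. = FALSE)
  }
  if (nrow(vals) < 2L) stop("need at least 2 compounds to scale", call. = FALSE)
  ctr <- colMeans(vals)
  scl <- apply(vals, 2L, stats::sd)
  dropped <- colnames(vals)[scl == 0]
  keep <- scl > 0
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2L, ctr[keep]), 2L, scl[keep], "/")
  structure(list(values = z, center = ctr[keep], scale = scl[keep],
                 dropped = dropped), class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat("scaled_matrix:", nrow(x$values), "compounds x", ncol(x$values),
      "descriptors (mean 0, SD 1)\n")
  if (length(x$dropped)) cat("  dropped zero-variance:",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
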