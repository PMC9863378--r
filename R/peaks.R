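#' Measure peak-shape descriptors of a chromatographic trace
#'
#' Locates the apex (global maximum, refined by a 3-point parabola), then
#' finds the threshold crossings at two height fractions by linear
#' interpolation between samples.  With `a` the apex-to-left-crossing and `b`
#' the apex-to-right-crossing distance:
#' \itemize{
#'   \item asymmetry = `b/a` at 4.4\% of apex height,
#'   \item tailing factor = `(a+b)/(2a)` at 5\% of apex height,
#'   \item width = `a+b` at 5\% of apex height.
#' }
#' These are the Empower system-suitability conventions for peak asymmetry
#' (4.4\%), USP tailing factor and peak width (5\%).
#'
#' @param trace A `chrom_trace`, assumed baseline-subtracted (see
#'   [subtract_baseline()]).
#' @param asym_frac Height fraction for asymmetry (default 0.044).
#' @param tail_frac Height fraction for tailing factor and width (default 0.05).
#' @return A `peak_metrics` list: `tr` (apex time, min), `width5`, `asym44`,
#'   `tailing`, `kprime_vs_ref` (`NA` until filled by [traces_to_matrix()]),
#'   plus the fractions used.
#' @export
measure_peak <- function(trace, asym_frac = 0.044, tail_frac = 0.05) {
  t <- trace$time; s <- trace$signal
  n <- length(s)
  m <- which.max(s)
  h0 <- s[m]
  if (h0 <= 0) stop("trace has non-positive maximum", call. = FALSE)

  # multi-peak guard: disjoint regions above 50% of apex height
  above <- s >= 0.5 * h0
  runs <- rle(above)
  if (sum(runs$values) > 1L) {
    stop("multiple disjoint regions above 50% height: not a single peak",
         call. = FALSE)
  }

  # 3-point parabolic apex refinement (general, non-uniform spacing)
  tr <- t[m]; h <- h0
  if (m > 1L && m < n) {
    tt <- t[(m - 1L):(m + 1L)]; ss <- s[(m - 1L):(m + 1L)]
    co <- tryCatch(unname(solve(cbind(1, tt, tt^2), ss)), error = function(e) NULL)
    if (!is.null(co) && co[3L] < 0) {
      v <- -co[2L] / (2 * co[3L])
      if (v >= tt[1L] && v <= tt[3L]) {
        tr <- v
        h <- co[1L] + co[2L] * v + co[3L] * v^2
      }
    }
  }

  cross <- function(frac) {
    thr <- frac * h
    left <- which(s[seq_len(m)] < thr)
    if (!length(left)) {
      stop(sprintf("peak truncated: %.1f%% threshold not crossed left of apex",
                   100 * frac), call. = FALSE)
    }
    i <- max(left)
    tl <- t[i] + (thr - s[i]) * (t[i + 1L] - t[i]) / (s[i + 1L] - s[i])
    right <- which(s[m:n] < thr)
    if (!length(right)) {
      stop(sprintf("peak truncated: %.1f%% threshold not crossed right of apex",
                   100 * frac), call. = FALSE)
    }
    j <- m + min(right) - 1L   # first below-threshold sample right of apex
    tr_ <- t[j - 1L] + (thr - s[j - 1L]) * (t[j] - t[j - 1L]) / (s[j] - s[j - 1L])
    c(a = tr - tl, b = tr_ - tr)
  }

  ab_asym <- cross(asym_frac)
  ab_tail <- cross(tail_frac)
  if (any(c(ab_asym, ab_tail) <= 0)) {
    stop("degenerate peak: non-positive half-width", call. = FALSE)
  }
  structure(list(
    tr = tr,
    width5 = unname(ab_tail["a"] + ab_tail["b"]),
    asym44 = unname(ab_asym["b"] / ab_asym["a"]),
    tailing = unname((ab_tail["a"] + ab_tail["b"]) / (2 * ab_tail["a"])),
    kprime_vs_ref = NA_real_,
    asym_frac = asym_frac, tail_frac = tail_frac,
    compound_id = trace$compound_id, column_code = trace$column_code,
    solvent_code = trace$solvent_code), class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf(
    "peak_metrics %s [%s/%s]: tr=%.4f min, width5=%.4f, asym44=%.3f, tailing=%.3f\n",
    x$compound_id, x$column_code, x$solvent_code, x$tr, x$width5, x$asym44,
    x$tailing))
  invisible(x)
}

#' Relative retention versus a reference compound
#'
#' `k' vs ref = (tr - tr_ref) / tr_ref`: retention normalised to the reference
#' peak on the same chromatographic condition (zero for the reference itself,
#' negative for earlier-eluting compounds).
#'
#' @param tr_bp Compound apex time (min).
#' @param tr_ref Reference apex time (min), > 0.
#' @return Dimensionless relative retention.
#' @export
relative_retention <- function(tr_bp, tr_ref) {
  if (any(tr_ref <= 0)) stop("reference retention time must be > 0", call. = FALSE)
  (tr_bp - tr_ref) / tr_ref
}

#' Assemble peak metrics from a set of traces into a descriptor matrix
#'
#' For every (column, solvent) condition present, measures each trace and
#' fills the four descriptor slots: `2` width at 5\%, `5` relative retention
#' versus the reference compound measured on the same condition, `7`
#' asymmetry at 4.4\%, `8` tailing factor.
#'
#' @param traces List of `chrom_trace` objects.
#' @param reference_compound Compound id used as retention reference (a trace
#'   of it must exist for every condition present).
#' @param schema Optional `descriptor_schema` to align the output to; default
#'   is a schema built from the conditions actually present.
#' @param ... Passed to [measure_peak()].
#' @return A `descriptor_matrix`.
#' @export
traces_to_matrix <- function(traces, reference_compound, schema = NULL, ...) {
  stopifnot(length(traces) > 0L)
  meta <- data.frame(
    compound = vapply(traces, `[[`, "", "compound_id"),
    column = vapply(traces, `[[`, "", "column_code"),
    solvent = vapply(traces, `[[`, "", "solvent_code"),
    stringsAsFactors = FALSE)
  meta$cond <- paste0(meta$column, meta$solvent)
  key <- paste(meta$compound, meta$cond)
  if (anyDuplicated(key)) {
    stop("compound measured twice on one condition: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  conds <- unique(meta[, c("column", "solvent", "cond")])
  no_ref <- conds$cond[!conds$cond %in% meta$cond[meta$compound == reference_compound]]
  if (length(no_ref)) {
    stop("reference trace missing for condition(s): ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  }
  metrics <- lapply(traces, measure_peak, ...)
  compounds <- unique(meta$compound)
  if (is.null(schema)) {
    schema <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
      as.data.frame(build_chrom_schema(conds$column[i], conds$solvent[i]))
    }))
    schema <- new_descriptor_schema(schema)
  }
  vals <- matrix(NA_real_, length(compounds), nrow(schema),
                 dimnames = list(compounds, schema$code))
  for (ci in seq_len(nrow(conds))) {
    sel <- which(meta$cond == conds$cond[ci])
    tr_ref <- metrics[[sel[meta$compound[sel] == reference_compound]]]$tr
    for (i in sel) {
      pm <- metrics[[i]]
      row <- meta$compound[i]
      slot <- function(p) paste0(conds$cond[ci], p)
      for (p in c("2", "5", "7", "8")) {
        code <- slot(p)
        if (!code %in% colnames(vals)) next
        vals[row, code] <- switch(p,
          "2" = pm$width5,
          "5" = relative_retention(pm$tr, tr_ref),
          "7" = pm$asym44,
          "8" = pm$tailing)
      }
    }
  }
  descriptor_matrix(vals, schema = schema, compound_ids = compounds)
}
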