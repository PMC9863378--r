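#' Canonical chromatographic column abbreviations
#'
#' The thirteen reversed-phase UPLC columns used to generate chromatographic
#' descriptors, by the abbreviations that prefix descriptor codes (e.g. the
#' `T3` in `T3A2`).
#'
#' @return Character vector of 13 column codes.
#' @export
chrom_columns <- function() {
  c("RB", "RCB", "FB", "CC18", "C18", "RP", "C8", "P", "PH", "FP",
    "T3", "PFP", "CN")
}

#' Chromatographic parameter codes
#'
#' Descriptor slot digits: `2` = peak width at 5\% height, `5` = relative
#' retention (k' vs the reference compound), `7` = peak asymmetry at 4.4\%
#' height, `8` = tailing factor.
#'
#' @return Named character vector mapping digit to parameter name.
#' @export
chrom_parameters <- function() {
  c("2" = "width_5pct", "5" = "kprime_vs_ref", "7" = "asymmetry",
    "8" = "tailing_factor")
}

new_descriptor_schema <- function(df) {
  stopifnot(is.data.frame(df), all(c("code", "family") %in% names(df)))
  if (anyDuplicated(df$code)) {
    stop("schema collision: duplicated descriptor codes: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("descriptor_schema", "data.frame"))
}

#' Build a chromatographic descriptor schema
#'
#' Forms the full factorial of column, solvent and parameter codes.  A
#' descriptor code is the concatenation `column + solvent + parameter digit`
#' (`T3A2` = width at 5\% on HSS T3 with acetonitrile).
#'
#' @param columns Character vector of column codes (default: the 13 canonical
#'   columns).
#' @param solvents Character vector of organic-modifier codes; `"A"` =
#'   acetonitrile, `"M"` = methanol.
#' @param parameters Character or numeric vector of parameter digits
#'   (subset of 2, 5, 7, 8).
#' @return A `descriptor_schema` with `length(columns) * length(solvents) *
#'   length(parameters)` entries.
#' @examples
#' nrow(build_chrom_schema())            # 104
#' build_chrom_schema("PFP", "M", c(2, 7))$code
#' @export
build_chrom_schema <- function(columns = chrom_columns(),
                               solvents = c("A", "M"),
                               parameters = c("2", "5", "7", "8")) {
  parameters <- as.character(parameters)
  for (nm in c("columns", "solvents", "parameters")) {
    v <- get(nm)
    if (length(v) == 0L) stop("empty ", nm, call. = FALSE)
    if (anyDuplicated(v)) stop("duplicated ", nm, call. = FALSE)
  }
  if (!all(parameters %in% names(chrom_parameters()))) {
    stop("unknown parameter code(s): ",
         paste(setdiff(parameters, names(chrom_parameters())), collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(parameter_code = parameters, solvent_code = solvents,
                      column_code = columns, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("column_code", "solvent_code", "parameter_code")]
  grid$code <- paste0(grid$column_code, grid$solvent_code, grid$parameter_code)
  grid$family <- "chromatographic"
  new_descriptor_schema(
    grid[, c("code", "family", "column_code", "solvent_code", "parameter_code")])
}

#' Canonical chromatographic schema (104 descriptors)
#'
#' 13 columns x 2 solvents x 4 peak parameters.
#'
#' @return A `descriptor_schema` with 104 entries.
#' @export
chrom_schema <- function() build_chrom_schema()

#' Canonical molecular descriptor schema (50 descriptors)
#'
#' A 50-slot schema partitioned 16 / 14 / 20 into physicochemical (LogP-type
#' `LP`, refractivity-type `CD`, property-type `CPP`), topological/steric
#' (`MT`, Connolly `CPS`) and thermo-electronic (`DE`) families, using the
#' descriptor codes of the published models (LP2, MT5, DE1, DE2, CPS3, ...).
#' The code inventory is a reconstruction compatible with those printed codes;
#' values for these slots are always supplied by the user (or the synthetic
#' generator), never computed from structures.
#'
#' @return A `descriptor_schema` with 50 entries.
#' @export
molecular_schema <- function() {
  phys <- c(paste0("LP", 1:3), paste0("CD", 1:3), paste0("CPP", 1:10))
  topo <- c(paste0("MT", 1:12), paste0("CPS", 2:3))
  thel <- paste0("DE", 1:20)
  df <- data.frame(
    code = c(phys, topo, thel),
    family = rep(c("physicochemical", "topological", "thermo-electronic"),
                 times = c(length(phys), length(topo), length(thel))),
    column_code = NA_character_, solvent_code = NA_character_,
    parameter_code = NA_character_,
    stringsAsFactors = FALSE)
  new_descriptor_schema(df)
}

#' Combine descriptor schemas
#'
#' @param ... `descriptor_schema` objects.
#' @return A single `descriptor_schema`; an error is raised if codes collide.
#' @export
combine_schemas <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0L)
  new_descriptor_schema(do.call(rbind, lapply(parts, as.data.frame)))
}

#' @export
print.descriptor_schema <- function(x, ...) {
  fam <- table(x$family)
  cat("descriptor_schema with", nrow(x), "descriptors (",
      paste(names(fam), fam, sep = ": ", collapse = "; "), ")\n")
  invisible(x)
}
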