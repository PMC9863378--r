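#' Run the full QSAR pipeline
#'
#' Orchestrates the complete analysis: load inputs, optionally measure
#' chromatographic descriptors from traces, scale, weight descriptors with
#' the backpropagation perceptron, enumerate uncorrelated combinations, fit
#' and prune a weighted multilinear regression per combination, rank the
#' survivors by BIC, and run the leave-many-out validation battery on the
#' top-ranked model.
#'
#' @param config A named list (or path to a YAML file with the same fields):
#' \describe{
#'   \item{descriptors / clearance}{`descriptor_matrix` / `clearance_table`
#'     objects, or CSV paths.  For `mode = "both"` supply
#'     `molecular_descriptors` and `chrom_descriptors` (objects or paths).}
#'   \item{traces, reference_compound}{optional: a list of `chrom_trace`
#'     objects or a manifest CSV path; measured into the chromatographic
#'     matrix instead of reading one.}
#'   \item{mode}{`"molecular"`, `"chromatographic"` or `"both"`.}
#'   \item{ann}{list of [ann_weights()] settings (restarts, stepmax,
#'     threshold, hidden).}
#'   \item{r2_threshold}{pairwise squared-correlation threshold (default 0.5).}
#'   \item{weighting}{`"1"`, `"1/Y"`, `"1/Y^2"` or `"auto"` (smallest RMSECV
#'     of the top model across the three weightings); default `"1/Y"`.}
#'   \item{r2_min}{model-survival R-squared filter (default 0.7).}
#'   \item{split}{a `split_plan`, or a list `list(seed=, n_sets=, test_size=)`
#'     for a random plan honouring the high-leverage pinning.}
#'   \item{thresholds}{validation thresholds, see [lmo_validate()].}
#'   \item{seed}{base seed (also the ANN seed unless `ann$seed` is set).}
#'   \item{output_dir}{optional directory for JSON/CSV artifacts.}
#' }
#' @return A `pipeline_result`: `report` (the `validation_report`), `model`
#'   (the final `mlr_model`), `selection`, `combinations`, `ranked`,
#'   `leverage`, `plan`, and machine-parseable `log` lines (`key=value`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    mode = "chromatographic", ann = list(), r2_threshold = 0.5,
    weighting = "1/Y", r2_min = 0.7, alpha = 0.05,
    thresholds = list(r2 = 0.65, q2 = 0.5, qlmo2 = 0.65, ccc = 0.85),
    seed = 1, output_dir = NULL), config)
  log_lines <- character(0)
  note <- function(stage, ...) {
    kv <- c(...)
    line <- paste0("stage=", stage,
                   if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                     collapse = " ")) else "")
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(cfg$output_dir)) {
        dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(list(config = cfg, log = log_lines, error = conditionMessage(e)),
                file.path(cfg$output_dir, "partial_state.rds"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  as_dm <- function(x, schema = NULL) {
    if (inherits(x, "descriptor_matrix")) x else load_descriptor_matrix(x, schema)
  }
  dm <- stage("load", {
    if (!is.null(cfg$traces) && cfg$mode != "molecular") {
      traces <- if (is.character(cfg$traces)) read_trace_manifest(cfg$traces)
                else cfg$traces
      chrom <- traces_to_matrix(traces, cfg$reference_compound,
                                schema = chrom_schema())
    } else if (cfg$mode != "molecular") {
      chrom <- as_dm(cfg[["chrom_descriptors"]] %||% cfg[["descriptors"]],
                     chrom_schema())
    }
    switch(cfg$mode,
      chromatographic = chrom,
      molecular = as_dm(cfg[["molecular_descriptors"]] %||% cfg[["descriptors"]],
                        molecular_schema()),
      both = {
        mol <- as_dm(cfg[["molecular_descriptors"]], molecular_schema())
        stopifnot(identical(mol$compound_ids, chrom$compound_ids))
        descriptor_matrix(cbind(mol$values, chrom$values),
                          schema = combine_schemas(molecular_schema(), chrom_schema()),
                          compound_ids = mol$compound_ids)
      },
      stop("unknown mode: ", cfg$mode))
  })
  y <- stage("load", {
    if (inherits(cfg$clearance, "clearance_table")) cfg$clearance
    else read_clearance(cfg$clearance)
  })
  note("load", c(n_compounds = length(dm$compound_ids),
                 n_descriptors = ncol(dm$values), mode = cfg$mode))

  xs <- stage("scale", scale_matrix(dm))
  note("scale", c(retained = ncol(xs$values), dropped = length(xs$dropped)))

  ann_cfg <- utils::modifyList(list(restarts = 5, seed = cfg$seed,
                                    stepmax = 1e5, threshold = 0.005,
                                    hidden = 0), cfg$ann)
  sel <- stage("ann_weights", do.call(ann_weights, c(list(xs = xs, y = y), ann_cfg)))
  note("ann_weights", c(selected = length(sel$selected),
                        median_weight = signif(sel$median_weight, 4)))

  combos <- stage("enumerate_uncorrelated",
                  enumerate_uncorrelated(xs, sel$selected, cfg$r2_threshold))
  note("enumerate_uncorrelated", c(combinations = length(combos$sets)))

  weightings <- if (identical(cfg$weighting, "auto")) c("1", "1/Y", "1/Y^2")
                else normalize_weighting(cfg$weighting)
  best_by_w <- list()
  for (w in weightings) {
    pruned <- stage("mlr", {
      fit_cache <- new.env(parent = emptyenv())
      fits <- lapply(combos$sets, function(s) {
        m <- tryCatch(fit_wls(xs, y, s, w, cache = fit_cache),
                      error = function(e) NULL)
        if (is.null(m)) {
          # the set holds more descriptors than the data can support (or is
          # internally collinear): build up by stepwise-AIC from the best
          # single descriptor instead of fitting the full set
          singles <- lapply(s, function(d) {
            tryCatch(fit_wls(xs, y, d, w, cache = fit_cache),
                     error = function(e) NULL)
          })
          singles <- singles[!vapply(singles, is.null, logical(1))]
          if (!length(singles)) return(NULL)
          m <- singles[[which.min(vapply(singles, `[[`, numeric(1), "aic"))]]
          m <- step_aic(xs, y, m, s, cache = fit_cache)
        }
        tryCatch(prune_model(m, alpha = cfg$alpha, cache = fit_cache),
                 error = function(e) NULL)
      })
      fits[!vapply(fits, is.null, logical(1))]
    })
    ranked <- rank_models(pruned, r2_min = cfg$r2_min, alpha = cfg$alpha)
    # deduplicate pruned models that collapsed to the same descriptor set
    if (length(ranked)) {
      key <- vapply(ranked, function(m) paste(sort(m$descriptors), collapse = "|"), "")
      ranked <- ranked[!duplicated(key)]
    }
    note("mlr", c(weighting = w, fitted = length(pruned),
                  survivors = length(ranked)))
    if (length(ranked)) {
      cv <- cross_validate(xs, y, ranked[[1L]]$descriptors, w)
      best_by_w[[w]] <- list(ranked = ranked, rmsecv = cv$rmsecv)
    }
  }
  if (!length(best_by_w)) {
    stop("pipeline stage 'mlr' failed: no candidate model passed the R2 and ",
         "significance filters", call. = FALSE)
  }
  w_final <- names(best_by_w)[which.min(vapply(best_by_w, `[[`, numeric(1), "rmsecv"))]
  ranked <- best_by_w[[w_final]]$ranked
  final <- ranked[[1L]]
  note("final_model", c(weighting = w_final, descriptors = final$A,
                        bic = signif(final$bic, 6),
                        codes = paste(final$descriptors, collapse = ",")))

  lev <- flag_high_leverage(final)
  pinned <- lev$compound_id[lev$flagged]
  note("leverage", c(flagged = sum(lev$flagged),
                     pinned = paste(pinned, collapse = ",")))

  plan <- stage("split", {
    if (inherits(cfg$split, "split_plan")) cfg$split
    else {
      sp <- if (is.list(cfg$split)) cfg$split else list()
      make_split_plan(dm$compound_ids, pinned = pinned,
                      n_sets = sp$n_sets %||% 3, test_size = sp$test_size %||% 4,
                      seed = sp$seed %||% cfg$seed)
    }
  })
  report <- stage("lmo_validate",
                  lmo_validate(xs, y, final$descriptors, plan, w_final,
                               thresholds = cfg$thresholds))
  note("validate", c(qlmo2 = signif(report$metrics$qlmo2, 4),
                     ccc = signif(report$metrics$ccc, 4)))

  result <- structure(list(
    report = report, model = final, selection = sel, combinations = combos,
    ranked = ranked, leverage = lev, plan = plan, weighting = w_final,
    seed = cfg$seed, log = log_lines), class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_pipeline_artifacts(result, cfg$output_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- result$model
  jsonlite::write_json(list(
    weights = as.list(result$selection$weights),
    median = result$selection$median_weight,
    threshold = result$selection$threshold_weight,
    selected = result$selection$selected,
    combinations = result$combinations$sets,
    seed = result$seed),
    file.path(dir, "selection_report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    descriptors = m$descriptors, intercept = m$intercept,
    coefficients_scaled = as.list(m$coefficients),
    coefficients_raw = as.list(m$coefficients / m$scale),
    p_values = as.list(m$p), r2 = m$r2, aic = m$aic, bic = m$bic,
    weighting = m$weighting,
    leverage = as.list(m$leverage_by_compound)),
    file.path(dir, "model_report.json"), auto_unbox = TRUE, digits = NA)
  rep <- result$report
  jsonlite::write_json(list(
    metrics = rep$metrics, verdicts = rep$verdicts,
    thresholds = rep$thresholds, per_set = rep$per_set),
    file.path(dir, "validation_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(rep$pooled, file.path(dir, "lmo_curve.csv"),
                   row.names = FALSE)
  writeLines(result$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (l in x$log) cat(" ", l, "\n")
  print(x$report)
  invisible(x)
}
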