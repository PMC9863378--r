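#' Build a leave-many-out split plan
#'
#' Allocates compounds to `n_sets` disjoint test sets of `test_size`
#' compounds each; the remaining compounds of each set form its training set
#' (all replicates of a compound follow the compound).  Pinned compounds
#' (high leverage) are never placed in a test set.
#'
#' @param compounds Character vector of compound ids.
#' @param pinned Compounds excluded from every test set.
#' @param n_sets Number of train/test pairs (default 3).
#' @param test_size Compounds per test set (default 4).
#' @param seed RNG seed for the random allocation.
#' @param test_sets Optional explicit list of test sets (fixture mode); must
#'   honour the pinning and disjointness rules.
#' @return A `split_plan`: `test_sets`, `training_sets`, `pinned`, `compounds`.
#' @export
make_split_plan <- function(compounds, pinned = character(0), n_sets = 3,
                            test_size = 4, seed = NULL, test_sets = NULL) {
  compounds <- as.character(compounds)
  stopifnot(!anyDuplicated(compounds), all(pinned %in% compounds))
  if (is.null(test_sets)) {
    eligible <- setdiff(compounds, pinned)
    if (length(eligible) < n_sets * test_size) {
      stop("not enough unpinned compounds for the requested plan", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(as.integer(seed))
    drawn <- sample(eligible, n_sets * test_size)
    test_sets <- split(drawn, rep(seq_len(n_sets), each = test_size))
    test_sets <- unname(test_sets)
  } else {
    stopifnot(length(test_sets) == n_sets)
    flat <- unlist(test_sets)
    if (anyDuplicated(flat)) {
      stop("test sets must be disjoint", call. = FALSE)
    }
    if (!all(flat %in% compounds)) {
      stop("test set compound(s) not in compound list", call. = FALSE)
    }
    bad <- intersect(flat, pinned)
    if (length(bad)) {
      stop("pinned compound(s) requested in a test set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(lengths(test_sets) != test_size)) {
      stop("every test set must have ", test_size, " compounds", call. = FALSE)
    }
  }
  structure(list(
    test_sets = lapply(test_sets, as.character),
    training_sets = lapply(test_sets, function(ts) setdiff(compounds, ts)),
    pinned = as.character(pinned), compounds = compounds,
    n_sets = n_sets, test_size = test_size), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan:", x$n_sets, "data sets,", x$test_size,
      "test compounds each; pinned:",
      if (length(x$pinned)) paste(x$pinned, collapse = ", ") else "(none)", "\n")
  for (k in seq_along(x$test_sets)) {
    cat(sprintf("  set %d test: %s\n", k, paste(x$test_sets[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Grouped (leave-one-compound-out) cross-validation
#'
#' Removes all replicates of one compound at a time, refits, and predicts the
#' held-out replicates.  Replicates share identical descriptor rows, so
#' row-level leave-one-out would leak the held-out compound into the fit;
#' grouping by compound is the default granularity throughout the package.
#'
#' @param xs A `scaled_matrix`.
#' @param y A `clearance_table` (the training data).
#' @param descriptors Descriptor codes of the model under validation.
#' @param weighting Weighting mode (see [fit_wls()]).
#' @return List with `q2`, `rmsecv`, `predictions` (data frame of per-replicate
#'   observed/predicted), and `skipped` (compounds whose fold failed).
#' @export
cross_validate <- function(xs, y, descriptors, weighting = "1/Y") {
  comps <- unique(y$compound_id)
  if (length(comps) < 3L) stop("need at least 3 training compounds", call. = FALSE)
  preds <- rep(NA_real_, nrow(y))
  skipped <- character(0)
  for (cmp in comps) {
    hold <- y$compound_id == cmp
    fold_fit <- tryCatch(
      fit_wls(xs, y[!hold, , drop = FALSE], descriptors, weighting),
      error = function(e) NULL)
    if (is.null(fold_fit)) { skipped <- c(skipped, cmp); next }
    preds[hold] <- predict(fold_fit, xs)[cmp]
  }
  ok <- !is.na(preds)
  m <- compute_metrics(y$ci[ok], preds[ok], "cv", I = sum(ok),
                       training_mean = mean(y$ci[ok]))
  list(q2 = m$q2, rmsecv = m$rmsecv,
       predictions = data.frame(compound_id = y$compound_id,
                                replicate_id = y$replicate_id,
                                observed = y$ci, predicted = preds,
                                stringsAsFactors = FALSE),
       skipped = skipped)
}

# leverage of prediction points relative to a fitted model:
# h0 = x0' (X' W X)^-1 x0 with x0 = (1, z0)
prediction_leverage <- function(model, z0) {
  Xd <- cbind(1, model$xs$values[model$y$compound_id, model$descriptors, drop = FALSE])
  w <- weight_vector(model$y$ci, model$weighting)
  XtWX <- crossprod(Xd * sqrt(w))
  inv <- solve(XtWX)
  x0 <- cbind(1, z0[, model$descriptors, drop = FALSE])
  rowSums((x0 %*% inv) * x0)
}

#' Leave-many-out validation
#'
#' For each data set of the plan: fit on the training compounds, cross-validate
#' within the training set, and predict the test compounds.  Per-set
#' calibration (R2, RMSEC), cross-validation (Q2, RMSECV) and prediction
#' (QLMO2, RMSEP) metrics are averaged over the sets; concordance (CCC) and
#' the squared Pearson/Spearman correlations are computed on predictions
#' pooled across all test sets against the per-compound mean observed CI.
#' Test compounds whose prediction leverage exceeds the high-leverage cutoff
#' in their training fit are kept but flagged unreliable.
#'
#' @param xs A `scaled_matrix`.
#' @param y A `clearance_table` covering all compounds of the plan.
#' @param descriptors Descriptor codes of the (final) model.
#' @param plan A `split_plan`.
#' @param weighting Weighting mode.
#' @param thresholds Named list of acceptance thresholds (defaults: R2 > 0.65,
#'   Q2 > 0.5, QLMO2 > 0.65, CCC > 0.85).
#' @return A `validation_report`: `per_set` data frame, aggregated `metrics`,
#'   `verdicts`, `pooled` observed/predicted pairs, `unreliable` flags.
#' @export
lmo_validate <- function(xs, y, descriptors, plan, weighting = "1/Y",
                         thresholds = list(r2 = 0.65, q2 = 0.5,
                                           qlmo2 = 0.65, ccc = 0.85)) {
  stopifnot(inherits(plan, "split_plan"))
  per_set <- vector("list", plan$n_sets)
  pooled <- vector("list", plan$n_sets)
  unreliable <- list()
  for (k in seq_len(plan$n_sets)) {
    tr <- plan$training_sets[[k]]; te <- plan$test_sets[[k]]
    y_tr <- y[y$compound_id %in% tr, , drop = FALSE]
    y_te <- y[y$compound_id %in% te, , drop = FALSE]
    fit <- fit_wls(xs, y_tr, descriptors, weighting)
    cal <- compute_metrics(y_tr$ci, fit$fitted, "calibration",
                           I = fit$I, A = fit$A)
    cv <- cross_validate(xs, y_tr, descriptors, weighting)
    pred_te <- predict(fit, xs)[y_te$compound_id]
    ss_tr <- sum((y_tr$ci - mean(y_tr$ci))^2)
    lmo <- compute_metrics(y_te$ci, pred_te, "lmo",
                           n_ext = nrow(y_te), n_tr = nrow(y_tr),
                           ss_training = ss_tr)
    h0 <- prediction_leverage(fit, xs$values[te, , drop = FALSE])
    cutoff <- 3 * (fit$A + 1) / fit$I
    if (any(h0 > cutoff)) {
      unreliable[[length(unreliable) + 1L]] <-
        data.frame(set = k, compound_id = te[h0 > cutoff],
                   leverage = h0[h0 > cutoff], stringsAsFactors = FALSE)
    }
    per_set[[k]] <- data.frame(
      set = k, r2 = cal$r2, rmsec = cal$rmsec, q2 = cv$q2,
      rmsecv = cv$rmsecv, qlmo2 = lmo$qlmo2, rmsep = lmo$rmsep,
      bic = fit$bic)
    mo <- tapply(y_te$ci, y_te$compound_id, mean)
    pooled[[k]] <- data.frame(compound_id = names(mo),
                              mean_observed = as.numeric(mo),
                              predicted = as.numeric(pred_te[match(names(mo), y_te$compound_id)]),
                              set = k, stringsAsFactors = FALSE)
  }
  per_set <- do.call(rbind, per_set)
  pooled <- do.call(rbind, pooled)
  pm <- compute_metrics(pooled$mean_observed, pooled$predicted, "lmo",
                        n_ext = nrow(pooled), n_tr = 1, ss_training = 1)
  metrics <- list(
    r2 = mean(per_set$r2), rmsec = mean(per_set$rmsec),
    q2 = mean(per_set$q2), rmsecv = mean(per_set$rmsecv),
    qlmo2 = mean(per_set$qlmo2), rmsep = mean(per_set$rmsep),
    ccc = pm$ccc, pearson2 = pm$pearson2, spearman2 = pm$spearman2,
    bic = mean(per_set$bic))
  verdicts <- list(
    r2 = !is.na(metrics$r2) && metrics$r2 > thresholds$r2,
    q2 = !is.na(metrics$q2) && metrics$q2 > thresholds$q2,
    qlmo2 = !is.na(metrics$qlmo2) && metrics$qlmo2 > thresholds$qlmo2,
    ccc = !is.na(metrics$ccc) && metrics$ccc > thresholds$ccc)
  structure(list(per_set = per_set, metrics = metrics, verdicts = verdicts,
                 thresholds = thresholds, pooled = pooled,
                 unreliable = if (length(unreliable)) do.call(rbind, unreliable)
                              else NULL,
                 descriptors = descriptors, weighting = weighting),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  m <- x$metrics; v <- x$verdicts; th <- x$thresholds
  mark <- function(nm) if (isTRUE(v[[nm]])) "pass" else "FAIL"
  cat("validation_report (", length(x$descriptors), " descriptors, weighting ",
      x$weighting, ")\n", sep = "")
  cat(sprintf("  calibration : R2 = %.3f (> %.2f: %s), RMSEC = %.3f\n",
              m$r2, th$r2, mark("r2"), m$rmsec))
  cat(sprintf("  cross-valid.: Q2 = %.3f (> %.2f: %s), RMSECV = %.3f\n",
              m$q2, th$q2, mark("q2"), m$rmsecv))
  cat(sprintf("  leave-many-out: QLMO2 = %.3f (> %.2f: %s), RMSEP = %.3f\n",
              m$qlmo2, th$qlmo2, mark("qlmo2"), m$rmsep))
  cat(sprintf("  concordance : CCC = %.3f (> %.2f: %s), Pearson2 = %.3f, Spearman2 = %.3f\n",
              m$ccc, th$ccc, mark("ccc"), m$pearson2, m$spearman2))
  cat(sprintf("  mean BIC = %.1f\n", m$bic))
  if (!is.null(x$unreliable)) {
    cat("  unreliable predictions (high leverage):",
        paste(unique(x$unreliable$compound_id), collapse = ", "), "\n")
  }
  invisible(x)
}
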