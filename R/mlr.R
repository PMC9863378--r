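normalize_weighting <- function(weighting) {
  w <- tolower(gsub("\\s", "", as.character(weighting)))
  switch(w,
    "1" = "1",
    "1/y" = "1/Y",
    "1/y^2" = , "1/y2" = "1/Y^2",
    stop("unknown weighting '", weighting, "' (use 1, 1/Y or 1/Y^2)",
         call. = FALSE))
}

weight_vector <- function(ci, weighting) {
  switch(weighting, "1" = rep(1, length(ci)), "1/Y" = 1 / ci, "1/Y^2" = 1 / ci^2)
}

#' Fit a weighted multilinear regression of CI on scaled descriptors
#'
#' Ordinary/weighted least squares of the replicate clearance indices on the
#' scaled descriptor values (each replicate contributes one row; descriptor
#' rows are repeated per replicate).  Observation weights are 1, 1/Y or
#' 1/Y^2 with Y the observed CI.  The reported `r2` uses unweighted
#' residuals (the weighted coefficient of determination is kept in `r2_weighted`);
#' AIC/BIC come from the Gaussian weighted log-likelihood; leverages are the
#' diagonal of the weighted hat matrix.
#'
#' @param xs A `scaled_matrix` (one row per compound).
#' @param y A `clearance_table` (strictly positive CI, required whenever the
#'   weighting is not 1).
#' @param descriptors Character vector of descriptor codes (may be empty for
#'   an intercept-only model).
#' @param weighting `"1"`, `"1/Y"` or `"1/Y^2"`.
#' @param cache Optional environment used to memoise fits by descriptor set
#'   and weighting (shared across the many overlapping fits of combination
#'   pruning; purely an optimisation).
#' @return An `mlr_model`: coefficients in scaled-descriptor space with
#'   standard errors, t- and p-values, `r2`, `aic`, `bic`, per-observation
#'   `leverage`, training bookkeeping (`I` observations, `A` descriptors) and
#'   the centring/scaling needed to predict from raw descriptors.
#' @export
fit_wls <- function(xs, y, descriptors, weighting = "1/Y", cache = NULL) {
  stopifnot(inherits(xs, "scaled_matrix"), inherits(y, "clearance_table"))
  weighting <- normalize_weighting(weighting)
  descriptors <- unique(as.character(descriptors))
  key <- NULL
  if (is.environment(cache)) {
    key <- paste(weighting, paste(sort(descriptors), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) {
      if (inherits(hit, "condition")) stop(hit) else return(hit)
    }
  }
  unknown <- setdiff(descriptors, colnames(xs$values))
  if (length(unknown)) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(y$compound_id %in% rownames(xs$values))) {
    stop("clearance table contains compounds absent from the matrix", call. = FALSE)
  }
  I <- nrow(y); A <- length(descriptors)
  fail <- function(msg) {
    cnd <- simpleError(msg)
    if (!is.null(key)) cache[[key]] <- cnd
    stop(cnd)
  }
  if (I <= A + 1L) {
    fail(sprintf("insufficient data: %d observations for %d descriptors", I, A))
  }
  X <- xs$values[y$compound_id, descriptors, drop = FALSE]
  w <- weight_vector(y$ci, weighting)
  sw <- sqrt(w)
  Xd <- cbind("(Intercept)" = 1, X)
  Xw <- Xd * sw
  qrx <- qr(Xw)
  if (qrx$rank < A + 1L) {
    aliased <- colnames(Xd)[qrx$pivot[(qrx$rank + 1L):(A + 1L)]]
    fail(paste0("collinear design; dependent column(s): ",
                paste(aliased, collapse = ", ")))
  }
  coefs <- stats::setNames(qr.coef(qrx, y$ci * sw), colnames(Xd))
  yhat <- drop(Xd %*% coefs)
  rss_w <- sum(w * (y$ci - yhat)^2)
  df <- I - A - 1L
  sigma2 <- rss_w / df
  V <- chol2inv(chol(crossprod(Xw)))
  se <- stats::setNames(sqrt(diag(V) * sigma2), colnames(Xd))
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)
  ybar <- mean(y$ci)
  r2 <- 1 - sum((y$ci - yhat)^2) / sum((y$ci - ybar)^2)
  ybar_w <- sum(w * y$ci) / sum(w)
  r2_weighted <- 1 - rss_w / sum(w * (y$ci - ybar_w)^2)
  # Gaussian weighted log-likelihood, as logLik.lm computes it
  ll <- 0.5 * (sum(log(w)) - I * (log(2 * pi) + 1 + log(rss_w / I)))
  npar <- A + 2L  # coefficients + intercept + error variance
  lev <- rowSums((Xw %*% V) * Xw)
  names(lev) <- paste(y$compound_id, y$replicate_id, sep = ":")
  out <- structure(list(
    descriptors = descriptors,
    intercept = unname(coefs["(Intercept)"]),
    coefficients = coefs[descriptors],
    weighting = weighting,
    se = se, t = tval,
    p = pval[descriptors],
    r2 = r2, r2_weighted = r2_weighted,
    aic = -2 * ll + 2 * npar, bic = -2 * ll + log(I) * npar,
    leverage = lev,
    leverage_by_compound = tapply(lev, y$compound_id, mean),
    fitted = stats::setNames(yhat, names(lev)),
    I = I, A = A, df_residual = df,
    training_compounds = unique(y$compound_id),
    center = xs$center[descriptors], scale = xs$scale[descriptors],
    xs = xs, y = y,
    degenerate = A == 0L, pruned = FALSE),
    class = "mlr_model")
  if (!is.null(key)) cache[[key]] <- out
  out
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("mlr_model (%d obs, %d descriptors, weighting %s): R2=%.3f, BIC=%.1f\n",
              x$I, x$A, x$weighting, x$r2, x$bic))
  if (x$A > 0) {
    terms <- sprintf("%+.3f x %s", x$coefficients, names(x$coefficients))
    cat(sprintf("  CI = %.3f %s\n", x$intercept, paste(terms, collapse = " ")))
  } else cat(sprintf("  CI = %.3f (intercept only%s)\n", x$intercept,
                     if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Predict clearance indices from a fitted model
#'
#' @param object An `mlr_model`.
#' @param newdata A `descriptor_matrix`, a raw-space numeric matrix with
#'   descriptor column names, or a `scaled_matrix` (used as is).
#' @param ... Ignored.
#' @return Named numeric vector of predicted CI.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  if (object$A == 0L) {
    n <- if (inherits(newdata, c("descriptor_matrix", "scaled_matrix"))) {
      nrow(newdata$values)
    } else nrow(as.matrix(newdata))
    return(rep(object$intercept, n))
  }
  codes <- object$descriptors
  if (inherits(newdata, "scaled_matrix")) {
    Z <- newdata$values[, codes, drop = FALSE]
  } else {
    vals <- if (inherits(newdata, "descriptor_matrix")) newdata$values else as.matrix(newdata)
    miss <- setdiff(codes, colnames(vals))
    if (length(miss)) stop("newdata lacks descriptor(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    Z <- sweep(sweep(vals[, codes, drop = FALSE], 2L, object$center),
               2L, object$scale, "/")
  }
  stats::setNames(drop(object$intercept + Z %*% object$coefficients),
                  rownames(Z))
}

# Bidirectional stepwise search minimising AIC: from the current model,
# consider dropping any present descriptor or re-adding any descriptor of
# the unpruned model; take the best strictly-improving move until none.
step_aic <- function(xs, y, current, full_set, cache = NULL) {
  repeat {
    moves <- c(lapply(current$descriptors,
                      function(d) setdiff(current$descriptors, d)),
               lapply(setdiff(full_set, current$descriptors),
                      function(d) c(current$descriptors, d)))
    fits <- lapply(moves, function(dd) {
      tryCatch(fit_wls(xs, y, dd, current$weighting, cache = cache),
               error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (!length(fits)) break
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    if (min(aics) >= current$aic) break
    current <- fits[[which.min(aics)]]
  }
  current
}

#' Prune a model to significant descriptors
#'
#' Repeatedly removes the least-significant descriptor (largest p-value at or
#' above `alpha`) and refits, until every coefficient has p < `alpha`.  When
#' more than `stepwise_trigger` descriptors are non-significant at once, a
#' bidirectional stepwise search minimising AIC is used for the bulk
#' simplification before p-value pruning resumes.  If pruning empties the
#' model, an intercept-only model flagged `degenerate` is returned (not an
#' error).
#'
#' @param model An `mlr_model`.
#' @param alpha Significance level (default 0.05).
#' @param stepwise_trigger Number of simultaneous non-significant descriptors
#'   that triggers stepwise-AIC (default 3).
#' @return A pruned `mlr_model` (`pruned = TRUE`).
#' @export
prune_model <- function(model, alpha = 0.05, stepwise_trigger = 3, cache = NULL) {
  stopifnot(inherits(model, "mlr_model"))
  xs <- model$xs; y <- model$y
  current <- model
  repeat {
    if (current$A == 0L) { current$degenerate <- TRUE; break }
    nonsig <- names(current$p)[current$p >= alpha]
    if (!length(nonsig)) break
    if (length(nonsig) > stepwise_trigger) {
      stepped <- step_aic(xs, y, current, model$descriptors, cache = cache)
      if (stepped$A < current$A) { current <- stepped; next }
      # stepwise removed nothing: fall through to single-descriptor removal
    }
    worst <- names(current$p)[which.max(current$p)]
    current <- fit_wls(xs, y, setdiff(current$descriptors, worst),
                       current$weighting, cache = cache)
  }
  current$pruned <- TRUE
  current
}

#' Filter and rank candidate models
#'
#' Keeps models with `r2 > r2_min`, all descriptors significant at `alpha`
#' and not degenerate; sorts ascending by BIC, breaking ties by fewer
#' descriptors, then by lexicographic descriptor codes.
#'
#' @param models List of `mlr_model` objects fitted on the same observations.
#' @param r2_min Minimum (unweighted) R-squared (default 0.7).
#' @param alpha Significance level for the all-significant filter.
#' @return The surviving models in rank order; if none survive, an empty list
#'   with a `diagnostic` attribute.
#' @export
rank_models <- function(models, r2_min = 0.7, alpha = 0.05) {
  ok <- vapply(models, function(m) {
    !m$degenerate && m$r2 > r2_min && (m$A == 0L || all(m$p < alpha))
  }, logical(1))
  surv <- models[ok]
  if (!length(surv)) {
    return(structure(list(), diagnostic = sprintf(
      "no model passed R2 > %g with all descriptors significant (n = %d candidates)",
      r2_min, length(models))))
  }
  key_codes <- vapply(surv, function(m) paste(sort(m$descriptors), collapse = "|"), "")
  ord <- order(vapply(surv, `[[`, numeric(1), "bic"),
               vapply(surv, `[[`, numeric(1), "A"), key_codes)
  surv[ord]
}

#' Flag high-leverage compounds
#'
#' A compound is flagged when its mean leverage over replicates exceeds the
#' cutoff rule, by default `3 (A + 1) / I` (three times the average hat
#' value).  Flagged compounds are pinned to training sets downstream and
#' their predictions treated as unreliable.
#'
#' @param model An `mlr_model`.
#' @param rule Function of `(A, I)` returning the cutoff.
#' @return Data frame with `compound_id`, `mean_leverage`, `cutoff`, `flagged`.
#' @export
flag_high_leverage <- function(model, rule = function(A, I) 3 * (A + 1) / I) {
  lev <- model$leverage_by_compound
  cutoff <- rule(model$A, model$I)
  data.frame(compound_id = names(lev), mean_leverage = as.numeric(lev),
             cutoff = cutoff, flagged = as.numeric(lev) > cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}
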