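#' Lin's concordance correlation coefficient
#'
#' Agreement of predictions with observations around the identity line:
#' `2 * sum((y - ybar) (yhat - yhatbar)) /
#'  (sum((y - ybar)^2) + sum((yhat - yhatbar)^2) + n (ybar - yhatbar)^2)`.
#'
#' @param y_obs,y_pred Equal-length numeric vectors.
#' @return CCC in `[-1, 1]`.
#' @export
lin_ccc <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  n <- length(y_obs)
  mo <- mean(y_obs); mp <- mean(y_pred)
  num <- 2 * sum((y_obs - mo) * (y_pred - mp))
  den <- sum((y_obs - mo)^2) + sum((y_pred - mp)^2) + n * (mo - mp)^2
  num / den
}

#' Regression, cross-validation and leave-many-out metrics
#'
#' Implements the validation metric battery in its three contexts:
#' \describe{
#'   \item{calibration}{`r2 = 1 - RSS / SS_tot` and
#'     `rmsec = sqrt(RSS / (I - A - 1))`.}
#'   \item{cv}{`q2` of the same 1 - RSS/SS form with cross-validation
#'     predictions, and `rmsecv = sqrt(RSS / I)`.}
#'   \item{lmo}{`qlmo2 = 1 - (PRESS / n_ext) / (ss_training / n_tr)`,
#'     `rmsep = sqrt(PRESS / n_ext)`, Lin's `ccc`, and squared Pearson and
#'     Spearman correlations between observed and predicted.}
#' }
#' `n_ext` and `n_tr` are numbers of observations in the test and training
#' sets (the standard external-Q2 form).
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values (same length).
#' @param context `"calibration"`, `"cv"` or `"lmo"`.
#' @param I Number of training observations (default `length(y_obs)`).
#' @param A Number of descriptors (required for `rmsec`).
#' @param n_ext,n_tr Test/training observation counts (lmo context).
#' @param training_mean Mean of the training observations; defaults to
#'   `mean(y_obs)`.
#' @param ss_training Total sum of squares of the training observations about
#'   `training_mean` (lmo context; required).
#' @return Named list of the context's metrics.  With zero variance in
#'   `y_obs`, R2-type metrics are returned as `NA` (flagged undefined).
#' @export
compute_metrics <- function(y_obs, y_pred,
                            context = c("calibration", "cv", "lmo"),
                            I = length(y_obs), A = NULL,
                            n_ext = length(y_obs), n_tr = NULL,
                            training_mean = mean(y_obs), ss_training = NULL) {
  context <- match.arg(context)
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  rss <- sum((y_obs - y_pred)^2)
  if (context == "calibration") {
    if (is.null(A)) stop("A (number of descriptors) required", call. = FALSE)
    ss <- sum((y_obs - training_mean)^2)
    list(r2 = if (ss > 0) 1 - rss / ss else NA_real_,
         rmsec = sqrt(rss / (I - A - 1)))
  } else if (context == "cv") {
    ss <- sum((y_obs - training_mean)^2)
    list(q2 = if (ss > 0) 1 - rss / ss else NA_real_,
         rmsecv = sqrt(rss / I))
  } else {
    if (is.null(ss_training) || is.null(n_tr)) {
      stop("ss_training and n_tr required in lmo context", call. = FALSE)
    }
    press <- rss
    denom <- ss_training / n_tr
    list(qlmo2 = if (denom > 0) 1 - (press / n_ext) / denom else NA_real_,
         rmsep = sqrt(press / n_ext),
         ccc = lin_ccc(y_obs, y_pred),
         pearson2 = if (stats::sd(y_obs) > 0 && stats::sd(y_pred) > 0)
           stats::cor(y_obs, y_pred)^2 else NA_real_,
         spearman2 = if (stats::sd(y_obs) > 0 && stats::sd(y_pred) > 0)
           stats::cor(y_obs, y_pred, method = "spearman")^2 else NA_real_)
  }
}
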