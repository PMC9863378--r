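sigmoid <- function(z) 1 / (1 + exp(-z))

# Full-batch gradient-descent backpropagation.
# Stops when the maximum absolute partial derivative of the mean squared
# error falls below `threshold`, or after `stepmax` updates.
backprop_gd <- function(par, grad_fn, stepmax, threshold, learning_rate) {
  gr <- grad_fn(par)
  steps <- 0L
  while (max(abs(gr)) >= threshold && steps < stepmax) {
    par <- par - learning_rate * gr
    gr <- grad_fn(par)
    steps <- steps + 1L
  }
  list(par = par, grad = gr, steps = steps,
       converged = max(abs(gr)) < threshold)
}

#' ANN-based descriptor importance weighting and selection
#'
#' Trains a perceptron (inputs directly connected to a single sigmoid output;
#' no hidden layer by default, so "the weight of each descriptor" is the
#' input weight itself) by full-batch gradient-descent backpropagation to
#' minimise squared error between the sigmoid output and the
#' min-max-rescaled clearance index.  Each replicate contributes one training
#' row (descriptor rows repeated per replicate).  The importance of a
#' descriptor is the mean over restarts of the absolute input weight;
#' descriptors with importance strictly greater than twice the median of all
#' importances are selected.
#'
#' Weights start near zero (SD `init_sd`), so importance reflects
#' training-driven growth: gradient descent grows the weights of descriptors
#' whose association with the outcome is consistent across compounds, while
#' weights of uninformative descriptors stay near the origin.  The error
#' function is the mean squared output error and training stops once its
#' largest absolute partial derivative drops below `threshold`; with many
#' more descriptors than compounds this gradient-magnitude stop acts as
#' implicit regularisation — training halts while the weight profile still
#' tracks outcome association, before the network starts interpolating
#' replicate noise (which would spread weight arbitrarily across collinear
#' descriptor groups).
#'
#' @param xs A `scaled_matrix` (one row per compound).
#' @param y A `clearance_table`.
#' @param restarts Number of random initialisations averaged (default 5).
#' @param seed Base RNG seed; restart r uses `seed + r`.
#' @param stepmax Maximum weight updates per restart (default 1e5).
#' @param threshold Convergence threshold on the maximum absolute partial
#'   derivative of the mean squared error (default 0.005).
#' @param learning_rate Gradient-descent step size (default 0.2).
#' @param init_sd SD of the random initial weights (default 0.01).
#' @param hidden Number of hidden sigmoid units (default 0; a small hidden
#'   layer is available for sensitivity analysis, with importances computed
#'   as connection-weight products summed over hidden units).
#' @return An `ann_selection`: `weights` (named importances), `median_weight`,
#'   `threshold_weight` (= 2 x median), `selected`, `converged` per restart,
#'   and the configuration echo.
#' @export
ann_weights <- function(xs, y, restarts = 5, seed = 1, stepmax = 1e5,
                        threshold = 0.005, learning_rate = 0.2,
                        init_sd = 0.01, hidden = 0) {
  stopifnot(inherits(xs, "scaled_matrix"), inherits(y, "clearance_table"))
  codes <- colnames(xs$values)
  p <- length(codes)
  if (p < 3L) stop("fewer than 3 descriptors: selection not meaningful", call. = FALSE)
  if (!all(y$compound_id %in% rownames(xs$values))) {
    stop("clearance table contains compounds absent from the matrix", call. = FALSE)
  }
  X <- xs$values[y$compound_id, , drop = FALSE]  # replicate-expanded rows
  ci <- y$ci
  if (length(unique(ci)) < 2L) stop("need >= 2 distinct outcome values", call. = FALSE)
  # min-max rescale into [0.1, 0.9] so sigmoid targets are attainable
  tgt <- 0.1 + 0.8 * (ci - min(ci)) / (max(ci) - min(ci))

  ord <- order(codes)  # init assigned by descriptor identity (sorted codes)
  run_restart <- function(r) {
    set.seed(as.integer(seed) + r)
    if (hidden == 0) {
      init_w <- numeric(p)
      init_w[ord] <- stats::rnorm(p, 0, init_sd)
      par0 <- c(init_w, 0)
      grad_fn <- function(par) {
        z <- drop(X %*% par[1:p]) + par[p + 1L]
        yhat <- sigmoid(z)
        d <- (yhat - tgt) * yhat * (1 - yhat) * (2 / length(tgt))
        c(drop(crossprod(X, d)), sum(d))
      }
      res <- backprop_gd(par0, grad_fn, stepmax, threshold, learning_rate)
      list(imp = abs(res$par[1:p]), converged = res$converged)
    } else {
      h <- hidden
      nW1 <- p * h
      par0 <- stats::rnorm(nW1 + h + h + 1, 0, max(init_sd, 1 / sqrt(p)))
      grad_fn <- function(par) {
        W1 <- matrix(par[1:nW1], p, h)
        b1 <- par[nW1 + 1:h]
        w2 <- par[nW1 + h + 1:h]
        b2 <- par[nW1 + 2 * h + 1]
        A <- sigmoid(sweep(X %*% W1, 2L, b1, "+"))
        yhat <- sigmoid(drop(A %*% w2) + b2)
        d2 <- (yhat - tgt) * yhat * (1 - yhat) * (2 / length(tgt))
        dA <- outer(d2, w2) * A * (1 - A)
        c(as.vector(crossprod(X, dA)), colSums(dA), drop(crossprod(A, d2)), sum(d2))
      }
      res <- backprop_gd(par0, grad_fn, stepmax, threshold, learning_rate)
      W1 <- matrix(res$par[1:nW1], p, h)
      w2 <- res$par[nW1 + h + 1:h]
      list(imp = drop(abs(W1) %*% abs(w2)), converged = res$converged)
    }
  }
  runs <- lapply(seq_len(restarts), run_restart)
  conv <- vapply(runs, `[[`, logical(1), "converged")
  imp <- rowMeans(vapply(runs, `[[`, numeric(p), "imp"))
  names(imp) <- codes
  med <- stats::median(imp)
  thr <- 2 * med
  result <- structure(list(
    weights = imp, median_weight = med, threshold_weight = thr,
    selected = codes[imp > thr], converged = conv,
    config = list(restarts = restarts, seed = seed, stepmax = stepmax,
                  threshold = threshold, learning_rate = learning_rate,
                  init_sd = init_sd, hidden = hidden)),
    class = "ann_selection")
  if (!any(conv)) {
    stop(errorCondition(
      "backpropagation failed to converge in every restart",
      class = c("qsarpt_convergence_error", "error"), partial = result))
  }
  result
}

#' @export
print.ann_selection <- function(x, ...) {
  cat(sprintf(
    "ann_selection: %d/%d descriptors above 2 x median weight (%.4g); %d/%d restarts converged\n",
    length(x$selected), length(x$weights), x$threshold_weight,
    sum(x$converged), length(x$converged)))
  if (length(x$selected)) cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
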