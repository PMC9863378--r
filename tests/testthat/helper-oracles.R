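# Independent reference implementations ("oracles") used to pin the package's
# numerics, plus small constructors for test data.

# --- constructors ------------------------------------------------------------

# scaled matrix straight from a plain numeric matrix with dimnames
mk_xs <- function(vals) {
  scale_matrix(descriptor_matrix(vals, compound_ids = rownames(vals)))
}

# replicate-expanded clearance table: one block of `reps` rows per compound
mk_y <- function(compound_ids, ci_per_compound, reps = 1L, noise_sd = 0,
                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ci <- rep(ci_per_compound, each = reps)
  if (noise_sd > 0) ci <- ci + stats::rnorm(length(ci), 0, noise_sd)
  ci <- pmax(ci, 1e-3)
  clearance_table(rep(compound_ids, each = reps),
                  rep(seq_len(reps), times = length(compound_ids)), ci)
}

# random compounds x descriptors matrix with standard names
mk_mat <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p,
         dimnames = list(sprintf("X%02d", seq_len(n)),
                         sprintf("d%02d", seq_len(p))))
}

# 15-compound study with a planted linear outcome on the named descriptors.
# Defaults keep the linear predictor comfortably positive so the CI floor in
# mk_y never engages and the outcome stays exactly linear in the descriptors.
planted_linear_data <- function(seed = 21, noise_sd = 0.08, p = 3,
                                beta = c(d01 = 0.12, d02 = 0.1), reps = 5L,
                                intercept = 0.55) {
  xs <- mk_xs(mk_mat(15, p, seed = seed))
  lp <- intercept + drop(xs$values[, names(beta), drop = FALSE] %*% beta)
  y <- mk_y(rownames(xs$values), lp, reps = reps, noise_sd = noise_sd,
            seed = seed + 500)
  list(xs = xs, y = y, beta = beta, intercept = intercept)
}

# --- brute-force maximal independent sets ------------------------------------

# All maximal independent sets of a logical adjacency matrix, by exhaustive
# subset enumeration (n <= ~14).  Returns a canonically sorted list of sorted
# integer vectors.
brute_mis <- function(adj) {
  n <- nrow(adj)
  indep <- list()
  for (m in 0:(2^n - 1)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) >= 2L && any(adj[idx, idx])) next
    indep[[length(indep) + 1L]] <- idx
  }
  keep <- vapply(seq_along(indep), function(i) {
    !any(vapply(seq_along(indep), function(j) {
      i != j && length(indep[[i]]) < length(indep[[j]]) &&
        all(indep[[i]] %in% indep[[j]])
    }, logical(1)))
  }, logical(1))
  canon_sets(indep[keep])
}

canon_sets <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, "", collapse = ","))]
}

# --- analytic EMG oracle -----------------------------------------------------

# Textbook exponentially modified Gaussian via the direct erfc product (an
# implementation independent of the package's log-space form).
emg_oracle_fun <- function(tr0, sigma, tau, amplitude = 1) {
  if (tau == 0) {
    function(t) amplitude * exp(-(t - tr0)^2 / (2 * sigma^2))
  } else {
    function(t) {
      u <- sigma / tau - (t - tr0) / sigma
      # erfc(u / sqrt(2)) = 2 * pnorm(-u)
      amplitude * (sigma / tau) * sqrt(pi / 2) *
        exp((sigma / tau)^2 / 2 - (t - tr0) / tau) * (2 * stats::pnorm(-u))
    }
  }
}

# Peak metrics straight from the analytic curve: apex by continuous
# optimisation, height-fraction crossings by root finding.
emg_metrics_oracle <- function(tr0, sigma, tau, lo, hi,
                               asym_frac = 0.044, tail_frac = 0.05) {
  f <- emg_oracle_fun(tr0, sigma, tau)
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
  tr <- opt$maximum
  h <- opt$objective
  half <- function(frac) {
    thr <- frac * h
    tl <- stats::uniroot(function(t) f(t) - thr, c(lo, tr), tol = 1e-12)$root
    tu <- stats::uniroot(function(t) f(t) - thr, c(tr, hi), tol = 1e-12)$root
    c(a = tr - tl, b = tu - tr)
  }
  ab_a <- half(asym_frac)
  ab_t <- half(tail_frac)
  list(tr = tr,
       width5 = unname(ab_t["a"] + ab_t["b"]),
       asym44 = unname(ab_a["b"] / ab_a["a"]),
       tailing = unname((ab_t["a"] + ab_t["b"]) / (2 * ab_t["a"])))
}

# --- weighted least squares oracle -------------------------------------------

# Reference WLS via stats::lm(weights =); returns coefficients with the
# intercept first, matching fit_wls ordering.
wls_oracle <- function(X, y, w) {
  fit <- stats::lm(y ~ X, weights = w)
  unname(stats::coef(fit))
}
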