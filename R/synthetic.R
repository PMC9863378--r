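#' Exponentially modified Gaussian peak profile
#'
#' The EMG — a Gaussian of location `tr0` and width `sigma` convolved with an
#' exponential decay of time constant `tau` — is the standard model for
#' tailed chromatographic peaks: `tau = 0` gives a symmetric Gaussian, and
#' increasing `tau/sigma` increases asymmetry and tailing.  Computed in
#' log-space (via `pnorm(log.p = TRUE)`) so small `tau/sigma` does not
#' overflow.
#'
#' @param t Time vector (min).
#' @param tr0 Gaussian centre (min).
#' @param sigma Gaussian SD (min), > 0.
#' @param tau Exponential time constant (min), >= 0.
#' @param amplitude Gaussian amplitude scale (default 1).
#' @return Signal values at `t`.
#' @export
emg_signal <- function(t, tr0, sigma, tau, amplitude = 1) {
  stopifnot(sigma > 0, tau >= 0)
  if (tau < 1e-9) {
    return(amplitude * exp(-(t - tr0)^2 / (2 * sigma^2)))
  }
  z <- sigma / tau
  u <- z - (t - tr0) / sigma
  # A * z * sqrt(pi/2) * exp(z^2/2 - (t - tr0)/tau) * erfc(u / sqrt(2))
  log_erfc <- log(2) + stats::pnorm(-u, log.p = TRUE)
  amplitude * z * sqrt(pi / 2) * exp(z^2 / 2 - (t - tr0) / tau + log_erfc)
}

#' Configure a synthetic chromatographic study
#'
#' Bundles everything [generate_traces()] needs: the condition grid, the
#' per-compound-per-condition EMG parameters, the sampling window and rate,
#' and the detector noise level.
#'
#' @param seed RNG seed (full determinism: identical configs give identical
#'   studies).
#' @param compound_ids Character vector of compound ids.
#' @param conditions Data frame with columns `column_code`, `solvent_code`.
#' @param peak_params Data frame with columns `compound_id`, `column_code`,
#'   `solvent_code`, `tr0`, `sigma`, `tau`, `amplitude` — one row per
#'   compound x condition.
#' @param window Sampling window in minutes, `c(from, to)`; must cover every
#'   peak.
#' @param sampling_rate Samples per minute (default 200).
#' @param detector_noise_sd Additive Gaussian noise SD on the signal
#'   (default 0).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed, compound_ids, conditions, peak_params,
                             window = c(0.5, 12), sampling_rate = 200,
                             detector_noise_sd = 0) {
  stopifnot(all(c("column_code", "solvent_code") %in% names(conditions)),
            all(c("compound_id", "column_code", "solvent_code",
                  "tr0", "sigma", "tau", "amplitude") %in% names(peak_params)),
            detector_noise_sd >= 0,
            all(peak_params$sigma > 0), all(peak_params$tau >= 0))
  # peaks decay ~6 sigma to the left and ~6 (sigma + tau) to the right
  if (any(peak_params$tr0 - 6 * peak_params$sigma < window[1L]) ||
      any(peak_params$tr0 + 6 * (peak_params$sigma + peak_params$tau) > window[2L])) {
    stop("sampling window does not cover every peak (need ~6 sigma margin ",
         "left and ~6 (sigma + tau) right of each tr0)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), compound_ids = as.character(compound_ids),
                 conditions = conditions, peak_params = peak_params,
                 window = window, sampling_rate = sampling_rate,
                 detector_noise_sd = detector_noise_sd),
            class = "synthetic_config")
}

#' Generate synthetic chromatographic traces
#'
#' One EMG-shaped single-peak trace per row of `cfg$peak_params`, sampled on
#' the configured window with optional additive Gaussian detector noise.
#' Deterministic under the config seed.
#'
#' @param cfg A `synthetic_config`.
#' @return List of `chrom_trace` objects.
#' @export
generate_traces <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  t <- seq(cfg$window[1L], cfg$window[2L], by = 1 / cfg$sampling_rate)
  pp <- cfg$peak_params
  lapply(seq_len(nrow(pp)), function(i) {
    s <- emg_signal(t, pp$tr0[i], pp$sigma[i], pp$tau[i], pp$amplitude[i])
    if (cfg$detector_noise_sd > 0) {
      s <- s + stats::rnorm(length(t), 0, cfg$detector_noise_sd)
    }
    chrom_trace(t, s, compound_id = pp$compound_id[i],
                column_code = pp$column_code[i],
                solvent_code = pp$solvent_code[i])
  })
}

#' Plant replicate clearance indices from a linear model
#'
#' `CI_ij = intercept + sum_k beta_k z_k(i) + eps_ij` with `z` the scaled
#' descriptor values and `eps ~ N(0, noise_sd)`.  Values at or below 0.01 are
#' resampled (a generator property keeping the 1/Y and 1/Y^2 weights finite,
#' not a modelling assumption).
#'
#' @param dm A `descriptor_matrix` containing every planted descriptor.
#' @param planted List with `intercept` and named `coefficients` (scaled
#'   space).
#' @param n_replicates Replicates per compound (default 5).
#' @param noise_sd Replicate noise SD (default 0.08).
#' @param seed RNG seed.
#' @return A `clearance_table`.
#' @export
plant_ci <- function(dm, planted, n_replicates = 5, noise_sd = 0.08, seed = 1) {
  stopifnot(inherits(dm, "descriptor_matrix"), noise_sd >= 0)
  codes <- names(planted$coefficients)
  miss <- setdiff(codes, colnames(dm$values))
  if (length(miss)) {
    stop("planted descriptor(s) missing from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  xs <- scale_matrix(dm)
  lp <- drop(planted$intercept +
               xs$values[, codes, drop = FALSE] %*% planted$coefficients)
  set.seed(as.integer(seed))
  n <- length(lp)
  ci <- rep(lp, each = n_replicates) +
    stats::rnorm(n * n_replicates, 0, noise_sd)
  for (iter in 1:100) {
    low <- ci <= 0.01
    if (!any(low)) break
    ci[low] <- rep(lp, each = n_replicates)[low] +
      stats::rnorm(sum(low), 0, noise_sd)
  }
  ci[ci <= 0.01] <- 0.01 + abs(ci[ci <= 0.01] - 0.01)  # last-resort reflection
  clearance_table(rep(dm$compound_ids, each = n_replicates),
                  rep(seq_len(n_replicates), times = n),
                  ci)
}

# correlated descriptor blocks: equicorrelated factor construction so each
# pair in a block has correlation ~ sqrt(r2_target)
correlated_block <- function(n, k, r2_target) {
  rho <- sqrt(r2_target)
  f <- stats::rnorm(n)
  sapply(seq_len(k), function(j) sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n))
}

#' Generate a complete synthetic study shaped like the real one
#'
#' Produces a bundle mirroring the published study design: 15 compounds x 5
#' replicate clearance indices, a 104-column chromatographic descriptor
#' matrix measured from generated EMG traces on 13 columns x 2 solvents, and
#' a 50-column molecular-like matrix with correlated descriptor blocks.  The
#' clearance outcome follows a planted six-descriptor linear model in scaled
#' chromatographic-descriptor space whose compound means are rescaled to span
#' approximately 0.06-0.85; two compounds are constructed as descriptor-space
#' outliers (see below).
#'
#' The study is identifiable by design.  Six stationary-phase chemistries
#' expressing secondary interactions (T3, PFP, CC18, C8, CN, RCB) each probe
#' an independent interaction dimension per solvent; the planted model places
#' one positive coefficient on the relative-retention (k') descriptor of one
#' solvent per expressive chemistry.  The other seven chemistries retain
#' almost purely (95\%) on a shared hydrophobicity trait, so their k' columns
#' are mutually near-collinear and collapse to a single redundant
#' representative during correlation splitting.  Peak width and tailing
#' follow compound-level propensities shared across conditions.  Every
#' nuisance variation source (the hydrophobicity, width and tailing traits
#' and all non-planted condition residuals) is sample-orthogonalised against
#' the planted descriptor span: at n = 15 a random vector explains an
#' expected R-squared of 6/14 of any six-column span by chance alone, so
#' without this construction nuisance columns routinely proxy for planted
#' descriptors and no subset search could be expected to recover the truth.
#' Latent draws are additionally rejected until an explicit identifiability
#' contract holds on the matrix actually measured from the traces (marginal
#' signal of every planted descriptor, bounded planted collinearity, unique
#' variance against solvent siblings, unconfounded nuisance traits), and the
#' replicate noise stream is redrawn on deterministic sub-seeds until the
#' planted model is clearly supported by its own data.  These rejections are
#' documented design properties of the study -- its stated purpose is a
#' ground-truth benchmark whose planted answer is recoverable -- not
#' per-seed tuning: the same fixed rules run for every seed.
#'
#' Outlier construction: CPD14 elutes as an anomalously broad peak on
#' T3/acetonitrile and CPD15 as an anomalously tailed peak on C8/methanol,
#' making each a descriptor-space outlier along a single peak-shape
#' dimension (the width and tailing descriptors of that condition).  Shape
#' descriptors carry no outcome signal, so the outliers probe leverage
#' geometry without destabilising the planted model's cross-validation.  With five identical replicate rows per compound, a
#' compound's mean leverage is at most 1/5, below the 3(A+1)/I cutoff of
#' 0.28 for the full six-descriptor model (I = 75); the outliers are
#' therefore flagged by [flag_high_leverage()] on compact models of the
#' displaced dimension, not on the final model (see the vignette).
#'
#' @param seed RNG seed.
#' @param n_replicates Replicates per compound (default 5).
#' @param noise_sd Replicate noise SD (default 0.08).
#' @param detector_noise_sd Trace noise SD (default 0).
#' @return List with `traces`, `chrom_matrix` (15 x 104), `molecular_matrix`
#'   (15 x 50), `clearance` (75 rows), `planted` (effective planted model),
#'   `reference_compound`, `outliers`, `config`.
#' @export
paperlike_study <- function(seed = 1, n_replicates = 5, noise_sd = 0.08,
                            detector_noise_sd = 0) {
  seed <- as.integer(seed)
  compounds <- sprintf("CPD%02d", 1:15)
  reference <- "CPD01"
  outliers <- c("CPD14", "CPD15")
  cond <- expand.grid(column_code = chrom_columns(), solvent_code = c("A", "M"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cond_key <- paste0(cond$column_code, cond$solvent_code)
  expressive_chems <- c("T3", "PFP", "CC18", "C8", "CN", "RCB")

  planted_codes <- c("T3A5", "PFPA5", "CC18A5", "C8M5", "CNM5", "RCBA5")
  beta <- stats::setNames(c(0.28, 0.24, 0.26, 0.28, 0.22, 0.25), planted_codes)
  planted_cond <- sub("5$", "", planted_codes)

  set.seed(seed)
  n_cond <- nrow(cond)
  # each expressive chemistry x solvent condition probes an independent
  # secondary-interaction dimension; the other chemistries retain almost
  # purely on hydrophobicity (near-collinear k' descriptors)
  # The study is redrawn until the planted design satisfies the generator's
  # identifiability contract on the *measured* descriptor matrix at the
  # realised n = 15: every planted descriptor carries visible marginal
  # signal (signed correlation with the planted linear predictor >= 0.5)
  # and a solid unique-variance fraction against its solvent sibling and
  # the other planted descriptors (>= 0.30, the information that separates
  # the generative solvent from its sibling in a model comparison); no
  # planted pair crosses the correlation-splitting region (pairwise
  # R^2 <= 0.4); and the nuisance traits (hydrophobicity, width, tailing)
  # stay essentially unconfounded with the outcome.  This enforces the
  # documented recoverability property of the study design rather than
  # leaving it to sampling luck at such a small n.  A cheap check on the
  # latent retention values prescreens draws before the expensive trace
  # synthesis; the contract is then verified on the matrix actually
  # measured from the traces.
  sibling_codes <- paste0(ifelse(endsWith(planted_cond, "A"),
                                 sub("A$", "M", planted_cond),
                                 sub("M$", "A", planted_cond)), "5")
  contract_ok <- function(z, zs, extra) {
    z <- scale(z); zs <- scale(zs)
    lp0 <- drop(z %*% beta)
    rho <- drop(stats::cor(z, lp0))
    r2p <- stats::cor(z)^2; diag(r2p) <- 0
    rho_nuis <- abs(stats::cor(extra, lp0))
    rho_sib <- drop(stats::cor(zs, lp0))
    uniq <- vapply(seq_along(beta), function(j) {
      X <- cbind(1, zs[, j], z[, -j])
      res <- stats::lm.fit(X, z[, j])$residuals
      sum(res^2) / sum((z[, j] - mean(z[, j]))^2)
    }, numeric(1))
    min(rho) >= 0.40 && max(r2p) <= 0.4 && min(rho - rho_sib) >= 0.05 &&
      max(rho_nuis) <= 0.2 && min(uniq) >= 0.30
  }
  for (draw in 1:50) {
    for (try in 1:2000) {
      h0 <- stats::rnorm(15)    # general hydrophobicity (nuisance trait)
      w_trait <- stats::rnorm(15)  # compound peak-width propensity
      q_trait <- stats::rnorm(15)  # compound tailing propensity
      resid_comp <- matrix(stats::rnorm(15 * n_cond), 15, n_cond,
                           dimnames = list(NULL, cond_key))
      cond_z <- function(ck) resid_comp[, ck]
      zl <- sapply(planted_cond, cond_z)
      # everything that is not the planted mechanism is unrelated to
      # placental transport by design: the nuisance traits and every
      # non-planted condition residual are sample-orthogonalised against
      # the planted descriptor span.  At n = 15 a random vector explains
      # an expected R^2 of 6/14 of any 6-column span by chance alone, so
      # without this construction nuisance columns routinely proxy for
      # planted descriptors; with it, the planted model is the unique
      # linear explanation of the outcome up to replicate noise
      orth <- function(v) {
        r <- stats::lm.fit(cbind(1, zl), v)$residuals
        r / stats::sd(r)
      }
      h0 <- orth(h0); w_trait <- orth(w_trait); q_trait <- orth(q_trait)
      for (ck in setdiff(cond_key, planted_cond)) {
        resid_comp[, ck] <- orth(resid_comp[, ck])
      }
      if (contract_ok(zl, sapply(sub("5$", "", sibling_codes), cond_z),
                      cbind(h0, w_trait, q_trait))) break
    }
    base_tr <- stats::runif(n_cond, 4, 7)        # condition-specific retention
    pp <- do.call(rbind, lapply(seq_len(n_cond), function(ci) {
      chem <- cond$column_code[ci]
      log_ret <- if (chem %in% expressive_chems) {
        0.12 * resid_comp[, cond_key[ci]]
      } else {
        0.12 * (sqrt(0.95) * h0 + sqrt(0.05) * resid_comp[, cond_key[ci]])
      }
      # peak shape is dominated by compound-level propensities shared across
      # conditions (96% trait / 4% condition-specific), as diffusion- and
      # silanol-driven broadening mostly travels with the analyte
      sigma <- pmin(exp(log(0.055) +
                          0.35 * (sqrt(0.96) * w_trait +
                                  sqrt(0.04) * orth(stats::rnorm(15)))), 0.35)
      # tau/sigma kept moderate: large tails would shift the measured apex
      # and leak peak-shape traits into the retention descriptors
      ratio <- pmin(exp(0.3 * (sqrt(0.96) * q_trait +
                               sqrt(0.04) * orth(stats::rnorm(15)))), 2.5)
      # CPD14 / CPD15: deterministic descriptor-space outliers on the peak-
      # shape side (an anomalously broad peak, and an anomalously tailed
      # peak, on one condition each).  Shape descriptors carry no outcome
      # signal, so the outliers exercise leverage geometry without
      # destabilising the planted model's cross-validation
      if (cond_key[ci] == "T3A") sigma[14] <- 0.19
      if (cond_key[ci] == "C8M") ratio[15] <- 3
      data.frame(compound_id = compounds, column_code = chem,
                 solvent_code = cond$solvent_code[ci],
                 tr0 = base_tr[ci] * exp(log_ret), sigma = sigma,
                 tau = sigma * ratio,
                 amplitude = exp(stats::rnorm(15, 0, 0.2)),
                 stringsAsFactors = FALSE)
    }))
    cfg <- synthetic_config(seed, compounds, cond, pp,
                            window = c(0, 26), sampling_rate = 200,
                            detector_noise_sd = detector_noise_sd)
    # generate_traces seeds its own noise stream; preserve this function's
    # stream so every redraw sees fresh latent values
    rs <- get(".Random.seed", envir = globalenv())
    traces <- generate_traces(cfg)
    assign(".Random.seed", rs, envir = globalenv())
    chrom <- traces_to_matrix(traces, reference, schema = chrom_schema())
    zc <- scale_matrix(chrom)$values
    if (contract_ok(zc[, planted_codes], zc[, sibling_codes],
                    cbind(h0, w_trait, q_trait))) break
  }

  # molecular-like matrix: 50 columns, a few correlated blocks, rest noise
  set.seed(seed + 1L)
  mol_schema <- molecular_schema()
  vals <- matrix(stats::rnorm(15 * 50), 15, 50,
                 dimnames = list(compounds, mol_schema$code))
  blocks <- list(c("LP1", "LP2", "LP3", "CD1"),
                 c("MT2", "MT5", "MT12"),
                 c("DE1", "DE2", "DE5"))
  for (b in blocks) vals[, b] <- correlated_block(15, length(b), 0.7)
  vals[14, c("LP2", "DE1", "DE2")] <- vals[14, c("LP2", "DE1", "DE2")] + 4
  vals[15, c("MT5", "DE9")] <- vals[15, c("MT5", "DE9")] - 4
  mol <- descriptor_matrix(vals, schema = mol_schema)

  # planted model on six relative-retention descriptors (one per expressive
  # chemistry), linear predictor rescaled so compound means span 0.06-0.85
  xs <- scale_matrix(chrom)
  lp <- drop(xs$values[, planted_codes] %*% beta)
  a <- (0.85 - 0.06) / diff(range(lp))
  b <- 0.06 - a * min(lp)
  planted <- list(intercept = b, coefficients = a * beta)
  # final identifiability invariant, on the realised replicate noise: the
  # planted model itself must be clearly supported by the data it generated
  # (every planted coefficient significant at p <= 0.01 in the exact
  # weighted fit), and the per-compound mean of the replicate noise must be
  # essentially unconfounded with the nuisance traits and with the planted
  # descriptors' solvent siblings (|cor| <= 0.25 on compound means).  At
  # n = 15 a single unlucky noise draw can render a true descriptor
  # statistically invisible or hand a spurious competitor real utility; the
  # noise stream is therefore redrawn on a deterministic sub-seed sequence
  # until both conditions hold, falling back to the best draw seen.
  lp_mean <- planted$intercept +
    drop(xs$values[, planted_codes] %*% planted$coefficients)
  confounders <- cbind(h0, w_trait, q_trait,
                       scale(xs$values[, sibling_codes]))
  clearance <- plant_ci(chrom, planted, n_replicates = n_replicates,
                        noise_sd = noise_sd, seed = seed + 2L)
  best_score <- if (noise_sd > 0) Inf else -Inf  # invariant vacuous at sd 0
  for (k in 0:199) {
    if (best_score <= 1) break
    cl_k <- plant_ci(chrom, planted, n_replicates = n_replicates,
                     noise_sd = noise_sd, seed = seed + 2L + 1000L * k)
    m <- fit_wls(xs, cl_k, planted_codes, "1/Y")
    mp <- max(m$p[setdiff(names(m$p), "(Intercept)")])
    noise_mean <- tapply(cl_k$ci, cl_k$compound_id, mean)[compounds] - lp_mean
    conf <- max(abs(stats::cor(confounders, noise_mean)))
    # sibling added-variable check: given the planted model, each solvent
    # sibling must contribute nothing (p >= 0.2) while its planted partner
    # stays clearly needed in the sibling's presence (p <= 0.05)
    pair <- vapply(seq_along(planted_codes), function(j) {
      mj <- tryCatch(fit_wls(xs, cl_k, c(planted_codes, sibling_codes[j]),
                             "1/Y"), error = function(e) NULL)
      if (is.null(mj)) return(c(1, 0))
      c(mj$p[[planted_codes[j]]], mj$p[[sibling_codes[j]]])
    }, numeric(2))
    score <- max(mp / 0.01, conf / 0.25, max(pair[1, ]) / 0.05,
                 0.2 / max(min(pair[2, ]), 1e-12))
    if (score < best_score) { best_score <- score; clearance <- cl_k }
    if (best_score <= 1) break
  }

  list(traces = traces, chrom_matrix = chrom, molecular_matrix = mol,
       clearance = clearance, planted = planted,
       reference_compound = reference, outliers = outliers, config = cfg)
}
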