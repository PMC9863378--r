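test_that("an exactly linear outcome is fitted with zero residuals and R^2 = 1", {
  d <- planted_linear_data(noise_sd = 0)
  m <- fit_wls(d$xs, d$y, c("d01", "d02"), "1")
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(unname(m$coefficients[names(d$beta)]), unname(d$beta),
               tolerance = 1e-8)
  expect_equal(m$intercept, d$intercept, tolerance = 1e-8)
  expect_lt(max(abs(m$fitted - d$y$ci)), 1e-10)
})

test_that("weighted fits equal an independent lm(weights=) solve", {
  d <- planted_linear_data(seed = 22)
  X <- d$xs$values[d$y$compound_id, c("d01", "d02", "d03")]
  for (w_mode in c("1", "1/Y", "1/Y^2")) {
    m <- fit_wls(d$xs, d$y, c("d01", "d02", "d03"), w_mode)
    w <- switch(w_mode, "1" = rep(1, nrow(d$y)), "1/Y" = 1 / d$y$ci,
                "1/Y^2" = 1 / d$y$ci^2)
    ref <- wls_oracle(X, d$y$ci, w)
    expect_equal(unname(c(m$intercept, m$coefficients)), ref,
                 tolerance = 1e-8)
    # p-values against summary.lm on the same weighted fit
    sm <- summary(stats::lm(d$y$ci ~ X, weights = w))
    expect_equal(unname(m$p), unname(sm$coefficients[-1, 4]),
                 tolerance = 1e-8)
  }
})

test_that("leverages are hat diagonals summing to A + 1", {
  d <- planted_linear_data(seed = 23)
  for (w_mode in c("1", "1/Y", "1/Y^2")) {
    m <- fit_wls(d$xs, d$y, c("d01", "d02"), w_mode)
    expect_equal(sum(m$leverage), m$A + 1, tolerance = 1e-9)
    expect_true(all(m$leverage >= 0 & m$leverage <= 1))
    # compound-level leverage is the mean over that compound's replicates
    expect_equal(m$leverage_by_compound[["X01"]],
                 mean(m$leverage[paste("X01", 1:5, sep = ":")]))
  }
})

test_that("a compound at the descriptor centroid is predicted at the intercept", {
  vals <- rbind(X1 = c(a = -1, b = 2), X2 = c(a = 1, b = -2),
                X3 = c(a = -2, b = -1), X4 = c(a = 2, b = 1),
                X5 = c(a = 0, b = 0))  # X5 sits at the centroid
  dm <- descriptor_matrix(vals)
  xs <- scale_matrix(dm)
  y <- mk_y(rownames(vals), c(0.3, 0.7, 0.45, 0.55, 0.5))
  m <- fit_wls(xs, y, c("a", "b"), "1")
  expect_equal(unname(predict(m, dm)["X5"]), m$intercept, tolerance = 1e-12)
})

test_that("raw-space and scaled-space predictions agree", {
  d <- planted_linear_data(seed = 24)
  m <- fit_wls(d$xs, d$y, c("d01", "d02"), "1/Y")
  raw <- mk_mat(15, 3, seed = 24)  # the un-scaled original values
  expect_equal(predict(m, raw), predict(m, d$xs), tolerance = 1e-12)
})

test_that("degenerate designs raise specific errors", {
  d <- planted_linear_data(seed = 25, reps = 1L)
  # insufficient data: 3 observations for 3 descriptors
  y3 <- mk_y(rownames(d$xs$values)[1:3], c(0.3, 0.5, 0.7))
  expect_error(fit_wls(d$xs, y3, c("d01", "d02", "d03"), "1"),
               "insufficient data: 3 observations for 3 descriptors")
  # collinear design names the dependent column
  vals <- mk_mat(10, 3, seed = 26)
  vals[, 3] <- vals[, 1] + vals[, 2]
  xsc <- mk_xs(vals)
  yc <- mk_y(rownames(vals), seq(0.2, 0.9, length.out = 10))
  expect_error(fit_wls(xsc, yc, c("d01", "d02", "d03"), "1"),
               "collinear design; dependent column\\(s\\)")
  expect_error(fit_wls(d$xs, d$y, "nope", "1"), "unknown descriptor")
  expect_error(fit_wls(d$xs, d$y, "d01", "1/z"), "unknown weighting")
})

test_that("the fit cache returns identical models and replays errors", {
  d <- planted_linear_data(seed = 27)
  cache <- new.env(parent = emptyenv())
  m1 <- fit_wls(d$xs, d$y, c("d02", "d01"), "1/Y", cache = cache)
  m2 <- fit_wls(d$xs, d$y, c("d01", "d02"), "1/Y", cache = cache)
  # same set, same weighting: served from cache regardless of order
  expect_identical(m1, m2)
  y3 <- mk_y(rownames(d$xs$values)[1:3], c(0.3, 0.5, 0.7))
  expect_error(fit_wls(d$xs, y3, c("d01", "d02", "d03"), "1", cache = cache),
               "insufficient data")
  expect_error(fit_wls(d$xs, y3, c("d01", "d02", "d03"), "1", cache = cache),
               "insufficient data")  # cached condition re-raised
})

test_that("pruning removes a pure-noise descriptor in at least 90% of seeds", {
  # unit weights match the homoscedastic simulated noise, so the t-test holds
  # its nominal 5% size and removal is expected in ~95% of seeds
  removed <- vapply(1:20, function(s) {
    d <- planted_linear_data(seed = 300 + s)
    m <- prune_model(fit_wls(d$xs, d$y, c("d01", "d02", "d03"), "1"))
    !("d03" %in% m$descriptors)
  }, logical(1))
  expect_gte(sum(removed), 18L)
})

test_that("pruning leaves a strongly planted model unchanged", {
  unchanged <- vapply(1:20, function(s) {
    d <- planted_linear_data(seed = 300 + s)
    m <- prune_model(fit_wls(d$xs, d$y, c("d01", "d02"), "1"))
    setequal(m$descriptors, c("d01", "d02"))
  }, logical(1))
  expect_gte(sum(unchanged), 18L)
})

test_that("pruning a pure-noise model yields a degenerate intercept-only model", {
  xs <- mk_xs(mk_mat(15, 3, seed = 31))
  y <- mk_y(rownames(xs$values), rep(0.5, 15), reps = 5L, noise_sd = 0.1,
            seed = 31)
  m <- prune_model(fit_wls(xs, y, "d01", "1"))
  expect_true(m$degenerate)
  expect_equal(m$A, 0L)
  expect_true(m$pruned)
  expect_equal(unname(predict(m, xs)), rep(m$intercept, 15))
})

test_that("many simultaneous non-significant descriptors trigger stepwise simplification", {
  d <- planted_linear_data(seed = 32, p = 8)
  m <- prune_model(fit_wls(d$xs, d$y, colnames(d$xs$values), "1"))
  expect_true(all(m$p < 0.05))
  expect_true(all(c("d01", "d02") %in% m$descriptors))
  expect_lt(m$A, 8L)
})

test_that("model ranking filters on R^2 and significance and sorts by BIC", {
  d <- planted_linear_data(seed = 33)
  small <- prune_model(fit_wls(d$xs, d$y, c("d01", "d02"), "1/Y"))
  big <- fit_wls(d$xs, d$y, c("d01", "d02", "d03"), "1/Y")
  ranked <- rank_models(list(big, small), r2_min = 0.5)
  # the pure-noise extra descriptor fails the all-significant filter or the
  # BIC comparison; the parsimonious model must rank first
  expect_equal(ranked[[1]]$descriptors, c("d01", "d02"))
  # R^2 filter: demand more than the model achieves
  expect_equal(length(rank_models(list(small), r2_min = small$r2 + 0.01)), 0L)
  expect_match(attr(rank_models(list(small), r2_min = small$r2 + 0.01),
                    "diagnostic"), "no model passed")
  # single survivor is returned alone
  expect_equal(length(rank_models(list(small), r2_min = 0.5)), 1L)
})

test_that("BIC ties are broken by fewer descriptors, then lexicographic codes", {
  d <- planted_linear_data(seed = 34)
  base <- fit_wls(d$xs, d$y, c("d01", "d02"), "1/Y")
  m_a <- base; m_a$bic <- 10; m_a$A <- 3L; m_a$descriptors <- c("a", "b", "c")
  m_b <- base; m_b$bic <- 10; m_b$A <- 2L; m_b$descriptors <- c("a", "b")
  m_c <- base; m_c$bic <- 10; m_c$A <- 2L; m_c$descriptors <- c("a", "c")
  ranked <- rank_models(list(m_a, m_c, m_b), r2_min = 0.5)
  expect_equal(lapply(ranked, `[[`, "descriptors"),
               list(c("a", "b"), c("a", "c"), c("a", "b", "c")))
})

test_that("a balanced orthogonal design has uniform leverage and no flags", {
  vals <- cbind(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  rownames(vals) <- sprintf("X%d", 1:4)
  xs <- mk_xs(vals)
  y <- mk_y(rownames(vals), c(0.3, 0.5, 0.4, 0.6))
  m <- fit_wls(xs, y, c("a", "b"), "1")
  flags <- flag_high_leverage(m)
  expect_equal(flags$mean_leverage, rep((m$A + 1) / m$I, 4))
  expect_false(any(flags$flagged))
  expect_equal(flags$cutoff, rep(3 * (m$A + 1) / m$I, 4))
})

test_that("a far-displaced compound is flagged as high leverage", {
  set.seed(41)
  x <- c(stats::rnorm(11), 10)   # one compound ~10 SDs out
  vals <- cbind(d01 = x)
  rownames(vals) <- sprintf("X%02d", 1:12)
  xs <- mk_xs(vals)
  y <- mk_y(rownames(vals), 0.2 + 0.03 * seq_len(12))
  flags <- flag_high_leverage(fit_wls(xs, y, "d01", "1"))
  expect_true(flags$flagged[flags$compound_id == "X12"])
  expect_false(any(flags$flagged[flags$compound_id != "X12"]))
  # custom rule is honoured
  all_in <- flag_high_leverage(fit_wls(xs, y, "d01", "1"),
                               rule = function(A, I) 2)
  expect_false(any(all_in$flagged))
})
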