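test_that("random split plans have the published arithmetic", {
  compounds <- table1_fixture()$compound_id
  plan <- make_split_plan(compounds, pinned = c("BPS", "BPFL"), seed = 1)
  expect_equal(plan$n_sets, 3L)
  for (k in 1:3) {
    expect_equal(length(plan$test_sets[[k]]), 4L)
    expect_equal(length(plan$training_sets[[k]]), 11L)
    # 11 training compounds x 5 replicates = 55; 4 x 5 = 20
    expect_equal(5L * length(plan$training_sets[[k]]), 55L)
    expect_equal(5L * length(plan$test_sets[[k]]), 20L)
  }
  tested <- unlist(plan$test_sets)
  expect_false(anyDuplicated(tested) > 0)      # disjoint test sets
  expect_equal(length(tested), 12L)            # 12 of 13 eligible tested once
  expect_false(any(c("BPS", "BPFL") %in% tested))
})

test_that("pinned compounds never enter a test set over 1000 random seeds", {
  compounds <- sprintf("C%02d", 1:15)
  pinned <- c("C01", "C09")
  hit <- FALSE
  for (s in 1:1000) {
    plan <- make_split_plan(compounds, pinned = pinned, seed = s)
    if (any(pinned %in% unlist(plan$test_sets))) { hit <- TRUE; break }
  }
  expect_false(hit)
})

test_that("split plan construction enforces its contract", {
  compounds <- sprintf("C%02d", 1:15)
  expect_error(make_split_plan(compounds, pinned = compounds[1:5]),
               "not enough unpinned compounds")
  expect_error(make_split_plan(compounds,
                               test_sets = list(c("C01", "C02", "C03", "C01"),
                                                c("C04", "C05", "C06", "C07"),
                                                c("C08", "C09", "C10", "C11"))),
               "disjoint")
  expect_error(make_split_plan(compounds, pinned = "C01",
                               test_sets = list(c("C01", "C02", "C03", "C04"),
                                                c("C05", "C06", "C07", "C08"),
                                                c("C09", "C10", "C11", "C12"))),
               "pinned compound\\(s\\) requested in a test set: C01")
  expect_error(make_split_plan(compounds,
                               test_sets = list(c("C01", "C02", "C03"),
                                                c("C05", "C06", "C07", "C08"),
                                                c("C09", "C10", "C11", "C12"))),
               "every test set must have 4 compounds")
  expect_error(make_split_plan(compounds,
                               test_sets = list(c("ZZ", "C02", "C03", "C04"),
                                                c("C05", "C06", "C07", "C08"),
                                                c("C09", "C10", "C11", "C12"))),
               "not in compound list")
})

test_that("noiseless planted data cross-validate perfectly", {
  d <- planted_linear_data(seed = 61, noise_sd = 0)
  cv <- cross_validate(d$xs, d$y, c("d01", "d02"), "1/Y")
  expect_equal(cv$q2, 1, tolerance = 1e-9)
  expect_equal(cv$rmsecv, 0, tolerance = 1e-6)
  expect_equal(length(cv$skipped), 0L)
})

test_that("cross-validation is grouped by compound with one fold each", {
  vals <- cbind(d01 = c(-1, 0, 1))
  rownames(vals) <- c("A", "B", "C")
  xs <- mk_xs(vals)
  y <- mk_y(rownames(vals), c(0.2, 0.5, 0.8), reps = 2L, noise_sd = 0.01,
            seed = 62)
  cv <- cross_validate(xs, y, "d01", "1")
  expect_false(anyNA(cv$predictions$predicted))
  # both replicates of a held-out compound get the same prediction (their
  # descriptors are identical, so the fold refit predicts them together)
  pa <- cv$predictions$predicted[cv$predictions$compound_id == "A"]
  expect_equal(pa[1], pa[2])
  expect_error(cross_validate(xs, y[y$compound_id != "A", ], "d01", "1"),
               "at least 3 training compounds")
})

test_that("cross-validated Q^2 is below calibration R^2 (optimism) in >= 90% of seeds", {
  worse <- vapply(1:20, function(s) {
    d <- planted_linear_data(seed = 600 + s, noise_sd = 0.1)
    m <- fit_wls(d$xs, d$y, c("d01", "d02"), "1/Y")
    cv <- cross_validate(d$xs, d$y, c("d01", "d02"), "1/Y")
    cv$q2 < m$r2
  }, logical(1))
  expect_gte(sum(worse), 18L)
})

test_that("noiseless planted data pass leave-many-out validation perfectly", {
  d <- planted_linear_data(seed = 63, noise_sd = 0)
  plan <- make_split_plan(rownames(d$xs$values), seed = 63)
  rep_ <- lmo_validate(d$xs, d$y, c("d01", "d02"), plan, "1/Y")
  expect_equal(rep_$metrics$qlmo2, 1, tolerance = 1e-9)
  expect_equal(rep_$metrics$ccc, 1, tolerance = 1e-9)
  expect_equal(rep_$metrics$r2, 1, tolerance = 1e-9)
  expect_equal(rep_$metrics$q2, 1, tolerance = 1e-9)
  expect_true(all(unlist(rep_$verdicts)))
  expect_equal(nrow(rep_$pooled), 12L)  # 3 sets x 4 test compounds
})

test_that("withholding a planted descriptor lowers QLMO^2 in >= 90% of seeds", {
  lower <- vapply(1:20, function(s) {
    d <- planted_linear_data(seed = 700 + s, noise_sd = 0.08,
                             beta = c(d01 = 0.25, d02 = 0.2))
    plan <- make_split_plan(rownames(d$xs$values), seed = s)
    full <- lmo_validate(d$xs, d$y, c("d01", "d02"), plan, "1/Y")
    mis <- lmo_validate(d$xs, d$y, "d01", plan, "1/Y")
    mis$metrics$qlmo2 < full$metrics$qlmo2
  }, logical(1))
  expect_gte(sum(lower), 18L)
})

test_that("validation verdicts compare each metric to its threshold", {
  d <- planted_linear_data(seed = 64, noise_sd = 0.1)
  plan <- make_split_plan(rownames(d$xs$values), seed = 64)
  th <- list(r2 = 0.65, q2 = 0.5, qlmo2 = 0.65, ccc = 0.85)
  rep_ <- lmo_validate(d$xs, d$y, c("d01", "d02"), plan, "1/Y",
                       thresholds = th)
  for (nm in names(th)) {
    expect_equal(rep_$verdicts[[nm]], rep_$metrics[[nm]] > th[[nm]])
  }
  # a threshold just above the achieved value flips the verdict
  th2 <- th; th2$ccc <- rep_$metrics$ccc + 1e-6
  rep2 <- lmo_validate(d$xs, d$y, c("d01", "d02"), plan, "1/Y",
                       thresholds = th2)
  expect_false(rep2$verdicts$ccc)
})

test_that("per-set metrics aggregate as means and CCC pools compound means", {
  d <- planted_linear_data(seed = 65, noise_sd = 0.05)
  plan <- make_split_plan(rownames(d$xs$values), seed = 65)
  rep_ <- lmo_validate(d$xs, d$y, c("d01", "d02"), plan, "1/Y")
  expect_equal(rep_$metrics$qlmo2, mean(rep_$per_set$qlmo2), tolerance = 1e-12)
  expect_equal(rep_$metrics$r2, mean(rep_$per_set$r2), tolerance = 1e-12)
  expect_equal(rep_$metrics$ccc,
               lin_ccc(rep_$pooled$mean_observed, rep_$pooled$predicted),
               tolerance = 1e-12)
})

test_that("test compounds outside the training cloud are flagged unreliable", {
  vals <- cbind(d01 = c(1:9, 30))
  rownames(vals) <- sprintf("X%02d", 1:10)
  xs <- mk_xs(vals)
  y <- mk_y(rownames(vals), 0.1 + 0.02 * c(1:9, 30))
  plan <- make_split_plan(rownames(vals), n_sets = 1, test_size = 2,
                          test_sets = list(c("X09", "X10")))
  rep_ <- lmo_validate(xs, y, "d01", plan, "1")
  expect_false(is.null(rep_$unreliable))
  expect_true("X10" %in% rep_$unreliable$compound_id)
  expect_false("X09" %in% rep_$unreliable$compound_id)
})
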