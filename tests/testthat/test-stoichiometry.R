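test_that("ratio series follow the stated conventions", {
  tab <- toy_table(n = 2, nf = 6,
                   ibaq = rbind(c(1, 2, 0, 4, 5, 6), c(2, 4, 8, 8, 10, 12)))
  # self-ratio is exactly 1
  s <- ratio_series(tab, "P02", "P02", window = c(1L, 6L))
  expect_true(all(s$ratios == 1))
  # bait-zero fractions are skipped and counted
  s2 <- ratio_series(tab, "P02", "P01", window = c(1L, 6L))
  expect_identical(s2$fractions, c(1L, 2L, 4L, 5L, 6L))
  expect_identical(s2$n_skipped, 1L)
  expect_equal(s2$ratios, c(2, 2, 2, 2, 2))
  # all-zero protein gives all-zero ratios
  zero <- toy_table(n = 2, nf = 4, ibaq = rbind(c(1, 1, 1, 1), c(0, 0, 0, 0)))
  expect_true(all(ratio_series(zero, "P02", "P01", c(1L, 4L))$ratios == 0))
  expect_error(ratio_series(tab, "P01", "missing", c(1L, 6L)),
               class = "bnpcp_value_error")
  expect_error(ratio_series(tab, "P01", "P02", c(1L, 99L)),
               class = "bnpcp_input_error")
})

test_that("synthetic flat subunits have the closed-form constant iBAQ ratio", {
  tr <- default_truth(noise_cv = 0, dropout_rate = 0)
  tab <- simulate_table(tr, 1L)
  pep <- bnpcp:::peptide_counts(tr)
  ids <- vapply(tr$subunits, `[[`, character(1), "protein_id")
  for (id in truth_ids(tr, "core")) {
    s <- ratio_series(tab, id, "P_MTA2", window = c(26L, 36L))
    su <- tr$subunits[[match(id, ids)]]
    # iBAQ ratio = intensity ratio x (bait peptides / protein peptides)
    expected <- su$per_entity_ratio[1] *
      pep[match("P_MTA2", ids)] / pep[match(id, ids)]
    expect_equal(s$ratios, rep(expected, length(s$ratios)), tolerance = 1e-10)
  }
})

test_that("OLS slope matches analytic values and stats::lm", {
  flat <- structure(list(protein_id = "x", fractions = 26:36,
                         ratios = rep(1, 11), n_skipped = 0L),
                    class = "ratio_series")
  f <- fit_slope(flat)
  expect_identical(f$slope, 0)
  expect_identical(f$trend, "flat")

  line <- structure(list(protein_id = "x", fractions = 26:36,
                         ratios = as.numeric(26:36), n_skipped = 0L),
                    class = "ratio_series")
  fl <- fit_slope(line)
  expect_equal(fl$slope, 1, tolerance = 1e-12)
  expect_identical(fl$trend, "ascending")

  five <- structure(list(protein_id = "x", fractions = 26:30,
                         ratios = c(1, 2, 3, 4.5, 4.5), n_skipped = 0L),
                    class = "ratio_series")
  ff <- fit_slope(five)
  lm_fit <- summary(stats::lm(c(1, 2, 3, 4.5, 4.5) ~ I(26:30)))
  expect_equal(ff$slope, unname(lm_fit$coefficients[2, 1]), tolerance = 1e-12)
  expect_equal(ff$intercept, unname(lm_fit$coefficients[1, 1]), tolerance = 1e-10)
  expect_equal(ff$stderr_slope, unname(lm_fit$coefficients[2, 2]), tolerance = 1e-10)
  expect_equal(ff$p_value, unname(lm_fit$coefficients[2, 4]), tolerance = 1e-10)

  exact5 <- structure(list(protein_id = "x", fractions = 26:30,
                           ratios = c(1, 2, 3, 4, 5), n_skipped = 0L),
                      class = "ratio_series")
  fe <- fit_slope(exact5)
  expect_equal(fe$slope, 1, tolerance = 1e-12)
  expect_equal(fe$intercept, -25, tolerance = 1e-10)
})

test_that("fit_slope input contracts hold", {
  short <- structure(list(protein_id = "x", fractions = 26:27,
                          ratios = c(1, 2), n_skipped = 0L),
                     class = "ratio_series")
  expect_error(fit_slope(short), class = "bnpcp_insufficient_data_error")
  same_x <- structure(list(protein_id = "x", fractions = c(26L, 26L, 26L),
                           ratios = c(1, 2, 3), n_skipped = 0L),
                      class = "ratio_series")
  expect_error(fit_slope(same_x), class = "bnpcp_value_error")
})

test_that("trend classification applies the alpha rule and scaling invariance", {
  res <- list(slope = 0.04, p_value = 0.001)
  expect_identical(classify_trend(res, 0.05), "ascending")
  expect_identical(classify_trend(list(slope = 0, p_value = 1), 0.05), "flat")
  expect_identical(classify_trend(list(slope = -2, p_value = 0.01), 0.05), "descending")
  expect_error(classify_trend(res, 1.5), class = "bnpcp_input_error")

  withr::local_seed(12)
  y <- 2 + 0.1 * (26:36) + rnorm(11, sd = 0.3)
  s1 <- structure(list(protein_id = "x", fractions = 26:36, ratios = y,
                       n_skipped = 0L), class = "ratio_series")
  s2 <- s1; s2$ratios <- y * 7
  f1 <- fit_slope(s1); f2 <- fit_slope(s2)
  expect_equal(f2$slope, 7 * f1$slope, tolerance = 1e-10)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-10)
  expect_identical(f1$trend, f2$trend)
})

test_that("bait self-ratio is exactly flat even under noise", {
  tr <- default_truth(noise_cv = 0.2)
  tab <- simulate_table(tr, 1L)
  f <- fit_slope(ratio_series(tab, "P_MTA2", "P_MTA2", c(26L, 36L)))
  expect_identical(f$slope, 0)
  expect_identical(f$trend, "flat")
})

test_that("slope_table reports every protein with not_fitted fallbacks", {
  tr <- default_truth(noise_cv = 0, dropout_rate = 0)
  tab <- simulate_table(tr, 1L)
  st <- slope_table(tab, "P_MTA2", bh = TRUE)
  expect_identical(st$protein_id, tab$proteins$protein_id)
  expect_true(all(c("slope", "p_value", "trend", "p_bh", "trend_bh") %in% names(st)))
  # contaminants have no structured signal; their row exists regardless
  expect_true(all(st$trend %in% c("flat", "ascending", "descending", "not_fitted")))
  # enriched subunits rise toward the high-mass entity in the noiseless world
  expect_true(all(st$trend[st$protein_id %in% truth_ids(tr, "enriched")] == "ascending"))
  expect_true(all(st$trend[st$protein_id %in% truth_ids(tr, "core")] == "flat"))
})
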