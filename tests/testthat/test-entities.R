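gaussian_profile <- function(nf, apex, width, amount = 1) {
  amount * exp(-((seq_len(nf) - apex)^2) / (2 * width^2))
}

test_that("a single clean Gaussian yields one region at its mean", {
  v <- gaussian_profile(48, 20, 2)
  pk <- detect_peaks(v / sum(v))
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$apex, 20L)
  expect_true(pk$left < 20 && pk$right > 20)
})

test_that("the default noiseless bait has exactly two regions at 29 and 33", {
  tr <- default_truth(noise_cv = 0, dropout_rate = 0)
  pr <- build_profiles(simulate_table(tr, 1L))
  pk <- detect_peaks(profile_of(pr, "P_MTA2"))
  expect_identical(nrow(pk), 2L)
  expect_identical(pk$apex, c(29L, 33L))
  expect_identical(pk$label, c("I", "II"))
  calib <- calibrate_mw(default_marker_ladder())
  pk2 <- detect_peaks(profile_of(pr, "P_MTA2"), calibration = calib)
  # both assemblies annotate to the ~1 MDa region
  expect_true(all(pk2$apex_mass_kda > 900 & pk2$apex_mass_kda < 1200))
})

test_that("adjacent equal maxima merge into one plateau region", {
  v <- c(0, 1, 1, 0)
  pk <- detect_peaks(v)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$apex, 2L)
})

test_that("well-separated k-Gaussian mixtures give k regions at the true apexes", {
  v <- gaussian_profile(60, 10, 1.5) + gaussian_profile(60, 25, 2) +
    gaussian_profile(60, 45, 1.5, amount = 0.8)
  pk <- detect_peaks(v / sum(v))
  expect_identical(pk$apex, c(10L, 25L, 45L))
})

test_that("detect_peaks validates its inputs", {
  expect_error(detect_peaks(rep(0, 10)), class = "bnpcp_value_error")
  expect_error(detect_peaks(c(0, 1, 0), smooth_window = 2), class = "bnpcp_input_error")
})

test_that("isolated dropout zeros do not destroy a true peak", {
  v <- gaussian_profile(48, 29, 0.8) + 1.15 * gaussian_profile(48, 33, 0.8)
  v[33] <- 0  # the apex cell of the stronger peak drops out
  pk <- detect_peaks(v / sum(v))
  expect_identical(nrow(pk), 2L)
  expect_true(all(abs(pk$apex - c(29, 33)) <= 1))
})

test_that("entity shares and calls follow containment and monotonicity", {
  regions <- structure(data.frame(label = c("I", "II"),
                                  left = c(5L, 12L), apex = c(8L, 15L),
                                  right = c(11L, 18L),
                                  apex_mass_kda = NA_real_),
                       class = c("peak_regions", "data.frame"))
  v <- numeric(20); v[13:17] <- 0.2
  em <- assign_entity(v, regions, call_threshold = 0.2)
  expect_equal(unname(em$shares), c(0, 1))
  expect_identical(unname(em$calls), c(FALSE, TRUE))
  expect_false(em$outside)

  # scaling invariance
  em2 <- assign_entity(v * 100, regions)
  expect_equal(em2$shares, em$shares)

  # raising the threshold never adds a call
  mixed <- numeric(20); mixed[6:10] <- 0.06; mixed[13:17] <- 0.14
  calls <- lapply(c(0.1, 0.3, 0.5, 0.8), function(th) {
    assign_entity(mixed, regions, call_threshold = th)$calls
  })
  for (i in seq_len(length(calls) - 1)) {
    expect_true(all(calls[[i + 1]] <= calls[[i]]))
  }

  # outside reporting
  out <- numeric(20); out[1:3] <- 1 / 3
  expect_true(assign_entity(out, regions)$outside)

  overlapping <- regions
  overlapping$left[2] <- 10L
  expect_error(assign_entity(v, overlapping), class = "bnpcp_input_error")
})

test_that("entity report joins calls, trends, and cluster membership", {
  expect_identical(nrow(entity_report(NULL)), 0L)
  empty <- entity_report(data.frame())
  expect_true(all(c("protein_id", "trend", "in_bait_cluster") %in% names(empty)))

  tr <- default_truth(noise_cv = 0, dropout_rate = 0)
  tab <- simulate_table(tr, 1L)
  pr <- build_profiles(tab)
  regions <- detect_peaks(profile_of(pr, "P_MTA2"))
  mem <- entity_assignments(pr, regions)
  slopes <- slope_table(tab, "P_MTA2")
  rep <- entity_report(mem, slopes, co_cluster_members = c("P_MTA2", "P_HDAC1"))
  expect_identical(nrow(rep), nrow(tab$proteins))
  expect_true(all(c("share_I", "share_II", "call_I", "call_II",
                    "trend", "in_bait_cluster") %in% names(rep)))
  expect_true(rep$in_bait_cluster[rep$protein_id == "P_HDAC1"])

  # noiseless truth: II-only partners are called II and not I
  ii_only <- c("P_SALL4", "P_CDK2AP1")
  expect_true(all(rep$call_II[rep$protein_id %in% ii_only]))
  expect_false(any(rep$call_I[rep$protein_id %in% ii_only]))
  expect_true(rep$call_I[rep$protein_id == "P_SUZ12"])
  expect_false(rep$call_II[rep$protein_id == "P_SUZ12"])
  expect_true(all(rep$call_I[rep$protein_id == "P_WDR5"],
                  rep$call_II[rep$protein_id == "P_WDR5"]))
})
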