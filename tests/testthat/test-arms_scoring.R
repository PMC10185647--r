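test_that("assay definitions carry the published primers and scoring setup", {
  g12v <- assay_definition("G12V")
  expect_equal(g12v$forward_primer, "CTTGTGGTAGTTGGAGCTTT")
  expect_equal(g12v$reverse_primer, "CTCTATTGTTGGATCATATTCG")
  expect_equal(g12v$scoring_temp, 79.5)
  expect_equal(g12v$expected_peaks, 80.0)
  g12d <- assay_definition("G12D")
  expect_equal(g12d$forward_primer, "CTTGTGGTAGTTGGAGCTTA")
  expect_equal(g12d$expected_peaks, c(75.5, 79.5))
  expect_equal(assay_definition("WT")$expected_peaks, 78.5)
  expect_error(assay_definition("G12V", threshold = 1.2), "threshold")
})

test_that("peak intensity reads the scoring window of the derivative", {
  assay <- assay_definition("G12D")  # window 78.5-80.5
  d <- negative_derivative(logistic_melt(tm = 79.5, w = 0.8, A = 1))
  expect_equal(peak_intensity(d, assay), 1 / (4 * 0.8), tolerance = 0.02)
  flat <- negative_derivative(melt_curve("W", "S", melt_grid(), rep(1, 251)))
  expect_equal(peak_intensity(flat, assay), 0)
  # a 75.5-only transition leaves only its far tail in the 78.5-80.5 window;
  # oracle: the analytic logistic derivative evaluated on the actual grid
  # (first window point 78.6 degC -> tail ~ 8% of the peak height at w = 0.8)
  lo <- negative_derivative(logistic_melt(tm = 75.5, w = 0.8, A = 1))
  own_peak <- max(lo$neg_dfdt)
  g <- function(T) exp((T - 75.5) / 0.8) /
    (0.8 * (1 + exp((T - 75.5) / 0.8))^2)
  grid <- melt_grid()
  expected_ratio <- max(g(grid[grid >= 78.5 & grid <= 80.5])) / max(g(grid))
  expect_lt(peak_intensity(lo, assay), 0.1 * own_peak)
  expect_equal(peak_intensity(lo, assay) / own_peak, expected_ratio,
               tolerance = 0.03)
  # window outside the grid errors
  short <- melt_curve("W", "S", seq(45, 70, 0.2), rep(1, 126))
  expect_error(peak_intensity(negative_derivative(short), assay),
               "outside the temperature grid")
})

test_that("at-temperature readout mode reads the grid point nearest the scoring temp", {
  assay <- assay_definition("G12V")  # scoring_temp 79.5
  d <- negative_derivative(logistic_melt(tm = 80.0, w = 0.8, A = 1))
  at <- peak_intensity(d, assay, mode = "at_temp")
  expect_equal(at, d$neg_dfdt[which.min(abs(d$temperatures - 79.5))])
  expect_lte(at, peak_intensity(d, assay, mode = "window_max"))
})

test_that("two-control normalization maps the controls to 0 and 1", {
  expect_equal(normalize_score(8, 2, 8), 1.0)
  expect_equal(normalize_score(2, 2, 8), 0.0)
  expect_equal(normalize_score(5, 2, 8), 0.5)
  expect_gt(normalize_score(10, 2, 8), 1)   # over-unity not clipped
  expect_lt(normalize_score(1, 2, 8), 0)    # below-zero not clipped
  expect_error(normalize_score(5, 8, 2), "control failure")
  expect_error(normalize_score(5, 3, 3), "control failure")
})

test_that("classification is strictly above-threshold", {
  expect_equal(classify_call(0.51, 0.5), "MUT")
  expect_equal(classify_call(0.49, 0.5), "NEG")
  expect_equal(classify_call(0.50, 0.5), "NEG")  # tie goes negative
  expect_equal(classify_call(c(0.2, 0.8)), c("NEG", "MUT"))
  expect_error(classify_call(0.5, 0), "threshold")
})

test_that("score_run calls simulated genotypes and validates controls", {
  tr <- tiny_run("G12V", seed = 11)
  res <- score_run(tr$run$curves, tr$run$sheet, tr$assay)
  sc <- res$scores
  expect_equal(sc$call[sc$sample_id == "MUT1"], "MUT")
  expect_equal(sc$call[sc$sample_id == "WT1"], "NEG")
  expect_equal(sc$n_replicates[sc$sample_id == "MUT1"], 4L)
  # controls score themselves: replicate means of 1 and 0 by construction
  expect_equal(sc$mean_score[sc$role == "mut_control"], 1.0)
  expect_equal(sc$mean_score[sc$role == "wt_control"], 0.0)
  expect_equal(sc$qc_flags, rep("", nrow(sc)))  # clean NTCs
  # mean_score is the mean of replicate scores
  reps <- res$replicates
  expect_equal(sc$mean_score[sc$sample_id == "MUT1"],
               mean(reps$score[reps$sample_id == "MUT1"]))
})

test_that("a run without its controls is invalid", {
  tr <- tiny_run("G12V", seed = 3)
  sheet <- tr$run$sheet
  no_mut <- sheet[sheet$role != "mut_control", ]
  expect_error(score_run(tr$run$curves, no_mut, tr$assay), "mut_control")
  no_wt <- sheet[sheet$role != "wt_control", ]
  expect_error(score_run(tr$run$curves, no_wt, tr$assay), "wt_control")
})

test_that("swapped control roles trigger the control-failure error", {
  tr <- tiny_run("G12V", seed = 9)
  sheet <- tr$run$sheet
  sheet$role[sheet$role == "wt_control"] <- "swap"
  sheet$role[sheet$role == "mut_control"] <- "wt_control"
  sheet$role[sheet$role == "swap"] <- "mut_control"
  expect_error(score_run(tr$run$curves, sheet, tr$assay), "control failure")
})

test_that("normalized scores and calls are invariant to fluorescence scale", {
  tr <- tiny_run("G12V", seed = 21)
  res <- score_run(tr$run$curves, tr$run$sheet, tr$assay)
  for (k in c(0.05, 3, 1e4)) {
    scaled <- lapply(tr$run$curves, function(cu)
      melt_curve(cu$well_id, cu$sample_id, cu$temperatures,
                 k * cu$fluorescence))
    res_k <- score_run(scaled, tr$run$sheet, tr$assay)
    expect_equal(res_k$scores$mean_score, res$scores$mean_score)
    expect_equal(res_k$scores$call, res$scores$call)
  }
})

test_that("re-scoring the same quadruplicate run is bit-identical", {
  tr <- tiny_run("G12D", seed = 33)
  r1 <- score_run(tr$run$curves, tr$run$sheet, tr$assay)
  r2 <- score_run(tr$run$curves, tr$run$sheet, tr$assay)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$replicates, r2$replicates)
})

test_that("contaminated NTC wells raise a QC flag", {
  tr <- tiny_run("G12V", seed = 4)
  curves <- tr$run$curves
  mut_well <- tr$run$sheet$well_id[tr$run$sheet$role == "mut_control"][1]
  for (w in tr$run$sheet$well_id[tr$run$sheet$role == "ntc"])
    curves[[w]] <- melt_curve(w, "ntc", curves[[mut_well]]$temperatures,
                              curves[[mut_well]]$fluorescence)
  res <- score_run(curves, tr$run$sheet, tr$assay)
  expect_true(all(res$scores$qc_flags == "NTC_SIGNAL"))
})
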