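test_that("amplification follows capped geometric growth", {
  expect_equal(amplify(1, 1, 10, Inf), 1024)       # perfect doubling, 2^10
  expect_equal(amplify(50, 0, 35, 1e9), 50)        # zero efficiency
  # plateau approach: iterate the recurrence independently
  n <- 10
  for (i in 1:35) n <- n + 0.9 * n * (1 - n / 1e9)
  expect_equal(amplify(10, 0.9, 35, 1e9), n)
  expect_gt(amplify(10, 0.9, 35, 1e9), 0.99e9)     # within 1% of plateau
  # monotone in starting copies
  cfg <- simulation_config("G12V")
  n0 <- c(10, 50, 250, 1000)
  out <- vapply(n0, amplify, numeric(1), efficiency = 0.9, cycles = 35,
                plateau = cfg$plateau)
  expect_true(all(diff(out) > 0))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config("G12V", eff_matched = 0.3,
                                 eff_mismatched = 0.5), "efficiencies")
  expect_error(simulation_config("G12V", cycles = 0), "cycles")
  expect_error(simulation_config("G12V", noise_sd = -0.1), "noise_sd")
  expect_error(amplicon_species(79.5, 0.8, 0.7), "sum to 1")
  expect_error(amplicon_species(79.5, 0, 1), "width")
})

test_that("rendered curves produce the programmed melting peak", {
  cfg <- simulation_config("G12V", noise_sd = 0)
  sp <- amplicon_species(79.5, 0.8, 1)
  cu <- render_melt_curve(sp, 1e12, cfg)
  d <- negative_derivative(cu)
  tmax <- d$temperatures[which.max(d$neg_dfdt)]
  expect_gte(tmax, 79.4); expect_lte(tmax, 79.6)
  # zero product: baseline-only curve with ~zero scoring intensity
  base <- render_melt_curve(amplicon_species(numeric(0), numeric(0),
                                             numeric(0)), 0, cfg)
  pi0 <- peak_intensity(negative_derivative(base), assay_definition("G12V"))
  expect_lt(pi0, 0.01)
  # linearity: doubling product doubles the derivative peak (flat baseline)
  cfg0 <- simulation_config("G12V", noise_sd = 0, baseline_slope = 0)
  p1 <- max(negative_derivative(render_melt_curve(sp, 5e11, cfg0))$neg_dfdt)
  p2 <- max(negative_derivative(render_melt_curve(sp, 1e12, cfg0))$neg_dfdt)
  expect_equal(p2 / p1, 2, tolerance = 1e-9)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config("G12D", seed = 123)
  a <- simulate_sample("wt/G12D", assay_definition("G12D"), cfg)
  b <- simulate_sample("wt/G12D", assay_definition("G12D"), cfg)
  expect_identical(a, b)
  co1 <- simulate_cohort(data.frame(sample_id = "S1", genotype = "wt/G12V"),
                         config = simulation_config("G12V", seed = 5))
  co2 <- simulate_cohort(data.frame(sample_id = "S1", genotype = "wt/G12V"),
                         config = simulation_config("G12V", seed = 5))
  expect_identical(co1, co2)
})

test_that("mutant controls outshine wild-type controls in their own assay", {
  for (aid in c("G12V", "G12D")) {
    assay <- assay_definition(aid)
    cfg <- simulation_config(aid, seed = 8)
    run <- simulate_run(data.frame(sample_id = "S", genotype = "wt/wt"),
                        assay, cfg)
    res <- score_run(run$curves, run$sheet, assay)
    expect_gt(res$controls$f_pos, res$controls$f_neg)
  }
})

test_that("the G12D by-product peak at 75.5 degC appears regardless of genotype", {
  cfg <- simulation_config("G12D", noise_sd = 0, n_replicates = 1)
  for (gt in c("wt/wt", "wt/G12D")) {
    cu <- simulate_sample(gt, assay_definition("G12D"), cfg)[[1]]
    pk <- detect_peaks(negative_derivative(smooth_curve(cu)), c(74, 77),
                       min_prominence_frac = 0.01)
    expect_gte(nrow(pk), 1L)
    expect_lt(abs(pk$tm[1] - 75.5), 0.3)
  }
  # ... but not in the G12V assay
  cu <- simulate_sample("wt/wt", assay_definition("G12V"),
                        simulation_config("G12V", noise_sd = 0,
                                          n_replicates = 1))[[1]]
  pk <- detect_peaks(negative_derivative(smooth_curve(cu)), c(74, 77),
                     min_prominence_frac = 0.01)
  expect_equal(nrow(pk), 0L)
})

test_that("mean score rises strictly with mutant fraction", {
  assay <- assay_definition("G12V")
  cfg <- simulation_config("G12V", seed = 7)
  fr <- c(0, 0.05, 0.25, 0.5, 1.0)
  run <- simulate_run(data.frame(sample_id = paste0("S", seq_along(fr)),
                                 genotype = "wt/G12V",
                                 mutant_fraction = fr),
                      assay, cfg)
  sc <- score_run(run$curves, run$sheet, assay)$scores
  sc <- sc[sc$role == "sample", ]
  sc <- sc[order(match(sc$sample_id, paste0("S", seq_along(fr)))), ]
  expect_true(all(diff(sc$mean_score) > 0))
  expect_equal(sc$call, c("NEG", "NEG", "MUT", "MUT", "MUT"))
})

test_that("non-target G12R templates score negative in both assays", {
  for (aid in c("G12V", "G12D")) {
    assay <- assay_definition(aid)
    cfg <- simulation_config(aid, seed = 15)
    run <- simulate_run(data.frame(sample_id = "R1", genotype = "wt/G12R"),
                        assay, cfg)
    sc <- score_run(run$curves, run$sheet, assay)$scores
    expect_equal(sc$call[sc$sample_id == "R1"], "NEG")
  }
})

test_that("genotypes derived from the call table follow the ARMS-first rule", {
  tum <- load_call_table("tumor")
  gt <- genotypes_from_calls(tum)
  expect_equal(gt[tum$patient_id == 1], "wt/G12V")
  expect_equal(gt[tum$patient_id == 2], "wt/G12D")
  expect_equal(gt[tum$patient_id == 4], "wt/wt")
  expect_equal(gt[tum$patient_id == 9], "wt/G12V")   # ARMS missing, SS het
  expect_equal(gt[tum$patient_id == 15], "wt/G12R")
})

test_that("a simulated tumor cohort recovers every programmed call", {
  tum <- load_call_table("tumor")
  co <- simulate_cohort(tum, config = simulation_config("G12V", seed = 1))
  expect_equal(nrow(co$truth), 30L)
  for (aid in c("G12V", "G12D")) {
    res <- score_run(co$runs[[aid]]$curves, co$runs[[aid]]$sheet,
                     assay_definition(aid))
    sc <- res$scores[res$scores$role == "sample", ]
    calls <- sc$call[match(co$truth$sample_id, sc$sample_id)]
    expected <- co$truth[[paste0("expected_", tolower(aid))]]
    expect_equal(calls, expected)
  }
})

test_that("an all-wild-type cohort is uniformly negative", {
  truth <- data.frame(sample_id = paste0("S", 1:5), genotype = "wt/G12V",
                      mutant_fraction = 0)
  co <- simulate_cohort(truth, config = simulation_config("G12V", seed = 2))
  sc <- score_run(co$runs$G12V$curves, co$runs$G12V$sheet,
                  assay_definition("G12V"))$scores
  expect_true(all(sc$call[sc$role == "sample"] == "NEG"))
})

test_that("genotype strings are validated", {
  cfg <- simulation_config("G12V")
  expect_error(simulate_sample("wt/G13D", assay_definition("G12V"), cfg),
               "unknown allele")
  expect_error(simulate_sample("wt", assay_definition("G12V"), cfg),
               "two alleles")
  expect_error(simulate_sample("wt/G12V", assay_definition("G12V"), cfg,
                               mutant_fraction = 1.5), "mutant_fraction")
})
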