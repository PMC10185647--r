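# Shared fixtures: analytic melt curves and an independent Mann-Whitney
# oracle, built in code at test time.

# Falling two-state melting sigmoid F(T) = A / (1 + exp((T - tm) / w)).
logistic_melt <- function(grid = melt_grid(), tm = 79.5, w = 0.8, A = 1,
                          well = "W1", sample = "S1") {
  melt_curve(well, sample, grid, A / (1 + exp((grid - tm) / w)))
}

# Mixture of two transitions with amplitudes A1, A2.
two_peak_melt <- function(grid = melt_grid(), tm1 = 75.5, tm2 = 79.5,
                          w = 0.8, A1 = 1, A2 = 1,
                          well = "W1", sample = "S1") {
  f <- A1 / (1 + exp((grid - tm1) / w)) + A2 / (1 + exp((grid - tm2) / w))
  melt_curve(well, sample, grid, f)
}

# Brute-force Mann-Whitney oracle, independent of the package code path:
# U by direct pair counting, exact two-sided p by enumerating every
# assignment of the pooled values to group A.
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  u_obs <- oracle_u(a, b)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small simulated plate: one het mutant, one wild type, controls + NTC.
tiny_run <- function(assay_id = "G12V", seed = 11, ...) {
  assay <- assay_definition(assay_id)
  cfg <- simulation_config(assay_id, seed = seed, ...)
  samples <- data.frame(sample_id = c("MUT1", "WT1"),
                        genotype = c("wt/MUT", "wt/wt"),
                        stringsAsFactors = FALSE)
  list(run = simulate_run(samples, assay, cfg), assay = assay, config = cfg)
}
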