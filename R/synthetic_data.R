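#' Simulation configuration for ARMS-HRMA melt-curve runs
#'
#' Bundles the parameters of the generative model: allele-specific PCR
#' amplification (logistic-capped geometric growth with matched vs
#' 3'-mismatched per-cycle efficiencies), two-state melting transitions at
#' the assay's characteristic temperatures, a linear fluorescence baseline,
#' multiplicative Gaussian noise, and the replicate structure of a plate.
#'
#' Melting temperatures are per assay: the G12V-specific product melts at
#' 80.0 degC, the G12D-specific product at 79.5 degC, the wild-type assay
#' product at 78.5 degC; the G12D assay additionally produces a
#' genotype-independent by-product melting at 75.5 degC.
#'
#' The two-phase thermal cycling of the wet assay (10 low-stringency + 25
#' high-stringency cycles) is collapsed into one effective per-cycle
#' efficiency per allele: `eff_matched` when the forward primer's 3' base
#' matches the template allele, `eff_mismatched` for the residual
#' amplification of any other allele.
#'
#' @param assay_id `"G12V"`, `"G12D"` or `"WT"`.
#' @param ramp Temperature grid (degC); default [melt_grid()] =
#'   45--95 degC at 0.2 degC steps.
#' @param cycles Effective PCR cycles (default 35 = 10 + 25).
#' @param eff_matched,eff_mismatched Per-cycle amplification efficiencies in
#'   (0, 1] for matched and 3'-mismatched templates (defaults 0.9 / 0.35;
#'   must satisfy `0 < eff_mismatched < eff_matched <= 1`).
#' @param template_copies Total genomic template copies per reaction
#'   (default 1000, about 4 ng of genomic DNA); split across alleles by
#'   genotype fraction.
#' @param plateau Product ceiling in copies (default 1e12).
#' @param tm_specific Melting temperature of the assay-specific product,
#'   degC; default per assay as above.
#' @param tm_nonspecific Melting temperature of the genotype-independent
#'   by-product (G12D assay only), degC; default 75.5.
#' @param nonspecific_product Copies of the by-product, independent of
#'   template (default 6e11, large enough that the 75.5 degC peak stays a
#'   distinct peak — not a shoulder — next to a full-strength specific
#'   transition 4 degC away).
#' @param transition_width Melting-transition steepness `w` in degC
#'   (default 0.8); the derivative peak height of a transition of amplitude
#'   `A` is `A / (4 w)`.
#' @param fluor_scale Fluorescence per product copy (a.u.; default 3.2e-12,
#'   anchoring the mutant-control derivative peak near 1 a.u./degC — an
#'   arbitrary anchor, since scoring is scale-invariant).
#' @param baseline_intercept,baseline_slope Linear fluorescence baseline:
#'   `baseline_intercept + baseline_slope * (T - min(ramp))` (defaults 0.2
#'   a.u. and -0.002 a.u./degC).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   curve's amplitude (default 0.02).
#' @param n_replicates Replicate wells per sample (default 4).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(assay_id = c("G12V", "G12D", "WT"),
                              ramp = melt_grid(),
                              cycles = 35L,
                              eff_matched = 0.9,
                              eff_mismatched = 0.35,
                              template_copies = 1000,
                              plateau = 1e12,
                              tm_specific = NULL,
                              tm_nonspecific = 75.5,
                              nonspecific_product = 6e11,
                              transition_width = 0.8,
                              fluor_scale = 3.2e-12,
                              baseline_intercept = 0.2,
                              baseline_slope = -0.002,
                              noise_sd = 0.02,
                              n_replicates = 4L,
                              seed = NULL) {
  assay_id <- match.arg(assay_id)
  if (is.null(tm_specific))
    tm_specific <- c(G12V = 80.0, G12D = 79.5, WT = 78.5)[[assay_id]]
  if (!(eff_mismatched > 0 && eff_mismatched < eff_matched && eff_matched <= 1))
    stop("efficiencies must satisfy 0 < eff_mismatched < eff_matched <= 1")
  if (cycles < 1L) stop("cycles must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (transition_width <= 0) stop("transition_width must be > 0")
  if (any(diff(ramp) <= 0)) stop("ramp must be strictly increasing")
  structure(
    list(assay_id = assay_id, ramp = ramp, cycles = as.integer(cycles),
         eff_matched = eff_matched, eff_mismatched = eff_mismatched,
         template_copies = template_copies, plateau = plateau,
         tm_specific = tm_specific, tm_nonspecific = tm_nonspecific,
         nonspecific_product = nonspecific_product,
         transition_width = transition_width, fluor_scale = fluor_scale,
         baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         seed = seed),
    class = "simulation_config")
}

#' PCR amplification with a product plateau
#'
#' Logistic-capped geometric growth: each cycle,
#' `n <- n + efficiency * n * (1 - n / plateau)`.  With `plateau = Inf`
#' this is pure geometric growth `n0 * (1 + efficiency)^cycles`; with a
#' finite plateau the product saturates toward the ceiling, so templates
#' that differ several-fold in starting copies end up compressed but still
#' ordered — the regime that makes control-normalized scoring meaningful.
#'
#' @param n0 Starting copies (>= 0).
#' @param efficiency Per-cycle efficiency in `[0, 1]`.
#' @param cycles Number of cycles.
#' @param plateau Product ceiling (copies), possibly `Inf`.
#' @return Final copy number.
#' @export
#' @examples
#' amplify(1, 1, 10, Inf)  # 2^10 = 1024
amplify <- function(n0, efficiency, cycles, plateau = Inf) {
  stopifnot(n0 >= 0, efficiency >= 0, cycles >= 0)
  n <- n0
  if (is.finite(plateau)) {
    for (i in seq_len(cycles)) n <- n + efficiency * n * (1 - n / plateau)
  } else {
    n <- n * (1 + efficiency)^cycles
  }
  n
}

#' Amplicon species table
#'
#' One row per melting species: melting temperature `tm` (degC), transition
#' steepness `width` (degC) and `weight` (fraction of total product; must
#' sum to 1).
#'
#' @param tm,width,weight Numeric vectors of equal length.
#' @return A validated data.frame.
#' @export
amplicon_species <- function(tm, width, weight) {
  stopifnot(length(tm) == length(width), length(tm) == length(weight),
            all(width > 0))
  if (length(weight) && abs(sum(weight) - 1) > 1e-8)
    stop("species weights must sum to 1")
  data.frame(tm = tm, width = width, weight = weight)
}

#' Render a melt curve from amplicon species
#'
#' Two-state melting model: each species contributes a falling sigmoid
#' `weight / (1 + exp((T - tm) / width))`, scaled by
#' `fluor_scale * total_product`, on top of the linear baseline, plus
#' Gaussian noise with standard deviation `noise_sd` times the curve's
#' amplitude.  Deterministic given the RNG state (set `config$seed`
#' upstream, e.g. via [simulate_run()]).
#'
#' @param species A data.frame from [amplicon_species()] (zero rows allowed:
#'   baseline-only curve).
#' @param total_product Total product copies.
#' @param config A [simulation_config()].
#' @param well_id,sample_id Identifiers for the resulting curve.
#' @return A [melt_curve].
#' @export
render_melt_curve <- function(species, total_product, config,
                              well_id = "sim", sample_id = "sim") {
  stopifnot(inherits(config, "simulation_config"), total_product >= 0)
  tt <- config$ramp
  amplitude <- config$fluor_scale * total_product
  sig <- numeric(length(tt))
  for (i in seq_len(nrow(species)))
    sig <- sig + species$weight[i] / (1 + exp((tt - species$tm[i]) / species$width[i]))
  baseline <- config$baseline_intercept + config$baseline_slope * (tt - tt[1L])
  ff <- amplitude * sig + baseline
  if (config$noise_sd > 0 && amplitude > 0)
    ff <- ff + stats::rnorm(length(tt), sd = config$noise_sd * amplitude)
  melt_curve(well_id, sample_id, tt, ff)
}

known_alleles <- c("wt", "G12V", "G12D", "G12R")

#' Parse a genotype string into allele fractions
#' @noRd
genotype_fractions <- function(genotype, assay, mutant_fraction = NULL) {
  alleles <- strsplit(genotype, "/", fixed = TRUE)[[1L]]
  alleles[alleles == "MUT"] <- assay$target_allele
  bad <- setdiff(alleles, known_alleles)
  if (length(bad))
    stop("unknown allele(s) in genotype '", genotype, "': ",
         paste(bad, collapse = ", "))
  if (length(alleles) != 2L)
    stop("genotype must name two alleles, e.g. 'wt/G12V'")
  frac <- c(0.5, 0.5)
  if (!is.null(mutant_fraction)) {
    if (mutant_fraction < 0 || mutant_fraction > 1)
      stop("mutant_fraction must be in [0, 1]")
    non_wt <- alleles != "wt"
    if (sum(non_wt) == 1L) {
      frac[non_wt] <- mutant_fraction
      frac[!non_wt] <- 1 - mutant_fraction
    } else if (all(alleles == "wt")) {
      # wt/wt with an override is still all wild type
    } else {
      stop("mutant_fraction override requires a wt/<variant> genotype")
    }
  }
  agg <- tapply(frac, alleles, sum)
  data.frame(allele = names(agg), fraction = as.numeric(agg),
             row.names = NULL)
}

#' Simulate one sample's replicate melt curves
#'
#' Each allele's template share is amplified with the matched efficiency if
#' the allele is the assay's target (perfect 3' primer match) and the
#' mismatched efficiency otherwise — so non-target codon-12 variants such as
#' G12R behave like wild type under the G12V and G12D assays.  All templates
#' yield the same amplicon (the discriminating base sits inside the primer),
#' so amplified product pools into one melting species at the assay's
#' specific Tm; under the G12D assay a genotype-independent by-product
#' species at 75.5 degC is added (also present in template-free wells).
#' Each replicate is rendered with independent noise.
#'
#' @param genotype Genotype string: two `/`-separated alleles from
#'   `wt`, `G12V`, `G12D`, `G12R`; `MUT` is shorthand for the assay's
#'   target allele (e.g. `"wt/MUT"`).
#' @param assay An [assay_definition()].
#' @param config A [simulation_config()] (its `seed`, if non-`NULL`, is set
#'   before rendering).
#' @param mutant_fraction Optional override in `[0, 1]` of the non-wt
#'   allele's template share, for circulating-tumor-DNA-like mixtures where
#'   the mutant fraction can be far below the heterozygous 50%.
#' @param sample_id,well_prefix Identifiers; replicate wells are named
#'   `<well_prefix>_r1`, `_r2`, ...
#' @return List of `config$n_replicates` [melt_curve] objects.
#' @export
simulate_sample <- function(genotype, assay, config, mutant_fraction = NULL,
                            sample_id = genotype, well_prefix = sample_id) {
  stopifnot(inherits(assay, "assay_definition"),
            inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fr <- genotype_fractions(genotype, assay, mutant_fraction)
  amplified <- sum(vapply(seq_len(nrow(fr)), function(i) {
    eff <- if (fr$allele[i] == assay$target_allele) config$eff_matched
           else config$eff_mismatched
    amplify(fr$fraction[i] * config$template_copies, eff, config$cycles,
            config$plateau)
  }, numeric(1)))
  build_replicates(amplified, config, sample_id, well_prefix)
}

#' Assemble species table and render replicate curves
#' @noRd
build_replicates <- function(specific_product, config, sample_id,
                             well_prefix) {
  nonspec <- if (config$assay_id == "G12D") config$nonspecific_product else 0
  total <- specific_product + nonspec
  species <- if (total > 0) {
    amplicon_species(
      tm = c(config$tm_specific, if (nonspec > 0) config$tm_nonspecific),
      width = rep(config$transition_width, 1 + (nonspec > 0)),
      weight = c(specific_product, if (nonspec > 0) nonspec) / total)
  } else {
    amplicon_species(numeric(0), numeric(0), numeric(0))
  }
  lapply(seq_len(config$n_replicates), function(r)
    render_melt_curve(species, total, config,
                      well_id = paste0(well_prefix, "_r", r),
                      sample_id = sample_id))
}

#' Cell-line control genotypes per assay
#'
#' Mirrors the wet assay's plate controls: SW48 (wt/wt) as the negative
#' control for both mutation assays; SW480 (G12V homozygous) as the G12V
#' positive control; LS174T (wt/G12D heterozygous) as the G12D positive
#' control.  For the wild-type-allele assay the roles invert: SW48 carries
#' the matched (wt) allele and SW480 carries none.
#'
#' @param assay_id `"G12V"`, `"G12D"` or `"WT"`.
#' @return Named list with `wt_control` and `mut_control` genotype strings.
#' @export
control_genotypes <- function(assay_id = c("G12V", "G12D", "WT")) {
  assay_id <- match.arg(assay_id)
  switch(assay_id,
         G12V = list(wt_control = "wt/wt", mut_control = "G12V/G12V"),
         G12D = list(wt_control = "wt/wt", mut_control = "wt/G12D"),
         WT = list(wt_control = "G12V/G12V", mut_control = "wt/wt"))
}

#' Simulate a full plate run for one assay
#'
#' Builds replicate wells for every requested sample plus the assay's
#' wild-type control, mutant control and non-template controls, together
#' with the matching sample sheet, ready for [score_run()].
#'
#' @param samples A data.frame with columns `sample_id`, `genotype` and
#'   optionally `mutant_fraction` (`NA` = no override).
#' @param assay An [assay_definition()].
#' @param config A [simulation_config()]; its seed (if non-`NULL`) is set
#'   once at the start, making the whole run deterministic.
#' @param n_ntc Number of non-template-control wells (default 2).
#' @return A list with `curves` (named list of [melt_curve]) and `sheet`
#'   (a `sample_sheet`).
#' @export
simulate_run <- function(samples, assay, config, n_ntc = 2L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "genotype") %in% names(samples)))
  if (!is.null(config$seed)) set.seed(config$seed)
  config$seed <- NULL  # draw everything from the one stream set above
  ctl <- control_genotypes(assay$assay_id)

  curves <- list()
  sheet_rows <- list()
  add <- function(reps, sample_id, role) {
    for (cu in reps) curves[[cu$well_id]] <<- cu
    sheet_rows[[length(sheet_rows) + 1L]] <<- data.frame(
      well_id = vapply(reps, `[[`, "", "well_id"),
      sample_id = sample_id, role = role, assay_id = assay$assay_id,
      replicate_index = seq_along(reps), stringsAsFactors = FALSE)
  }

  add(simulate_sample(ctl$wt_control, assay, config,
                      sample_id = "wt_control",
                      well_prefix = paste0(assay$assay_id, "_wtc")),
      "wt_control", "wt_control")
  add(simulate_sample(ctl$mut_control, assay, config,
                      sample_id = "mut_control",
                      well_prefix = paste0(assay$assay_id, "_mutc")),
      "mut_control", "mut_control")
  if (n_ntc > 0L) {
    ntc_cfg <- config
    ntc_cfg$n_replicates <- as.integer(n_ntc)
    add(build_replicates(0, ntc_cfg, "ntc",
                         paste0(assay$assay_id, "_ntc")),
        "ntc", "ntc")
  }
  for (i in seq_len(nrow(samples))) {
    mf <- if ("mutant_fraction" %in% names(samples) &&
              !is.na(samples$mutant_fraction[i])) samples$mutant_fraction[i]
    add(simulate_sample(samples$genotype[i], assay, config,
                        mutant_fraction = mf,
                        sample_id = samples$sample_id[i],
                        well_prefix = paste0(assay$assay_id, "_",
                                             samples$sample_id[i])),
        samples$sample_id[i], "sample")
  }
  sheet <- validate_sample_sheet(do.call(rbind, sheet_rows))
  list(curves = curves, sheet = sheet)
}

#' Derive a per-patient genotype from a call-table row
#'
#' Ground-truth assignment used when simulating a cohort from a published
#' call table: an ARMS G12V call gives `wt/G12V`, an ARMS G12D call gives
#' `wt/G12D`; where both ARMS assays are negative or missing, a Sanger or
#' ddPCR G12R call gives `wt/G12R`, a Sanger heterozygous call gives the
#' corresponding `wt/<variant>`, and otherwise the genotype is `wt/wt`.
#'
#' @param table A `call_table`.
#' @return Character vector of genotype strings, one per row.
#' @export
genotypes_from_calls <- function(table) {
  table <- validate_call_table(as.data.frame(table))
  vapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (!is.na(r$arms_g12v) && r$arms_g12v == "G12V") return("wt/G12V")
    if (!is.na(r$arms_g12d) && r$arms_g12d == "G12D") return("wt/G12D")
    if (!is.na(r$ss) && r$ss == "wt_G12V") return("wt/G12V")
    if (!is.na(r$ss) && r$ss == "wt_G12D") return("wt/G12D")
    if ((!is.na(r$ss) && r$ss == "wt_G12R") ||
        (!is.na(r$ddpcr) && r$ddpcr == "G12R")) return("wt/G12R")
    "wt/wt"
  }, character(1))
}

#' Simulate a two-assay cohort with known ground truth
#'
#' Generates one G12V run and one G12D run for a cohort of patients, each
#' run carrying cell-line-style controls, non-template controls and
#' `n_replicates` wells per patient, and returns the programmed ground
#' truth so call recovery can be checked.
#'
#' @param truth Either a `call_table` (genotypes derived via
#'   [genotypes_from_calls()]) or a data.frame with columns `sample_id` and
#'   `genotype` (optional `mutant_fraction`).
#' @param config A [simulation_config()]; its `assay_id` is overridden per
#'   run, and its `seed` (if non-`NULL`) seeds the whole cohort.
#' @return A list with `runs` (named list `G12V`/`G12D`, each a
#'   `list(curves, sheet)`) and `truth` (data.frame with `sample_id`,
#'   `genotype`, and expected calls `expected_g12v`, `expected_g12d`).
#' @export
simulate_cohort <- function(truth, config = simulation_config("G12V")) {
  if (inherits(truth, "call_table") ||
      all(c("patient_id", "arms_g12v") %in% names(truth))) {
    truth <- data.frame(
      sample_id = paste0("P", truth$patient_id),
      genotype = genotypes_from_calls(truth),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "genotype") %in% names(truth)))
  truth$expected_g12v <- ifelse(grepl("G12V", truth$genotype), "MUT", "NEG")
  truth$expected_g12d <- ifelse(grepl("G12D", truth$genotype), "MUT", "NEG")
  if (!is.null(config$seed)) set.seed(config$seed)
  config$seed <- NULL
  runs <- lapply(c(G12V = "G12V", G12D = "G12D"), function(aid) {
    cfg <- config
    cfg$assay_id <- aid
    cfg$tm_specific <- c(G12V = 80.0, G12D = 79.5)[[aid]]
    simulate_run(truth[, c("sample_id", "genotype",
                           intersect("mutant_fraction", names(truth)))],
                 assay_definition(aid), cfg)
  })
  list(runs = runs, truth = truth)
}
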