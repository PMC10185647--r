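#!/usr/bin/env Rscript
# Simulate an ARMS-HRMA cohort matching the 30-patient tumor call table:
# one G12V plate and one G12D plate, each with SW48-style wt controls,
# SW480/LS174T-style mutant controls, non-template controls and four
# replicate wells per patient.  Writes the melt curves and sample sheets
# in the canonical wide-CSV dialect under results/sim/.

suppressPackageStartupMessages(library(armshrma))

seed <- 1L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tumor <- load_call_table("tumor")
message("Cohort truth from the tumor call table: ",
        sum(grepl("G12V", genotypes_from_calls(tumor))), " G12V carriers, ",
        sum(grepl("G12D", genotypes_from_calls(tumor))), " G12D carriers, ",
        sum(grepl("G12R", genotypes_from_calls(tumor))), " G12R carriers.")

co <- simulate_cohort(tumor, config = simulation_config("G12V", seed = seed))

for (aid in names(co$runs)) {
  run <- co$runs[[aid]]
  write_melt_run(run$curves, run$sheet,
                 file.path(out_dir, paste0("melt_", aid, ".csv")),
                 file.path(out_dir, paste0("sheet_", aid, ".csv")))
  message("Assay ", aid, ": wrote ", length(run$curves),
          " simulated wells (", nrow(run$sheet), " sheet entries).")
}
utils::write.csv(co$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
message("Ground truth written to ", file.path(out_dir, "truth.csv"),
        " (seed ", seed, ").")
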