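#!/usr/bin/env Rscript
# Cross-method comparison on the packaged tumor and plasma call tables:
# per-assay positive counts, ARMS-HRMA vs ddPCR and vs Sanger concordance
# (among co-assessed ARMS positives and symmetric over all co-assessed),
# discordant patient lists, and the supplementary sensitivity/specificity
# against ddPCR.  Writes results/concordance/.

suppressPackageStartupMessages(library(armshrma))

out_dir <- "results/concordance"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tumor <- load_call_table("tumor")
plasma <- load_call_table("plasma")

message("Tumor cohort (n = 30): ",
        count_calls(tumor, "tumor", "arms_g12v", "G12V"), " G12V and ",
        count_calls(tumor, "tumor", "arms_g12d", "G12D"),
        " G12D positives by ARMS-HRMA.")
message("Plasma cohort (n = 30): ",
        count_calls(plasma, "plasma", "arms_g12v", "G12V"), " G12V and ",
        count_calls(plasma, "plasma", "arms_g12d", "G12D"),
        " G12D positives by ARMS-HRMA; Sanger attempted in ",
        n_assessed(plasma, "plasma", "ss"), " plasmas, ",
        count_calls(plasma, "plasma", "ss", "UNREADABLE"),
        " of them unreadable.")

rep_t <- run_concordance(tumor, out_dir = file.path(out_dir, "tumor"))
rep_p <- run_concordance(plasma, out_dir = file.path(out_dir, "plasma"))

show <- rep_t[rep_t$scope == "positives_of_a", ]
for (i in seq_len(nrow(show)))
  message(sprintf("Tumor %s, ARMS vs %s: %.1f%% concordant among %d co-assessed ARMS positives%s",
                  show$assay_id[i], show$method_b[i], show$concordance_pct[i],
                  show$n_co_assessed[i],
                  ifelse(show$discordant_ids[i] == "", "",
                         paste0(" (discordant: ", show$discordant_ids[i], ")"))))

for (aid in c("G12V", "G12D")) {
  ss <- sensitivity_specificity(tumor, "tumor", aid)
  message(sprintf("Tumor %s vs ddPCR: sensitivity %.2f, specificity %.2f (n = %d co-assessed)",
                  aid, ss$sensitivity, ss$specificity, ss$n_co_assessed))
}
message("Full reports under ", out_dir, "/{tumor,plasma}/concordance.csv")
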