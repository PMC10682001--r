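#!/usr/bin/env Rscript
# Generate the synthetic SG pull-down study: matched G3BP1 (with the
# unstressed SG-ls condition) and CAPRIN1 TMT time courses with known
# class truth, written as plain TSV for the downstream steps.

library(sgdynamics)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config()  # 150 early / 100 late / 80 invariable, 3 reps
sim <- simulate_timecourse(cfg)

write_quant_table(sim$g3bp1, file.path(out, "g3bp1_quant.tsv"),
                  design_path = file.path(out, "g3bp1_design.tsv"))
write_quant_table(sim$caprin1, file.path(out, "caprin1_quant.tsv"),
                  design_path = file.path(out, "caprin1_design.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d proteins (%d early, %d late, %d invariable; %d ribosomal-like)\n",
  nrow(sim$truth), cfg$n_early, cfg$n_late, cfg$n_invariable,
  sum(sim$truth$is_ribosomal_like)))
cat(sprintf("G3BP1: %d samples (incl. SG-ls); CAPRIN1: %d samples\n",
            ncol(sim$g3bp1$values), ncol(sim$caprin1$values)))
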