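#!/usr/bin/env Rscript
# Stage 1: generate the synthetic FACS-sorted CRISPR screen used by the rest
# of the workflow. Default geometry: 2,000 genes x 4 guides + 1,000 NTC
# guides, three markers (MHCII, CD40, PD-L1) in duplicate, 15% sort gates,
# 10 planted shared positive regulators at -4 sigma. Everything downstream
# is reproducible from the seed written alongside the tables.

library(sortscreen)

seed <- 1
out <- file.path("results", "sim")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_screen(cfg)

write_result_table(
  data.frame(sgRNA = rownames(sim$screen$counts), sim$screen$counts,
             check.names = FALSE),
  file.path(out, "counts.tsv")
)
write_result_table(sim$screen$library, file.path(out, "library.tsv"))
write_result_table(as.data.frame(sim$screen$samples),
                   file.path(out, "samples.tsv"))
write_result_table(sim$truth$genes, file.path(out, "truth_genes.tsv"))
write_result_table(sim$truth$guides, file.path(out, "truth_guides.tsv"))
writeLines(c(paste("seed:", seed),
             paste("guides:", nrow(sim$screen$counts)),
             paste("samples:", ncol(sim$screen$counts))),
           file.path(out, "MANIFEST.txt"))

cat("Simulated", nrow(sim$screen$counts), "guides x",
    ncol(sim$screen$counts), "samples;",
    sum(sim$truth$genes$role != "null"), "planted regulators ->", out, "\n")
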