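#!/usr/bin/env Rscript
# Stage 2: depth normalization and guide-level QC. Median-of-ratios size
# factors remove sequencing-depth differences; per-guide high/low log2 fold
# changes are compared to the non-targeting-control null per gene.

library(sortscreen)

sim_dir <- file.path("results", "sim")
out <- file.path("results", "counts")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- read_guide_library(file.path(sim_dir, "library.tsv"))
sheet_df <- read.delim(file.path(sim_dir, "samples.tsv"))
sheet <- sample_sheet(sheet_df$sample_id, sheet_df$marker,
                      sheet_df$replicate, sheet_df$bin)
screen <- read_count_table(file.path(sim_dir, "counts.tsv"), lib, sheet)

screen <- median_normalize(screen)
write_result_table(
  data.frame(sample_id = names(screen$size_factors),
             size_factor = screen$size_factors),
  file.path(out, "size_factors.tsv")
)

lfc <- all_guide_lfc(screen, pseudocount = 1)
write_result_table(lfc, file.path(out, "guide_lfc.tsv"))

ntc <- ntc_compare(lfc)
write_result_table(ntc, file.path(out, "ntc_comparison.tsv"))

cat("Size factors span",
    paste(round(range(screen$size_factors), 3), collapse = "-"), "\n")
cat(sum(ntc$fdr < 0.05), "of", nrow(ntc),
    "genes deviate from the NTC null at FDR < 0.05\n")
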