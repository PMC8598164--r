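#!/usr/bin/env Rscript
# Stage 4: cross-screen integration. Per-condition betas are summed, z's
# Stouffer-combined, and each gene scored log10(p_sum) * beta_sum; genes
# are ranked in descending score order so shared positive regulators rise
# to the top. The most selected genes (5% most enriched or depleted per
# marker-aware screen) are k-means clustered (k = 8) on their per-screen
# beta vectors. Recovery of the planted regulators is evaluated last.

library(sortscreen)

out <- file.path("results", "integrate")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

blind <- read.delim(file.path("results", "mle", "blind.tsv"))
aware_low <- read.delim(file.path("results", "mle", "aware_low.tsv"))
truth <- list(genes = read.delim(file.path("results", "sim",
                                           "truth_genes.tsv")))

combined <- combine_screens(blind)
write_result_table(combined, file.path(out, "combined_ranking.tsv"))

clusters <- top_fraction_cluster(beta_matrix(aware_low),
                                 fraction = 0.05, k = 8, seed = 1)
write_result_table(clusters, file.path(out, "clusters.tsv"))

ev <- truth_eval(combined, truth, top_n = 20)
write_result_table(
  data.frame(metric = c("top20_recall", "n_regulators",
                        "ntc_pseudo_in_top20"),
             value = c(ev$recall, ev$n_regulators, ev$ntc_pseudo_in_top)),
  file.path(out, "recovery.tsv")
)

cat("Top of the combined ranking:\n")
print(head(combined[, c("gene", "beta_sum", "z_sum", "p_sum",
                        "gene_score", "rank")], 10), row.names = FALSE)
cat(sprintf("Recall of planted regulators in the top 20: %.2f\n", ev$recall))
cat("Cluster sizes:", paste(table(clusters$cluster), collapse = " "), "\n")
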