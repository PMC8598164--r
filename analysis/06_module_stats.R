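#!/usr/bin/env Rscript
# Stage 6: complex-level statistics.
# (a) Binomial depletion tests: for each gene (and for a pooled module) how
#     many guides fall below the library-wide null median of the high/low
#     fold change, against Binom(n, 0.5).
# (b) Stability-vs-selection correlation: a synthetic subunit-KO proteomics
#     matrix (stand-in for the published dataset) is scored per knockout as
#     the sum of module-member median log2 ratios minus the KO's own term;
#     the scores are correlated with the combined screen beta of the same
#     genes, excluding one essential-like subunit whose surviving guides
#     spared function.

library(sortscreen)

out <- file.path("results", "module_stats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lfc <- read.delim(file.path("results", "counts", "guide_lfc.tsv"))
truth <- read.delim(file.path("results", "sim", "truth_genes.tsv"))
planted <- truth$gene[truth$role != "null"]

# (a) binomial tests, planted regulators pooled as one module
one_rep <- lfc[lfc$marker == "MHCII" & lfc$replicate == 1, ]
bin <- module_binomial(one_rep, modules = list(planted_regulators = planted),
                       direction = "depleted")
write_result_table(bin, file.path(out, "binomial_tests.tsv"))
mod_row <- bin[bin$level == "module", ]
cat(sprintf("Module test: %d/%d planted-regulator guides below the null median, p = %.3g\n",
            mod_row$x, mod_row$n, mod_row$p))

# (b) stability score vs beta on a dedicated synthetic subunit screen
subunits <- sprintf("gene_%05d", 1:28)   # first 28 simulated genes
module_members <- subunits[1:9]
essential_like <- subunits[28]

prot <- simulate_subunit_proteomics(subunits, module_members, seed = 2)
# knockout requirement in the screen tracks destabilization strength;
# the essential-like subunit keeps function (no screen effect)
deltas <- -4 * prot$strength
deltas[essential_like] <- 0
sim <- simulate_screen(sim_config(n_genes = 300, n_ntc = 500,
                                  n_positive = 0,
                                  custom_deltas = unname(deltas), seed = 3))
sc <- median_normalize(sim$screen)
fit <- fit_all(sc, design_marker_blind(sc$samples), seed = 1)
combined <- combine_screens(fit)

scores <- n_module_scores(prot$log2_ratios, module_members)
betas <- setNames(combined$beta_sum, combined$gene)
corr <- stability_beta_correlation(scores, betas, exclude = essential_like)
print(corr)

write_result_table(scores, file.path(out, "stability_scores.tsv"))
write_result_table(
  data.frame(r = corr$r, ci_low = corr$conf_int[1],
             ci_high = corr$conf_int[2], p = corr$p, n = corr$n,
             excluded = paste(corr$excluded, collapse = ",")),
  file.path(out, "stability_beta_correlation.tsv")
)
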