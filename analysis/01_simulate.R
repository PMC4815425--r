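#!/usr/bin/env Rscript

# Stage 1: generate the default synthetic multi-study collection.
#
# The roster mirrors a realistic set of ten ATH1 water-stress contrasts:
# two root studies, one seedling study stressed with PEG, one deracination
# study, the rest shoot tissue under water withholding or mannitol, with
# 2-3 biological replicates per arm. Ground truth (per-gene mean effects,
# between-study heterogeneity tau2 = 0.05, 80% null genes, per-study batch
# shifts) is written alongside the expression matrix and sample sheet so
# every later stage can be checked against it.

suppressPackageStartupMessages(library(metaexpr))

dir.create("results", showWarnings = FALSE)

params <- sim_params(n_genes = 2000, seed = 20260919L)
sim <- simulate_collection(params)

m <- sim$study$matrix
expr_out <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
write_results(expr_out, "results/expression_matrix.tsv")
write_results(sim$study$samples, "results/sample_sheet.tsv")
write_results(sim$truth$genes, "results/truth_genes.tsv")

message(sprintf("collection: %d genes x %d samples across %d studies",
                nrow(m), ncol(m), nrow(params$studies)))
message(sprintf("true null fraction: %.2f; redrawn genes: %d",
                mean(sim$truth$genes$is_null), sim$n_redrawn))
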