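#!/usr/bin/env Rscript

# Stage 4: the conventional baseline -- a moderated t-test per contrast
# (empirical-Bayes variance shrinkage across genes, BH within contrast) --
# and the set comparison against the meta-analysis discoveries: per-contrast
# DEG counts, their intersections with the meta set, the per-gene support
# histogram, and the genes only the synthesis finds.

suppressPackageStartupMessages(library(metaexpr))

expr <- read_expression_matrix("results/expression_matrix.tsv")
expr <- read_sample_sheet("results/sample_sheet.tsv", expr)
calls <- read_results("results/meta_calls.tsv")

# restrict to the filtered gene universe used by the meta-analysis
expr$matrix <- expr$matrix[calls$gene_id, , drop = FALSE]

s <- expr$samples
contrasts <- unique(paste(s$study_id, s$part, sep = "."))
per_study <- lapply(contrasts, function(cid) moderated_t(expr, cid))
names(per_study) <- contrasts

cmp <- compare_gene_sets(calls, per_study, alpha = 0.05)
write_results(cmp$per_contrast, "results/per_contrast_degs.tsv")
write_results(cmp$support, "results/deg_support.tsv")
write_results(cmp$meta_only_small, "results/meta_only_genes.tsv")

print(cmp$per_contrast)
message(sprintf("meta DEGs: %d; t-test union: %d; found by both: %d",
                cmp$counts["n_meta"], cmp$counts["n_t_union"],
                cmp$counts["n_both"]))
message(sprintf(
  "meta-only genes: %d (%d with |mu| < 0.05 -- small, consistent effects)",
  cmp$counts["n_meta_only"], sum(cmp$meta_only_small$small_effect)))
message("support histogram (contrasts per DEG): ",
        paste(names(cmp$support_hist), cmp$support_hist, sep = ":",
              collapse = " "))
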