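#!/usr/bin/env Rscript

# Stage 3: per-gene mixed-effects meta-regression with each categorical
# moderator fitted separately: plant part (root vs shoot; the seedling
# contrast is excluded) and water-stress method (withholding, mannitol,
# deracination; the PEG contrast is excluded). Moderation is tested by the
# Q_M Wald statistic (equality of level means, chi-square with m - 1 df)
# and labeled from the FDR-adjusted level means.

suppressPackageStartupMessages(library(metaexpr))

effects <- read_results("results/effect_sizes.tsv")
cfg <- run_config()   # DerSimonian-Laird residual tau2 for meta-regression

for (moderator in c("part", "method")) {
  design <- build_design(effects, moderator, cfg)
  message(sprintf("%s design: %d contrasts on levels {%s}; excluded: %s",
                  moderator, nrow(design$X),
                  paste(design$levels, collapse = ", "),
                  paste(design$exclusions$contrast_id, collapse = ", ")))
  fit <- fit_meta_regression(effects, design, cfg)
  cl <- classify_moderation(fit, alpha = cfg$alpha)
  write_results(cl$fits, sprintf("results/metareg_%s_fits.tsv", moderator))
  write_results(cl$coefficients,
                sprintf("results/metareg_%s_coefficients.tsv", moderator))
  tab <- table(cl$fits$moderation)
  message(sprintf("%s-moderated genes at FDR %.2f: %d (%s)",
                  moderator, cfg$alpha,
                  sum(cl$fits$moderation != "ns"),
                  paste(names(tab), tab, sep = "=", collapse = ", ")))
}
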