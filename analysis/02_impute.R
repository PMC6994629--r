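#!/usr/bin/env Rscript

# Stage 2: impute genetically regulated expression (GReX).
#
# Reads the dosage VCF and weight table written by stage 1, fills missing
# genotypes with the per-variant modal genotype, and scores every gene model
# in every tissue as the weighted sum of harmonized effect-allele dosages.

suppressMessages(library(twaspleio))

study_dir <- "results/study"
out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- read_dosage_vcf(file.path(study_dir, "dosages.vcf"))
weights <- read_weight_table(file.path(study_dir, "weights.tsv"))

n_missing <- sum(is.na(panel$dosages))
panel <- fill_missing_dosages(panel)
cat("filled", n_missing, "missing dosage cells by modal genotype\n")

for (tis in sort(unique(weights$tissue))) {
  expr <- impute_expression(panel, weights, tis)
  df <- data.frame(sample_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, file.path(out, paste0("grex_", tis, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(tis, ": ", ncol(expr), " genes imputed for ", nrow(expr),
      " samples\n", sep = "")
}
cat("written to", out, "\n")
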