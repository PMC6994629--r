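#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study cohort.
#
# Builds an LD-blocked dosage panel (2,000 samples x 1,500 variants in
# 20-variant blocks over 2 chromosomes), 150 genes x 2 tissues of sparse cis
# prediction weights, a liability-threshold case/control phenotype driven by
# 15 causal genes, and 8 GWAS trait catalogs of which 3 have lead variants
# planted inside causal-gene spans (constructed pleiotropy). All downstream
# stages read these files back from disk, so the exchange formats are
# exercised end to end.

suppressMessages(library(twaspleio))

out <- "results/study"
cfg <- simulation_config(n_samples = 2000, n_variants = 1500, n_genes = 150,
                         n_tissues = 2, n_causal_genes = 15,
                         causal_effect_size = 0.6, cis_window = 1e5,
                         n_traits = 8, n_leads_per_trait = 4,
                         n_pleiotropic_traits = 3, seed = 20260923)

study <- simulate_study(cfg)
write_synthetic_study(study, out)
yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))

cat("samples:", cfg$n_samples,
    "| variants:", cfg$n_variants,
    "| missing dosage cells:", sum(is.na(study$panel$dosages)), "\n")
cat("prediction models:", n_weight_models(study$weights),
    "| causal genes:", paste(study$truth$causal_genes, collapse = " "), "\n")
cat("realized prevalence:", mean(study$cohort$status), "\n")
cat("GWAS catalogs:", paste(names(study$catalogs), collapse = " "), "\n")
cat("written to", out, "\n")
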