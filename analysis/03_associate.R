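#!/usr/bin/env Rscript

# Stage 3: per gene-tissue association and joint FDR.
#
# Linear regression of case/control status on GReX adjusted for sex, age and
# two genotype PCs; MHC genes excluded before adjustment; one BH correction
# across all gene-tissue tests; significance at Q < 0.001. Gene summaries
# record tissue counts, the strongest-effect tissue and the known/novel
# locus class against the focal trait's lead variants.

suppressMessages(library(twaspleio))

study_dir <- "results/study"
expr_dir <- "results/expression"
out <- "results/twas"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- read_cohort_table(file.path(study_dir, "cohort.tsv"))
annotation <- read_gene_annotation(file.path(study_dir, "genes.tsv"))
weights <- read_weight_table(file.path(study_dir, "weights.tsv"))
focal_gwas <- read_gwas_summary(file.path(study_dir, "gwas_focal.tsv"),
                                trait = "focal")
cfg <- analysis_config()

records <- do.call(rbind, lapply(list.files(expr_dir, "^grex_.*\\.tsv$",
                                            full.names = TRUE),
                                 function(f) {
  tis <- sub("^grex_(.*)\\.tsv$", "\\1", basename(f))
  df <- utils::read.delim(f, check.names = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df$sample_id
  attr(expr, "tissue") <- tis
  run_association(expr, cohort)
}))
cat("tests run:", nrow(records), "\n")

records <- apply_mhc_filter(records, annotation, cfg)
records$q <- bh_fdr(records$p)
records$significant <- records$q < cfg$q_threshold
cat("significant gene-tissue pairs (Q <", cfg$q_threshold, "):",
    sum(records$significant), "\n")

gene_summary <- summarize_genes(records)
leads <- focal_gwas[focal_gwas$p <= cfg$gws_threshold, ]
gene_summary$locus_class <- classify_locus(gene_summary$gene, annotation,
                                           leads, cfg)
counts <- t(vapply(seq_len(nrow(records)), function(i)
  annotate_model_variants(weights[weights$gene == records$gene[i] &
                                    weights$tissue == records$tissue[i], ],
                          focal_gwas, cfg),
  c(n_model = 0, n_gws = 0, n_suggestive = 0)))
records <- cbind(records, counts)

sig <- gene_summary[gene_summary$n_significant_tissues > 0, ]
cat("unique significant genes:", nrow(sig),
    "=", sum(sig$locus_class == "known"), "known +",
    sum(sig$locus_class == "novel"), "novel\n")
cat("genes with a genome-wide significant model variant:",
    length(unique(records$gene[records$significant & records$n_gws > 0])),
    "\n")

utils::write.table(records, file.path(out, "results.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(gene_summary, file.path(out, "gene_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("written to", out, "\n")
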