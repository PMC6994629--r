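#!/usr/bin/env Rscript

# Stage 4: cross-trait pleiotropy via LD-defined R2 loci.
#
# For every trait's genome-wide significant leads (p <= 5e-8), the locus is
# the span of all reference-panel variants with r2 > 0.5 to the lead;
# overlapping loci are merged across traits (pleiotropic regions), and a
# second, 1-Mb-extended locus set is derived. Genes are assigned to trait
# categories by positional overlap and the significant-gene list is tested
# for category enrichment with the two-sided Fisher exact test against all
# predictable genes.

suppressMessages(library(twaspleio))

study_dir <- "results/study"
twas_dir <- "results/twas"
out <- "results/pleiotropy"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- fill_missing_dosages(read_dosage_vcf(file.path(study_dir,
                                                        "dosages.vcf")))
annotation <- read_gene_annotation(file.path(study_dir, "genes.tsv"))
categories <- read_trait_categories(file.path(study_dir, "categories.tsv"))
records <- utils::read.delim(file.path(twas_dir, "results.tsv"))
gene_summary <- utils::read.delim(file.path(twas_dir, "gene_summary.tsv"))

gwas_files <- list.files(study_dir, "^gwas_.*\\.tsv$", full.names = TRUE)
leads <- lapply(gwas_files, function(f) {
  gw <- read_gwas_summary(f)
  gw[gw$p <= 5e-8, ]
})
names(leads) <- sub("^gwas_(.*)\\.tsv$", "\\1", basename(gwas_files))

loci_r2 <- merge_loci(build_trait_loci(panel, leads, categories))
loci_ext <- extend_loci(loci_r2, 1e6)
cat("R2 loci:", nrow(loci_r2), "(mean size",
    round(mean(loci_r2$end - loci_r2$start + 1) / 1e3, 1), "kb) |",
    "1-Mb-extended loci:", nrow(loci_ext), "\n")

predictable <- sort(unique(records$gene))
pred_ann <- annotation[annotation$gene %in% predictable, ]
overlap <- overlap_genes(loci_r2, pred_ann)
sig_genes <- gene_summary$gene[gene_summary$n_significant_tissues > 0]

cat("significant genes in an R2 locus:",
    sum(overlap$in_any_locus[match(sig_genes, overlap$gene)]),
    "of", length(sig_genes),
    sprintf("(%.2f%%)", 100 * mean(overlap$in_any_locus[
      match(sig_genes, overlap$gene)])), "\n")
cat("predictable genes in an R2 locus:", sum(overlap$in_any_locus),
    "of", length(predictable),
    sprintf("(%.2f%%)", 100 * mean(overlap$in_any_locus)), "\n")
cat("potentially pleiotropic genes (>= 2 categories):",
    sum(overlap$pleiotropic), "\n")

enrich <- category_enrichment_all(sig_genes, predictable, overlap)
cat("\ncategory enrichment (two-sided Fisher):\n")
print(enrich, digits = 3)

mw <- tissue_count_comparison(gene_summary, overlap)
cat("\nsignificant-tissue counts, in-locus vs out-of-locus genes:",
    "Mann-Whitney U =", mw$U, ", p =", signif(mw$p, 3), "\n")

write_locus_bed(loci_r2, file.path(out, "loci_r2.bed"))
write_locus_bed(loci_ext, file.path(out, "loci_1mb.bed"))
utils::write.table(overlap, file.path(out, "gene_overlap.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(enrich, file.path(out, "enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("written to", out, "\n")
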