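test_that("genotype simulation recovers the target allele frequency", {
  cfg <- simulation_config(n_samples = 5000, n_variants = 40,
                           ld_block_size = 4, within_block_correlation = 0,
                           maf_range = c(0.3, 0.3), missing_rate = 0,
                           seed = 3)
  panel <- simulate_genotypes(cfg)
  af <- colMeans(panel$dosages) / 2
  # 2n independent alleles per variant: binomial CI oracle
  tol <- 3 * sqrt(0.3 * 0.7 / (2 * cfg$n_samples))
  expect_true(all(abs(af - 0.3) < tol))
})

test_that("within-block LD matches a Monte-Carlo oracle of the thresholded
           latent-Gaussian construction", {
  rho <- 0.9; maf <- 0.5
  cfg <- simulation_config(n_samples = 5000, n_variants = 10,
                           ld_block_size = 5, within_block_correlation = rho,
                           maf_range = c(maf, maf), missing_rate = 0,
                           seed = 4)
  panel <- simulate_genotypes(cfg)
  r2 <- ld_r2(panel, "v000001", "v000002")
  # independent Monte-Carlo of the construction: threshold a bivariate
  # normal with correlation rho at qnorm(maf), correlate the indicators
  set.seed(999)
  n_mc <- 2e5
  u <- rnorm(n_mc)
  z1 <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n_mc)
  z2 <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n_mc)
  thr <- qnorm(maf)
  r2_expected <- cor(z1 < thr, z2 < thr)^2
  expect_lt(abs(r2 - r2_expected), 0.06)
  # at MAF 0.5 a rho = 0.95 block comfortably exceeds the r2 > 0.5 linkage
  # threshold used for locus construction
  cfg95 <- simulation_config(n_samples = 5000, n_variants = 10,
                             ld_block_size = 5,
                             within_block_correlation = 0.95,
                             maf_range = c(0.5, 0.5), missing_rate = 0,
                             seed = 4)
  p95 <- simulate_genotypes(cfg95)
  expect_gt(ld_r2(p95, "v000001", "v000002"), 0.5)
})

test_that("genotype simulation handles empty panels and is seed-deterministic", {
  cfg0 <- simulation_config(n_samples = 0, n_variants = 10, seed = 1)
  expect_equal(dim(simulate_genotypes(cfg0)), c(0L, 10L))
  cfg <- simulation_config(n_samples = 50, n_variants = 30, seed = 5)
  expect_identical(simulate_genotypes(cfg)$dosages,
                   simulate_genotypes(cfg)$dosages)
})

test_that("weight model simulation respects entry counts and cis windows", {
  cfg <- simulation_config(n_samples = 20, n_variants = 100, n_genes = 10,
                           n_tissues = 2, weights_per_gene_range = c(1, 1),
                           missing_rate = 0, seed = 2)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_gene_annotation(cfg)
  wm <- simulate_weight_models(cfg, panel, ann)
  per_model <- table(paste(wm$weights$tissue, wm$weights$gene))
  expect_true(all(per_model == 1L))
  expect_equal(n_weight_models(wm$weights), 10L * 2L)

  # a gene with an empty cis window is skipped with a warning
  cfg_far <- simulation_config(n_samples = 10, n_variants = 10, n_genes = 2,
                               n_tissues = 1, cis_window = 0, seed = 2)
  panel_far <- simulate_genotypes(cfg_far)
  ann_far <- data.frame(gene = c("gA", "gB"),
                        chrom = c("chr1", "chr9"),
                        start = c(1000L, 1000L), end = c(2000L, 2000L))
  expect_warning(wm_far <- simulate_weight_models(cfg_far, panel_far, ann_far),
                 "empty cis window")
  expect_false("gB" %in% wm_far$weights$gene)

  # determinism
  wm2 <- simulate_weight_models(cfg, panel, ann)
  expect_identical(wm$weights, wm2$weights)
  expect_identical(wm$truth, wm2$truth)
})

test_that("liability-threshold cohort has exact prevalence and causal shift", {
  cfg <- simulation_config(n_samples = 400, n_variants = 200, n_genes = 20,
                           n_tissues = 1, n_causal_genes = 0,
                           prevalence = 0.5, missing_rate = 0,
                           covariate_effects = c(sex = 0, age = 0,
                                                 pc1 = 0, pc2 = 0),
                           seed = 9)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_gene_annotation(cfg)
  wm <- simulate_weight_models(cfg, panel, ann)
  coh <- simulate_cohort(cfg, panel, wm$weights, wm$truth)
  expect_equal(sum(coh$status), 200L)

  # one sample: quantile rule yields exactly ceiling(K * 1) = 1 case
  cfg1 <- simulation_config(n_samples = 1, n_variants = 20, n_genes = 2,
                            n_tissues = 1, prevalence = 0.3, seed = 9)
  p1 <- simulate_genotypes(cfg1)
  a1 <- simulate_gene_annotation(cfg1)
  w1 <- simulate_weight_models(cfg1, p1, a1)
  expect_equal(sum(simulate_cohort(cfg1, p1, w1$weights, w1$truth)$status), 1L)

  # strong causal effect: GReX mean among cases exceeds controls
  cfgc <- simulation_config(n_samples = 1000, n_variants = 200, n_genes = 10,
                            n_tissues = 1, n_causal_genes = 1,
                            causal_effect_size = 2, prevalence = 0.5,
                            missing_rate = 0, seed = 13)
  pc <- simulate_genotypes(cfgc)
  ac <- simulate_gene_annotation(cfgc)
  wc <- simulate_weight_models(cfgc, pc, ac)
  cc <- simulate_cohort(cfgc, pc, wc$weights, wc$truth)
  g <- wc$truth$causal_genes[1]
  expr <- impute_expression(pc, wc$weights, "tissue01")
  grex <- expr[, g]
  shift <- (mean(grex[cc$status == 1]) - mean(grex[cc$status == 0])) *
    sign(wc$truth$alpha[[g]])
  # two-sample comparison oracle on the simulated draw
  expect_gt(shift / sd(grex), 0.5)
})

test_that("GWAS catalogs carry genome-wide significant leads and graded blocks", {
  cfg <- simulation_config(n_samples = 200, n_variants = 100, n_genes = 10,
                           n_tissues = 1, n_traits = 1,
                           n_leads_per_trait = 1, n_pleiotropic_traits = 0,
                           missing_rate = 0, seed = 21)
  panel <- simulate_genotypes(cfg)
  ann <- simulate_gene_annotation(cfg)
  wm <- simulate_weight_models(cfg, panel, ann)
  gw <- simulate_gwas_catalogs(cfg, panel, wm$truth, ann)
  cat1 <- gw$catalogs[[1]]
  expect_equal(sum(cat1$p <= 5e-8), 1L)
  expect_equal(gw$leads[[1]]$variant_id,
               cat1$variant_id[cat1$p <= 5e-8])
  # LD-block mates of the lead are sub-threshold but enriched
  lead_block <- panel$variants$block[match(gw$leads[[1]]$variant_id,
                                           panel$variants$id)]
  mates <- panel$variants$id[panel$variants$block == lead_block]
  mates <- setdiff(mates, gw$leads[[1]]$variant_id)
  pm <- cat1$p[match(mates, cat1$variant_id)]
  expect_true(all(pm > 5e-8 & pm < 1e-2))

  # determinism: byte-identical files across runs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gwas_summary(cat1, f1)
  write_gwas_summary(simulate_gwas_catalogs(cfg, panel, wm$truth,
                                            ann)$catalogs[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("constructed pleiotropic traits share lead loci with causal genes", {
  cfg <- simulation_config(n_samples = 100, n_variants = 400, n_genes = 40,
                           n_tissues = 1, n_causal_genes = 5,
                           n_traits = 4, n_leads_per_trait = 3,
                           n_pleiotropic_traits = 2, missing_rate = 0,
                           seed = 31)
  study <- simulate_study(cfg)
  ann <- study$annotation
  causal_spans <- ann[ann$gene %in% study$truth$causal_genes, ]
  in_causal <- function(leads) {
    vapply(seq_len(nrow(leads)), function(i)
      any(causal_spans$chrom == leads$chrom[i] &
            causal_spans$start <= leads$pos[i] &
            causal_spans$end >= leads$pos[i]), logical(1))
  }
  # focal and constructed traits hit causal genes; others need not
  expect_true(any(in_causal(study$truth$leads[["focal"]])))
  expect_true(any(in_causal(study$truth$leads[["trait01"]])))
  expect_true(any(in_causal(study$truth$leads[["trait02"]])))
})

test_that("a written synthetic study round-trips through the format readers", {
  cfg <- simulation_config(n_samples = 30, n_variants = 60, n_genes = 6,
                           n_tissues = 2, n_causal_genes = 2, n_traits = 3,
                           seed = 17)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_study(study, dir)
  panel <- read_dosage_vcf(file.path(dir, "dosages.vcf"))
  expect_equal(panel$dosages, study$panel$dosages)
  w <- read_weight_table(file.path(dir, "weights.tsv"))
  expect_equal(w$weight, study$weights$weight)
  coh <- read_cohort_table(file.path(dir, "cohort.tsv"))
  expect_equal(coh$status, study$cohort$status)
  ann <- read_gene_annotation(file.path(dir, "genes.tsv"))
  expect_equal(ann, study$annotation)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(unname(lengths(sets)), unname(lengths(study$gene_sets)))
})
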