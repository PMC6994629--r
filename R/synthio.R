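#' Simulation configuration
#'
#' Defines a synthetic study: an LD-blocked diploid dosage panel, per-tissue
#' sparse cis prediction-weight models, a binary phenotype generated under a
#' liability-threshold model partly driven by the genetic expression
#' component of a subset of causal genes, and multi-trait GWAS catalogs whose
#' lead variants fall inside or outside the simulated genes.
#'
#' Defaults describe a desk-scale cohort: 2,000 samples, 3,000 variants in
#' 20-variant LD blocks on 2 chromosomes, 300 genes x 3 tissues, balanced
#' prevalence. LD is block-constant: within a block, latent Gaussian
#' haplotypes share pairwise correlation `within_block_correlation` and all
#' variants share one MAF drawn from `maf_range`, so the realized dosage
#' r-squared is a clean monotone function of the latent correlation.
#'
#' @param n_samples,n_variants,n_genes,n_tissues study dimensions
#' @param n_chromosomes chromosomes the variants are spread over
#' @param variant_spacing bp between adjacent variants
#' @param ld_block_size variants per LD block
#' @param within_block_correlation latent haplotype correlation rho in \[0,1)
#' @param maf_range minor-allele-frequency range, subset of (0, 0.5]
#' @param gene_span_bp span of each simulated gene
#' @param cis_window bp added on each side of a gene span when drawing model
#'   variants (default 1 Mb, the usual cis definition)
#' @param weights_per_gene_range integer range of model variants per gene
#' @param flip_fraction fraction of weight entries whose effect allele is the
#'   panel reference allele (exercises allele harmonization)
#' @param missing_rate fraction of dosage cells set missing (exercises
#'   modal-genotype fill)
#' @param n_causal_genes genes whose genetic expression drives liability
#' @param causal_effect_size per-gene liability effect alpha, in liability-SD
#'   units of the gene's standardized expression score (signs alternate
#'   across causal genes)
#' @param prevalence case fraction K in (0,1)
#' @param covariate_effects named numeric: liability coefficients for sex,
#'   age, pc1, pc2
#' @param n_traits number of simulated GWAS catalogs; trait 1 is the focal
#'   disease trait
#' @param n_leads_per_trait lead variants per trait
#' @param n_pleiotropic_traits non-focal traits whose leads are placed inside
#'   causal-gene spans (constructed cross-trait overlap); the remaining
#'   traits get leads at random variants
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed)
#' @return a validated list of class `simulation_config`
#' @export
simulation_config <- function(n_samples = 2000, n_variants = 3000,
                              n_genes = 300, n_tissues = 3,
                              n_chromosomes = 2, variant_spacing = 5000,
                              ld_block_size = 20,
                              within_block_correlation = 0.9,
                              maf_range = c(0.05, 0.5),
                              gene_span_bp = 20000, cis_window = 1e6,
                              weights_per_gene_range = c(1, 10),
                              flip_fraction = 0.1, missing_rate = 0.01,
                              n_causal_genes = 0, causal_effect_size = 0.5,
                              prevalence = 0.5,
                              covariate_effects = c(sex = 0.25, age = 0.01,
                                                    pc1 = 0.2, pc2 = 0.2),
                              n_traits = 6, n_leads_per_trait = 3,
                              n_pleiotropic_traits = 2, seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              n_genes = as.integer(n_genes),
              n_tissues = as.integer(n_tissues),
              n_chromosomes = as.integer(n_chromosomes),
              variant_spacing = as.integer(variant_spacing),
              ld_block_size = as.integer(ld_block_size),
              within_block_correlation = within_block_correlation,
              maf_range = as.numeric(maf_range),
              gene_span_bp = as.integer(gene_span_bp),
              cis_window = as.numeric(cis_window),
              weights_per_gene_range = as.integer(weights_per_gene_range),
              flip_fraction = flip_fraction,
              missing_rate = missing_rate,
              n_causal_genes = as.integer(n_causal_genes),
              causal_effect_size = causal_effect_size,
              prevalence = prevalence,
              covariate_effects = covariate_effects,
              n_traits = as.integer(n_traits),
              n_leads_per_trait = as.integer(n_leads_per_trait),
              n_pleiotropic_traits = as.integer(n_pleiotropic_traits),
              seed = as.integer(seed))
  counts <- c("n_samples", "n_variants", "n_genes", "n_tissues",
              "n_causal_genes", "n_traits", "n_leads_per_trait",
              "n_pleiotropic_traits")
  for (f in counts) if (cfg[[f]] < 0L) stop2(f, " must be >= 0")
  if (cfg$n_chromosomes < 1L || cfg$ld_block_size < 1L)
    stop2("n_chromosomes and ld_block_size must be >= 1")
  if (cfg$within_block_correlation < 0 || cfg$within_block_correlation >= 1)
    stop2("within_block_correlation must lie in [0, 1)")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop2("maf_range must be an increasing pair inside (0, 0.5]")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop2("prevalence must lie strictly in (0, 1)")
  if (cfg$n_causal_genes > cfg$n_genes)
    stop2("n_causal_genes exceeds n_genes")
  if (cfg$n_pleiotropic_traits > max(0L, cfg$n_traits - 1L))
    stop2("n_pleiotropic_traits must leave room for the focal trait")
  need <- c("sex", "age", "pc1", "pc2")
  if (!all(need %in% names(cfg$covariate_effects)))
    stop2("covariate_effects must be named: ", paste(need, collapse = ", "))
  structure(cfg, class = c("simulation_config", "list"))
}

# stage-specific child seed, kept inside 32-bit integer range
stage_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) + offset) %% .Machine$integer.max)
}

# deterministic variant layout: blocks assigned contiguously to chromosomes,
# positions at regular spacing within each chromosome
variant_layout <- function(config) {
  n <- config$n_variants
  if (n == 0L)
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), block = integer()))
  block <- (seq_len(n) - 1L) %/% config$ld_block_size + 1L
  n_blocks <- max(block)
  chrom_of_block <- rep(seq_len(config$n_chromosomes),
                        each = ceiling(n_blocks / config$n_chromosomes))[seq_len(n_blocks)]
  chrom <- paste0("chr", chrom_of_block[block])
  pos <- integer(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- config$variant_spacing * seq_along(idx)
  }
  data.frame(chrom = chrom, pos = pos,
             id = sprintf("v%06d", seq_len(n)),
             ref = "A", alt = "G", block = block,
             stringsAsFactors = FALSE)
}

#' Simulate an LD-blocked dosage panel
#'
#' Variants sit at regular spacing along chromosomes, grouped into LD blocks.
#' Within each block two latent Gaussian haplotypes per sample share pairwise
#' correlation rho (one-factor construction); each latent value is
#' thresholded at the block MAF quantile to an allele and the two haplotypes
#' are summed to a dosage in \{0, 1, 2\}. Blocks are independent. A fraction
#' `missing_rate` of cells is then set missing.
#'
#' @param config a [simulation_config()]
#' @return a [dosage_panel()] with an extra variant column `block`
#' @export
simulate_genotypes <- function(config) {
  set.seed(stage_seed(config, 101))
  lay <- variant_layout(config)
  n <- config$n_samples
  m <- nrow(lay)
  D <- matrix(numeric(0), nrow = n, ncol = m)
  if (n > 0L && m > 0L) {
    rho <- config$within_block_correlation
    D <- matrix(0, nrow = n, ncol = m)
    for (b in unique(lay$block)) {
      cols <- which(lay$block == b)
      maf <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      thr <- stats::qnorm(maf)
      for (h in 1:2) {
        u <- stats::rnorm(n)
        z <- sqrt(rho) * u +
          sqrt(1 - rho) * matrix(stats::rnorm(n * length(cols)), n)
        D[, cols] <- D[, cols] + (z < thr)
      }
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(n * m) < config$missing_rate
      D[drop] <- NA_real_
    }
  }
  panel <- dosage_panel(lay[c("chrom", "pos", "id", "ref", "alt")],
                        if (n > 0) sprintf("s%05d", seq_len(n)) else character(),
                        D)
  panel$variants$block <- lay$block
  panel
}

#' Simulate gene annotation on the panel's coordinate system
#'
#' Genes are placed deterministically: each chromosome receives its share of
#' genes at evenly spaced centers, each spanning `gene_span_bp`.
#'
#' @param config a [simulation_config()]
#' @return gene annotation data.frame (`gene`, `chrom`, `start`, `end`)
#' @export
simulate_gene_annotation <- function(config) {
  lay <- variant_layout(config)
  if (config$n_genes == 0L || nrow(lay) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer()))
  chroms <- unique(lay$chrom)
  per_chrom <- table(factor(rep(chroms, length.out = config$n_genes),
                            levels = chroms))
  out <- list()
  g <- 0L
  for (cc in chroms) {
    k <- as.integer(per_chrom[[cc]])
    if (k == 0L) next
    span_max <- max(lay$pos[lay$chrom == cc])
    centers <- as.integer(round(seq(1, span_max, length.out = k + 2L)[2:(k + 1L)]))
    half <- config$gene_span_bp %/% 2L
    out[[cc]] <- data.frame(gene = sprintf("g%04d", g + seq_len(k)),
                            chrom = cc,
                            start = pmax(1L, centers - half),
                            end = centers + half,
                            stringsAsFactors = FALSE)
    g <- g + k
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate per-tissue cis prediction weight models
#'
#' For each gene and tissue, K variants (K uniform on
#' `weights_per_gene_range`) are drawn uniformly from the gene's cis window
#' (span +/- `cis_window`) with weights N(0,1)/sqrt(K). A fraction
#' `flip_fraction` of entries use the panel reference allele as effect
#' allele, so downstream harmonization is exercised. Genes with an empty cis
#' window are skipped with a warning.
#'
#' @param config a [simulation_config()]
#' @param panel a [dosage_panel()]
#' @param annotation gene annotation data.frame
#' @return list with `weights` (a `weight_table` data.frame) and `truth`
#'   (list: `causal_genes`, `alpha` — named vector of liability effects,
#'   `leads` — filled in later by [simulate_gwas_catalogs()])
#' @export
simulate_weight_models <- function(config, panel, annotation) {
  set.seed(stage_seed(config, 202))
  v <- panel$variants
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  rows <- vector("list", nrow(annotation) * length(tissues))
  ri <- 0L
  skipped <- character()
  for (gi in seq_len(nrow(annotation))) {
    g <- annotation[gi, ]
    cis <- which(v$chrom == g$chrom &
                   v$pos >= g$start - config$cis_window &
                   v$pos <= g$end + config$cis_window)
    if (length(cis) == 0L) { skipped <- c(skipped, g$gene); next }
    for (tis in tissues) {
      k_range <- config$weights_per_gene_range
      k <- min(length(cis),
               if (k_range[1] == k_range[2]) k_range[1]
               else sample(k_range[1]:k_range[2], 1))
      chosen <- if (length(cis) == 1L) cis else sample(cis, k)
      w <- stats::rnorm(k) / sqrt(k)
      flip <- stats::runif(k) < config$flip_fraction
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        tissue = tis, gene = g$gene, variant_id = v$id[chosen],
        effect_allele = ifelse(flip, v$ref[chosen], v$alt[chosen]),
        non_effect_allele = ifelse(flip, v$alt[chosen], v$ref[chosen]),
        weight = w, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("genes with empty cis window skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  weights <- do.call(rbind, rows[seq_len(ri)]) %||%
    data.frame(tissue = character(), gene = character(),
               variant_id = character(), effect_allele = character(),
               non_effect_allele = character(), weight = numeric())
  rownames(weights) <- NULL
  class(weights) <- c("weight_table", "data.frame")

  modeled <- unique(weights$gene)
  n_causal <- min(config$n_causal_genes, length(modeled))
  causal <- if (n_causal > 0) sort(sample(modeled, n_causal)) else character()
  alpha <- if (n_causal > 0) {
    stats::setNames(config$causal_effect_size *
                      rep_len(c(1, -1), n_causal), causal)
  } else stats::setNames(numeric(0), character(0))
  list(weights = weights,
       truth = list(causal_genes = causal, alpha = alpha, leads = NULL))
}

#' Simulate a case/control cohort under a liability-threshold model
#'
#' Liability is the sum of (i) the standardized genetic expression score of
#' each causal gene (first tissue's model) times its alpha, (ii) linear
#' covariate terms (sex ~ Bernoulli(0.5); age ~ Uniform(50, 95); pc1, pc2 ~
#' N(0,1)), and (iii) N(0,1) noise. Status is assigned by empirical-quantile
#' thresholding: exactly `ceiling(prevalence * n)` samples with the largest
#' liabilities become cases, so realized prevalence is exact at any n.
#'
#' @param config a [simulation_config()]
#' @param panel a [dosage_panel()] (missing cells are modal-filled first)
#' @param models `weights` element from [simulate_weight_models()]
#' @param truth `truth` element from [simulate_weight_models()]
#' @return cohort data.frame (`sample_id`, `status`, `sex`, `age`, `pc1`,
#'   `pc2`) with attribute `liability`
#' @export
simulate_cohort <- function(config, panel, models, truth) {
  set.seed(stage_seed(config, 303))
  n <- config$n_samples
  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::runif(n, 50, 95)
  pc1 <- stats::rnorm(n)
  pc2 <- stats::rnorm(n)
  eff <- config$covariate_effects
  liability <- eff[["sex"]] * sex + eff[["age"]] * age +
    eff[["pc1"]] * pc1 + eff[["pc2"]] * pc2 + stats::rnorm(n)

  causal <- truth$causal_genes
  if (length(causal) > 0 && n > 1) {
    filled <- if (anyNA(panel$dosages)) fill_missing_dosages(panel) else panel
    tissue1 <- sort(unique(models$tissue))[1]
    grex <- impute_expression(filled, models, tissue1)
    causal <- intersect(causal, colnames(grex))
    for (g in causal) {
      x <- grex[, g]
      s <- stats::sd(x)
      if (s > 0) liability <- liability + truth$alpha[[g]] * (x - mean(x)) / s
    }
  }
  status <- integer(n)
  if (n > 0) {
    n_cases <- as.integer(ceiling(config$prevalence * n))
    status[order(liability, decreasing = TRUE)[seq_len(n_cases)]] <- 1L
  }
  out <- data.frame(sample_id = panel$samples[seq_len(n)],
                    status = status, sex = as.numeric(sex), age = age,
                    pc1 = pc1, pc2 = pc2, stringsAsFactors = FALSE)
  attr(out, "liability") <- liability
  out
}

#' Simulate multi-trait GWAS catalogs with constructed pleiotropy
#'
#' Trait 1 is the focal disease trait; its leads are placed at model variants
#' of causal genes (or random variants when there are none). The next
#' `n_pleiotropic_traits` traits get leads inside causal-gene spans, creating
#' cross-trait locus overlap by construction; remaining traits get leads at
#' random variants. Leads receive p-values below 5e-8; variants in a lead's
#' LD block get graded sub-threshold p-values (smaller nearer the lead, never
#' genome-wide significant); all other variants are Uniform(0,1).
#'
#' @param config a [simulation_config()]
#' @param panel a [dosage_panel()] from [simulate_genotypes()] (needs the
#'   `block` variant column)
#' @param truth truth list from [simulate_weight_models()]
#' @param annotation gene annotation (used to place constructed leads inside
#'   causal-gene spans)
#' @return list: `catalogs` (named list of GWAS summary data.frames),
#'   `leads` (named list of lead data.frames), `categories` (trait ->
#'   category map; focal trait has category "focal", constructed traits
#'   share category with their trait name, others likewise)
#' @export
simulate_gwas_catalogs <- function(config, panel, truth, annotation) {
  set.seed(stage_seed(config, 404))
  v <- panel$variants
  n_traits <- config$n_traits
  if (n_traits == 0L)
    return(list(catalogs = list(), leads = list(),
                categories = data.frame(trait = character(),
                                        category = character())))
  traits <- c("focal", sprintf("trait%02d", seq_len(max(0L, n_traits - 1L))))
  constructed <- traits[seq_len(config$n_pleiotropic_traits) + 1L]

  causal <- truth$causal_genes
  in_gene_variants <- function(genes) {
    hits <- integer(0)
    for (g in genes) {
      a <- annotation[annotation$gene == g, ]
      if (nrow(a) == 0) next
      inside <- which(v$chrom == a$chrom & v$pos >= a$start & v$pos <= a$end)
      if (length(inside) == 0) {
        cand <- which(v$chrom == a$chrom)
        inside <- cand[which.min(abs(v$pos[cand] - (a$start + a$end) / 2))]
      }
      hits <- c(hits, inside[ceiling(length(inside) / 2)])
    }
    hits
  }

  pick_leads <- function(trait) {
    k <- config$n_leads_per_trait
    if (k == 0L || nrow(v) == 0L) return(integer(0))
    if (length(causal) > 0 && (trait == "focal" || trait %in% constructed)) {
      pool <- in_gene_variants(causal)
      if (length(pool) >= k) return(sort(sample(pool, k)))
      extra <- sample(setdiff(seq_len(nrow(v)), pool),
                      min(k - length(pool), nrow(v) - length(pool)))
      return(sort(c(pool, extra)))
    }
    sort(sample(nrow(v), min(k, nrow(v))))
  }

  catalogs <- list(); leads <- list()
  for (trait in traits) {
    idx <- pick_leads(trait)
    p <- stats::runif(nrow(v))
    p[p <= 0] <- .Machine$double.eps
    for (li in idx) {
      b <- v$block[li]
      mates <- which(v$block == b)
      mates <- setdiff(mates, li)
      if (length(mates)) {
        # graded: closer to the lead -> smaller, but always above 5e-8
        d <- abs(v$pos[mates] - v$pos[li])
        frac <- 1 - d / (max(d) + config$variant_spacing)
        p[mates] <- 10^(-(4 + 2.8 * frac)) * stats::runif(length(mates), 0.5, 1.5)
        p[mates] <- pmin(pmax(p[mates], 5.01e-8), 1)
      }
      p[li] <- 10^(-stats::runif(1, 8.5, 12))
    }
    cat_df <- data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos,
                         p = p, stringsAsFactors = FALSE)
    attr(cat_df, "trait") <- trait
    catalogs[[trait]] <- cat_df
    leads[[trait]] <- cat_df[idx, , drop = FALSE]
  }
  list(catalogs = catalogs, leads = leads,
       categories = data.frame(trait = traits, category = traits,
                               stringsAsFactors = FALSE))
}

#' Simulate gene sets for enrichment testing
#'
#' Builds `n_sets` gene sets from the annotation universe: the first set is
#' seeded with the causal genes (plus random padding), the rest are random
#' draws — so overrepresentation of the causal-gene list in set 1 holds by
#' construction.
#'
#' @param config a [simulation_config()]
#' @param annotation gene annotation
#' @param truth truth list
#' @param n_sets number of sets
#' @param set_size_range integer range of set sizes
#' @return named list of gene-id vectors (GMT-compatible, see [write_gmt()])
#' @export
simulate_gene_sets <- function(config, annotation, truth, n_sets = 10,
                               set_size_range = c(10, 40)) {
  set.seed(stage_seed(config, 505))
  universe <- annotation$gene
  sizes <- sample(set_size_range[1]:set_size_range[2], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sort(sample(universe, min(k, length(universe)))))
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  if (length(truth$causal_genes) > 0 && n_sets > 0) {
    pad <- setdiff(sets[[1]], truth$causal_genes)
    k_pad <- max(0L, sizes[1] - length(truth$causal_genes))
    sets[[1]] <- sort(unique(c(truth$causal_genes, utils::head(pad, k_pad))))
  }
  attr(sets, "description") <- rep("synthetic", n_sets)
  sets
}

#' Simulate a complete synthetic study
#'
#' Runs all generators in order and returns every object the pipeline needs.
#'
#' @param config a [simulation_config()]
#' @return list: `config`, `panel`, `annotation`, `weights`, `truth` (with
#'   leads filled in), `cohort`, `catalogs`, `categories`, `gene_sets`
#' @export
simulate_study <- function(config) {
  panel <- simulate_genotypes(config)
  annotation <- simulate_gene_annotation(config)
  wm <- simulate_weight_models(config, panel, annotation)
  cohort <- simulate_cohort(config, panel, wm$weights, wm$truth)
  gw <- simulate_gwas_catalogs(config, panel, wm$truth, annotation)
  truth <- wm$truth
  truth$leads <- gw$leads
  sets <- simulate_gene_sets(config, annotation, truth)
  list(config = config, panel = panel, annotation = annotation,
       weights = wm$weights, truth = truth, cohort = cohort,
       catalogs = gw$catalogs, categories = gw$categories,
       gene_sets = sets)
}

#' Write a synthetic study to disk
#'
#' Emits `dosages.vcf`, `weights.tsv`, `cohort.tsv`, `genes.tsv`,
#' `gwas_<trait>.tsv`, `categories.tsv`, `gene_sets.gmt` and `truth.json`
#' under `dir`.
#'
#' @param study result of [simulate_study()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dosage_vcf(study$panel, file.path(dir, "dosages.vcf"))
  write_weight_table(study$weights, file.path(dir, "weights.tsv"))
  write_cohort_table(study$cohort, file.path(dir, "cohort.tsv"))
  write_gene_annotation(study$annotation, file.path(dir, "genes.tsv"))
  for (trait in names(study$catalogs))
    write_gwas_summary(study$catalogs[[trait]],
                       file.path(dir, paste0("gwas_", trait, ".tsv")))
  write_tsv_plain(study$categories, file.path(dir, "categories.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- study$truth
  truth$alpha <- as.list(truth$alpha)
  truth$leads <- lapply(truth$leads, function(df) df$variant_id)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
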