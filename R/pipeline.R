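#' Printed-percentage bookkeeping
#'
#' `100 * numerator / denominator`, rounded half-up to the number of printed
#' decimals (2 by default). A zero denominator is undefined and reported as
#' `NA` (serialized as JSON null).
#'
#' @param numerator,denominator counts
#' @param digits decimals to keep, default 2
#' @return percentage, or `NA` for a zero denominator
#' @export
compute_report_percentages <- function(numerator, denominator, digits = 2) {
  ifelse(denominator == 0, NA_real_,
         round_half_up(100 * numerator / denominator, digits))
}

pipeline_defaults <- function() {
  list(simulation = list(), analysis = list(),
       enrichment = list(n_random_lists = 100),
       pleiotropy = list(r2_threshold = 0.5, search_window_bp = 2e6,
                         extension_bp = 1e6))
}

validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop2("config must be a list or a YAML file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop2("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(defaults))
    defaults[[sec]] <- utils::modifyList(defaults[[sec]],
                                         config[[sec]] %||% list())
  known_sim <- names(formals(simulation_config))
  bad <- setdiff(names(defaults$simulation), known_sim)
  if (length(bad))
    stop2("unknown simulation field(s): ", paste(bad, collapse = ", "))
  known_an <- names(formals(analysis_config))
  bad <- setdiff(names(defaults$analysis), known_an)
  if (length(bad))
    stop2("unknown analysis field(s): ", paste(bad, collapse = ", "))
  defaults
}

#' Run the full synthetic-study pipeline
#'
#' Stages, in fixed order: simulate the study; fill missing dosages; impute
#' expression per tissue; associate expression with status (covariate-
#' adjusted); exclude MHC genes; joint BH FDR across all gene-tissue tests;
#' flag significance; summarize per gene (significant-tissue counts,
#' strongest-effect tissue, known/novel locus class, model-variant GWAS
#' counts); build per-trait R-squared loci, merge, extend by 1 Mb, overlap
#' genes, test category enrichment and compare tissue counts; run gene-set
#' overrepresentation for the significant genes. Every stage's outputs are
#' written under `out_dir` together with a machine-readable `report.json`.
#'
#' @param config a config list or YAML path with optional sections
#'   `simulation` (fields of [simulation_config()]), `analysis` (fields of
#'   [analysis_config()]), `pleiotropy` (`r2_threshold`, `search_window_bp`,
#'   `extension_bp`) and `enrichment` (`n_random_lists`)
#' @param out_dir output directory, or `NULL` to skip writing
#' @param seed overrides the simulation seed (and seeds the enrichment rank
#'   null)
#' @param force overwrite an existing non-empty `out_dir`
#' @return list: `report` (the run report), `records`, `gene_summary`,
#'   `loci_r2`, `loci_ext`, `overlap`, `category_tests`, `tissue_test`,
#'   `enrichment`, `study`
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL,
                         force = FALSE) {
  cfg <- validate_pipeline_config(config)
  sim_args <- cfg$simulation
  if (!is.null(seed)) sim_args$seed <- seed
  sim_cfg <- do.call(simulation_config, sim_args)
  an_cfg <- do.call(analysis_config, cfg$analysis)

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
      stop2("out_dir exists and is non-empty; use force = TRUE")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  log_event("pipeline", "simulate", seed = sim_cfg$seed)
  study <- simulate_study(sim_cfg)
  panel <- fill_missing_dosages(study$panel)
  tissues <- sort(unique(study$weights$tissue))

  log_event("pipeline", "impute", tissues = length(tissues))
  records <- do.call(rbind, lapply(tissues, function(tis) {
    expr <- impute_expression(panel, study$weights, tis)
    run_association(expr, study$cohort)
  }))
  n_tested <- nrow(records)

  records <- apply_mhc_filter(records, study$annotation, an_cfg)
  n_mhc <- attr(records, "n_mhc_removed")
  records$q <- bh_fdr(records$p)
  records$significant <- records$q < an_cfg$q_threshold

  # model-variant annotation against the focal trait's GWAS catalog
  focal_gwas <- if (length(study$catalogs)) study$catalogs[[1]] else
    data.frame(variant_id = character(), p = numeric())
  ann_counts <- t(vapply(seq_len(nrow(records)), function(i) {
    entries <- study$weights[study$weights$gene == records$gene[i] &
                               study$weights$tissue == records$tissue[i], ,
                             drop = FALSE]
    annotate_model_variants(entries, focal_gwas, an_cfg)
  }, c(n_model = 0, n_gws = 0, n_suggestive = 0)))
  records <- cbind(records, ann_counts)
  records$direction <- ifelse(records$beta >= 0, "+", "-")

  gene_summary <- summarize_genes(records)
  focal_leads <- if (length(study$truth$leads)) study$truth$leads[[1]] else
    data.frame(chrom = character(), pos = integer())
  gene_summary$locus_class <- classify_locus(gene_summary$gene,
                                             study$annotation, focal_leads,
                                             an_cfg)
  records$locus_class <- gene_summary$locus_class[match(records$gene,
                                                        gene_summary$gene)]

  sig_genes <- gene_summary$gene[gene_summary$n_significant_tissues > 0]
  n_known <- sum(gene_summary$locus_class[match(sig_genes,
                                                gene_summary$gene)] == "known")
  n_novel <- length(sig_genes) - n_known

  log_event("pipeline", "pleiotropy", traits = length(study$truth$leads))
  pl <- cfg$pleiotropy
  loci_raw <- build_trait_loci(panel, study$truth$leads, study$categories,
                               pl$r2_threshold, pl$search_window_bp)
  loci_r2 <- merge_loci(loci_raw)
  loci_ext <- extend_loci(loci_r2, pl$extension_bp)
  # predictable genes: tested in at least one tissue (post-MHC universe)
  predictable <- sort(unique(records$gene))
  pred_ann <- study$annotation[study$annotation$gene %in% predictable, ,
                               drop = FALSE]
  overlap <- overlap_genes(loci_r2, pred_ann)
  overlap_ext <- overlap_genes(loci_ext, pred_ann)
  category_tests <- if (length(sig_genes))
    category_enrichment_all(sig_genes, predictable, overlap) else NULL
  tissue_test <- tryCatch(
    tissue_count_comparison(gene_summary, overlap),
    error = function(e) list(U = NA_real_, p = NA_real_,
                             n_in = NA_integer_, n_out = NA_integer_))

  enr <- if (length(sig_genes) > 0)
    run_enrichment(sig_genes, study$gene_sets,
                   background_genes = predictable,
                   n_random_lists = cfg$enrichment$n_random_lists,
                   seed = sim_cfg$seed) else NULL

  sig_in_locus <- sum(overlap$in_any_locus[match(sig_genes, overlap$gene)],
                      na.rm = TRUE)
  n_pred_in_locus <- sum(overlap$in_any_locus)
  report <- list(
    seed = sim_cfg$seed,
    config = list(simulation = unclass(sim_cfg), analysis = unclass(an_cfg),
                  pleiotropy = pl,
                  enrichment = cfg$enrichment),
    counts = list(
      tests_run = n_tested,
      genes_excluded_mhc = n_mhc,
      significant_pairs = sum(records$significant),
      significant_genes = length(sig_genes),
      known_locus_genes = n_known,
      novel_locus_genes = n_novel,
      predictable_genes = length(predictable),
      significant_genes_in_any_locus = sig_in_locus,
      predictable_genes_in_any_locus = n_pred_in_locus,
      pleiotropic_genes = sum(overlap$pleiotropic),
      predictable_genes_in_any_extended_locus = sum(overlap_ext$in_any_locus)),
    percentages = list(
      pct_significant_genes_in_loci = compute_report_percentages(
        sig_in_locus, length(sig_genes)),
      pct_predictable_genes_in_loci = compute_report_percentages(
        n_pred_in_locus, length(predictable)),
      pct_predictable_genes_in_extended_loci = compute_report_percentages(
        sum(overlap_ext$in_any_locus), length(predictable))),
    tissue_count_test = tissue_test)

  stopifnot(report$counts$significant_genes <=
              report$counts$significant_pairs ||
              report$counts$significant_genes == 0,
            report$counts$known_locus_genes +
              report$counts$novel_locus_genes ==
              report$counts$significant_genes)

  if (!is.null(out_dir)) {
    write_tsv_plain(records, file.path(out_dir, "results.tsv"))
    write_tsv_plain(gene_summary, file.path(out_dir, "gene_summary.tsv"))
    write_locus_bed(loci_r2, file.path(out_dir, "loci_r2.bed"))
    write_locus_bed(loci_ext, file.path(out_dir, "loci_1mb.bed"))
    write_tsv_plain(overlap, file.path(out_dir, "gene_overlap.tsv"))
    if (!is.null(category_tests))
      write_tsv_plain(category_tests, file.path(out_dir, "enrichment.tsv"))
    if (!is.null(enr))
      write_tsv_plain(enr, file.path(out_dir, "enrichment_sets.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
  }
  list(report = report, records = records, gene_summary = gene_summary,
       loci_r2 = loci_r2, loci_ext = loci_ext, overlap = overlap,
       overlap_ext = overlap_ext, category_tests = category_tests,
       tissue_test = tissue_test, enrichment = enr, study = study)
}
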