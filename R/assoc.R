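#' Analysis configuration
#'
#' Thresholds and windows for the association stage: genes are significant
#' at BH Q-value below `q_threshold`; genes in the MHC interval are excluded
#' before FDR; model variants are counted against genome-wide significant
#' (p <= `gws_threshold`) and suggestive (p < `suggestive_threshold`) GWAS
#' p-values; a gene is in a known locus when its span lies within
#' `locus_window` of a lead variant.
#'
#' @param q_threshold significance threshold on the BH Q-value (default
#'   0.001)
#' @param mhc_chrom,mhc_start,mhc_end MHC interval (default
#'   chr6:28,477,797-33,448,354, hg19)
#' @param gws_threshold genome-wide significance threshold (default 5e-8,
#'   counted inclusively)
#' @param suggestive_threshold suggestive-association threshold (default
#'   1e-4, counted strictly)
#' @param locus_window bp on each side of a lead variant (default 1 Mb)
#' @return a validated list of class `analysis_config`
#' @export
analysis_config <- function(q_threshold = 0.001, mhc_chrom = "chr6",
                            mhc_start = 28477797, mhc_end = 33448354,
                            gws_threshold = 5e-8,
                            suggestive_threshold = 1e-4,
                            locus_window = 1e6) {
  for (thr in c(q_threshold, gws_threshold, suggestive_threshold))
    if (thr <= 0 || thr >= 1) stop2("thresholds must lie in (0, 1)")
  if (locus_window < 0) stop2("locus_window must be >= 0")
  structure(list(q_threshold = q_threshold, mhc_chrom = mhc_chrom,
                 mhc_start = mhc_start, mhc_end = mhc_end,
                 gws_threshold = gws_threshold,
                 suggestive_threshold = suggestive_threshold,
                 locus_window = locus_window),
            class = c("analysis_config", "list"))
}

#' Associate imputed expression with case/control status
#'
#' Per gene, ordinary least squares of status on
#' \[intercept, GReX, covariates\]; the reported effect is the GReX
#' coefficient, its standard error and two-sided t-test p-value. A positive
#' effect means predicted expression is higher in cases than controls.
#' Computed via residualization (Frisch–Waugh–Lovell): status and every GReX
#' column are projected off the covariate design once, which gives
#' coefficients, standard errors and p-values identical to the full fit at a
#' fraction of the cost. Genes whose residualized GReX has (numerically)
#' zero variance are flagged degenerate and excluded from testing.
#'
#' A logistic option exists behind `method = "logistic"` (per-gene GLM, Wald
#' z-test); the default is the linear model.
#'
#' @param expression samples x genes matrix from [impute_expression()]
#' @param cohort cohort data.frame (see [read_cohort_table()]); sample ids
#'   must cover the expression rows
#' @param covariates columns of `cohort` to adjust for (default sex, age,
#'   pc1, pc2); may be empty
#' @param method `"linear"` (default) or `"logistic"`
#' @return data.frame (`gene`, `tissue`, `beta`, `se`, `p`) for tested
#'   genes; attribute `degenerate` lists excluded gene ids
#' @export
run_association <- function(expression, cohort,
                            covariates = c("sex", "age", "pc1", "pc2"),
                            method = c("linear", "logistic")) {
  method <- match.arg(method)
  tissue <- attr(expression, "tissue") %||% NA_character_
  samp <- rownames(expression)
  idx <- match(samp, cohort$sample_id)
  if (anyNA(idx))
    stop2("expression samples absent from cohort: ",
          paste(utils::head(samp[is.na(idx)], 3), collapse = ", "))
  cohort <- cohort[idx, , drop = FALSE]
  y <- as.numeric(cohort$status)
  n <- length(y)
  miss_cov <- setdiff(covariates, names(cohort))
  if (length(miss_cov))
    stop2("covariate(s) absent from cohort: ", paste(miss_cov, collapse = ", "))
  X <- matrix(1, nrow = n, ncol = 1 + length(covariates),
              dimnames = list(NULL, c("(Intercept)", covariates)))
  for (cv in covariates) X[, cv] <- as.numeric(cohort[[cv]])
  if (n < ncol(X) + 2L)
    stop2("need at least ", ncol(X) + 2L, " samples, got ", n)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop2("covariate design is rank-deficient; collinear column(s): ",
          paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  G <- as.matrix(expression)
  genes <- colnames(G)
  sds <- apply(G, 2L, stats::sd)

  if (method == "logistic") {
    res <- lapply(seq_along(genes), function(j) {
      if (sds[j] == 0) return(NULL)
      fit <- stats::glm(y ~ G[, j] + X - 1, family = stats::binomial())
      cf <- summary(fit)$coefficients
      data.frame(gene = genes[j], tissue = tissue, beta = cf[1, 1],
                 se = cf[1, 2], p = cf[1, 4], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res) %||%
      data.frame(gene = character(), tissue = character(), beta = numeric(),
                 se = numeric(), p = numeric())
    attr(out, "degenerate") <- genes[sds == 0]
    rownames(out) <- NULL
    return(out)
  }

  ry <- qr.resid(qx, y)
  RG <- qr.resid(qx, G)
  ss_g <- colSums(RG^2)
  scale_ref <- pmax(colSums(G^2), 1)
  degenerate <- sds == 0 | ss_g <= 1e-12 * scale_ref
  df_resid <- n - ncol(X) - 1L
  beta <- colSums(RG * ry) / ss_g
  rss <- sum(ry^2) - beta^2 * ss_g
  sigma2 <- rss / df_resid
  se <- sqrt(sigma2 / ss_g)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df_resid)
  out <- data.frame(gene = genes, tissue = tissue, beta = beta, se = se,
                    p = p, stringsAsFactors = FALSE)[!degenerate, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- genes[degenerate]
  out
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_(j>=i) p_(j) * m / j` capped at 1,
#' mapped back to input order. Validates that p-values lie in (0, 1] and
#' delegates to [stats::p.adjust()]. In the pipeline this is applied once,
#' jointly across all gene–tissue tests.
#'
#' @param p numeric vector of p-values in (0, 1]
#' @return q-values in input order
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p) | p <= 0 | p > 1))
    stop2("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Exclude genes in the MHC region before FDR
#'
#' The major histocompatibility complex has a highly complex association
#' structure; genes whose span intersects the MHC interval are removed
#' before multiple-testing adjustment so they do not contribute to m.
#'
#' @param records association records data.frame (needs a `gene` column)
#' @param annotation gene annotation data.frame covering every gene
#' @param config an [analysis_config()]
#' @return filtered records; attribute `n_mhc_removed` counts removed rows
#' @export
apply_mhc_filter <- function(records, annotation, config = analysis_config()) {
  idx <- match(records$gene, annotation$gene)
  if (anyNA(idx))
    stop2("gene(s) missing from annotation: ",
          paste(utils::head(unique(records$gene[is.na(idx)]), 3),
                collapse = ", "))
  ann <- annotation[idx, , drop = FALSE]
  in_mhc <- ann$chrom == config$mhc_chrom &
    ann$start <= config$mhc_end & ann$end >= config$mhc_start
  out <- records[!in_mhc, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_mhc_removed") <- sum(in_mhc)
  log_event("assoc", "mhc_filter", removed = sum(in_mhc))
  out
}

#' Classify genes as lying in known or novel loci
#'
#' A gene is "known" when its span intersects the window
#' \[lead - locus_window, lead + locus_window\] of at least one lead variant
#' on the same chromosome; otherwise "novel".
#'
#' @param genes character vector of gene ids
#' @param annotation gene annotation covering `genes`
#' @param lead_variants data.frame with columns `chrom`, `pos` (the known
#'   GWAS hits of the focal disease)
#' @param config an [analysis_config()]
#' @return character vector over \{"known", "novel"\}, named by gene
#' @export
classify_locus <- function(genes, annotation, lead_variants,
                           config = analysis_config()) {
  idx <- match(genes, annotation$gene)
  if (anyNA(idx))
    stop2("gene(s) missing from annotation: ",
          paste(utils::head(genes[is.na(idx)], 3), collapse = ", "))
  ann <- annotation[idx, , drop = FALSE]
  w <- config$locus_window
  out <- vapply(seq_along(genes), function(i) {
    leads <- lead_variants[lead_variants$chrom == ann$chrom[i], , drop = FALSE]
    if (nrow(leads) == 0L) return("novel")
    hit <- any(ann$start[i] <= leads$pos + w & ann$end[i] >= leads$pos - w)
    if (hit) "known" else "novel"
  }, character(1))
  stats::setNames(out, genes)
}

#' Count GWAS-significant variants in one prediction model
#'
#' For one (gene, tissue) model, counts entries whose variant reaches
#' genome-wide significance (p <= `gws_threshold`) or suggestive association
#' (p < `suggestive_threshold`) in the supplied GWAS summary. Entries absent
#' from the summary count toward the model size only.
#'
#' @param model_entries weight-table rows of one (gene, tissue) model
#' @param gwas_summary GWAS summary data.frame (`variant_id`, `p`)
#' @param config an [analysis_config()]
#' @return named integer vector `c(n_model, n_gws, n_suggestive)`
#' @export
annotate_model_variants <- function(model_entries, gwas_summary,
                                    config = analysis_config()) {
  p <- gwas_summary$p[match(model_entries$variant_id, gwas_summary$variant_id)]
  c(n_model = nrow(model_entries),
    n_gws = sum(p <= config$gws_threshold, na.rm = TRUE),
    n_suggestive = sum(p < config$suggestive_threshold, na.rm = TRUE))
}

#' Per-gene summary across tissues
#'
#' Counts the tissues in which each gene is significant and identifies the
#' strongest-effect tissue: the tissue with the highest absolute effect size
#' over all records of the gene (ties broken by smaller p, then by
#' lexicographic tissue name).
#'
#' @param records association records with columns `gene`, `tissue`, `beta`,
#'   `p`, `q`, `significant`
#' @return data.frame (`gene`, `n_significant_tissues`,
#'   `strongest_effect_tissue`, `strongest_beta`) over all genes in
#'   `records`
#' @export
summarize_genes <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(gene = character(), n_significant_tissues = integer(),
                      strongest_effect_tissue = character(),
                      strongest_beta = numeric()))
  ord <- order(records$gene, -abs(records$beta), records$p, records$tissue)
  rec <- records[ord, , drop = FALSE]
  first <- !duplicated(rec$gene)
  strongest <- rec[first, c("gene", "tissue", "beta")]
  n_sig <- tapply(records$significant & !duplicated(paste(records$gene,
                                                          records$tissue)),
                  records$gene, sum)
  out <- data.frame(gene = strongest$gene,
                    n_significant_tissues =
                      as.integer(n_sig[strongest$gene]),
                    strongest_effect_tissue = strongest$tissue,
                    strongest_beta = strongest$beta,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
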