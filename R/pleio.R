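#' Linkage disequilibrium r-squared between two panel variants
#'
#' Squared Pearson correlation of the two dosage vectors across samples;
#' defined as 0 when either vector is constant.
#'
#' @param panel a [dosage_panel()] (the LD reference)
#' @param variant_a,variant_b variant ids
#' @return r-squared in \[0, 1\]
#' @export
ld_r2 <- function(panel, variant_a, variant_b) {
  for (v in c(variant_a, variant_b))
    if (!v %in% panel$variants$id) stop2("variant absent from panel: ", v)
  x <- panel$dosages[, variant_a]
  y <- panel$dosages[, variant_b]
  if (length(x) < 2L) stop2("need at least 2 samples to compute r2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Build the R-squared locus of one GWAS lead variant
#'
#' The locus spans the minimum to maximum position of all panel variants on
#' the lead's chromosome, within `search_window_bp` of it, whose dosage
#' r-squared with the lead strictly exceeds `r2_threshold`. The lead itself
#' always qualifies (r-squared 1), so the locus is at least a single
#' position. A lead absent from the panel falls back to a single-position
#' locus at its own coordinate (logged).
#'
#' @param panel LD reference [dosage_panel()]
#' @param lead_id lead variant id
#' @param r2_threshold strict lower bound, default 0.5
#' @param search_window_bp LD search bound around the lead (default 2 Mb)
#' @param trait trait label carried by the locus
#' @param lead_chrom,lead_pos fallback coordinates when the lead is absent
#'   from the panel
#' @return one-row [locus_table()]
#' @export
build_r2_locus <- function(panel, lead_id, r2_threshold = 0.5,
                           search_window_bp = 2e6, trait = ".",
                           lead_chrom = NULL, lead_pos = NULL) {
  v <- panel$variants
  li <- match(lead_id, v$id)
  if (is.na(li)) {
    if (is.null(lead_chrom) || is.null(lead_pos))
      stop2("lead variant absent from panel: ", lead_id)
    log_event("pleio", "lead_absent_from_panel", lead = lead_id)
    return(locus_table(lead_chrom, lead_pos, lead_pos, traits = trait))
  }
  cand <- which(v$chrom == v$chrom[li] &
                  abs(v$pos - v$pos[li]) <= search_window_bp)
  x <- panel$dosages[, li]
  if (stats::sd(x) == 0) {
    linked <- li
  } else {
    cm <- panel$dosages[, cand, drop = FALSE]
    sds <- apply(cm, 2L, stats::sd)
    r2 <- rep(0, length(cand))
    ok <- sds > 0
    if (any(ok)) r2[ok] <- as.vector(stats::cor(x, cm[, ok, drop = FALSE]))^2
    linked <- cand[r2 > r2_threshold]
    linked <- union(linked, li)
  }
  locus_table(v$chrom[li], min(v$pos[linked]), max(v$pos[linked]),
              traits = trait)
}

#' Build R-squared loci for every lead of every trait
#'
#' @param panel LD reference [dosage_panel()]
#' @param leads named list (by trait) of lead data.frames (`variant_id`,
#'   `chrom`, `pos`)
#' @param categories trait-to-category map data.frame (`trait`, `category`);
#'   loci carry their trait's category
#' @param r2_threshold,search_window_bp passed to [build_r2_locus()]
#' @return [locus_table()] with one row per lead (unmerged)
#' @export
build_trait_loci <- function(panel, leads, categories = NULL,
                             r2_threshold = 0.5, search_window_bp = 2e6) {
  rows <- list()
  for (trait in names(leads)) {
    ld <- leads[[trait]]
    cat_lab <- if (!is.null(categories)) {
      hit <- categories$category[match(trait, categories$trait)]
      if (is.na(hit)) trait else hit
    } else trait
    for (i in seq_len(nrow(ld))) {
      loc <- build_r2_locus(panel, ld$variant_id[i], r2_threshold,
                            search_window_bp, trait = trait,
                            lead_chrom = ld$chrom[i], lead_pos = ld$pos[i])
      loc$categories <- cat_lab
      rows[[length(rows) + 1L]] <- loc
    }
  }
  if (length(rows) == 0L) return(locus_table(character(), integer(), integer()))
  out <- do.call(rbind, rows)
  locus_table(out$chrom, out$start, out$end, out$traits, out$categories)
}

#' Merge overlapping loci into pleiotropic regions
#'
#' Per chromosome, the transitive union of intervals sharing at least one bp
#' (1-based inclusive, so `[100,200]` and `[200,300]` merge). A merged locus
#' carries the union of the traits and categories of its members. Output is
#' sorted by (chrom, start).
#'
#' @param loci a [locus_table()]
#' @return merged [locus_table()]
#' @export
merge_loci <- function(loci) {
  if (nrow(loci) == 0L) return(loci)
  out <- list()
  for (cc in sort(unique(loci$chrom))) {
    sub <- loci[loci$chrom == cc, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start, end = sub$end)
    # min.gapwidth = 0: merge only intervals sharing >= 1 bp, not adjacent ones
    red <- IRanges::reduce(ir, with.revmap = TRUE, min.gapwidth = 0L)
    revmap <- S4Vectors::mcols(red)$revmap
    traits <- vapply(revmap, function(ii)
      join_labels(unlist(split_labels(sub$traits[ii]))), character(1))
    cats <- vapply(revmap, function(ii)
      join_labels(unlist(split_labels(sub$categories[ii]))), character(1))
    out[[cc]] <- data.frame(chrom = cc, start = IRanges::start(red),
                            end = IRanges::end(red), traits = traits,
                            categories = cats, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  locus_table(res$chrom, res$start, res$end, res$traits, res$categories)
}

#' Extend loci by a window and re-merge
#'
#' Each locus is expanded by `window_bp` on both sides (start clamped at 1)
#' and overlapping extended loci are merged, mirroring the cis-window
#' convention of the prediction models (variants up to 1 Mb from a gene).
#'
#' @param loci a [locus_table()]
#' @param window_bp extension on each side, default 1 Mb
#' @return merged [locus_table()] of extended loci
#' @export
extend_loci <- function(loci, window_bp = 1e6) {
  if (nrow(loci) == 0L) return(loci)
  ext <- locus_table(loci$chrom,
                     pmax(1, loci$start - window_bp),
                     loci$end + window_bp,
                     loci$traits, loci$categories)
  merge_loci(ext)
}

#' Assign genes to trait-category loci by positional overlap
#'
#' A gene is assigned every category of every locus its span intersects
#' (at least one shared bp). Genes overlapping loci of two or more distinct
#' categories are flagged potentially pleiotropic.
#'
#' @param loci a [locus_table()] (typically merged)
#' @param annotation gene annotation data.frame
#' @return data.frame (`gene`, `categories` (`;`-joined), `n_categories`,
#'   `in_any_locus`, `pleiotropic`) over all annotated genes
#' @export
overlap_genes <- function(loci, annotation) {
  n <- nrow(annotation)
  cats <- rep(".", n); ncat <- integer(n); inloc <- logical(n)
  if (nrow(loci) > 0L && n > 0L) {
    gr_gene <- GenomicRanges::GRanges(annotation$chrom,
                                      IRanges::IRanges(annotation$start,
                                                       annotation$end))
    gr_loc <- GenomicRanges::GRanges(loci$chrom,
                                     IRanges::IRanges(loci$start, loci$end))
    hits <- GenomicRanges::findOverlaps(gr_gene, gr_loc)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      loc_cats <- unlist(split_labels(loci$categories[sh[qh == i]]))
      cats[i] <- join_labels(loc_cats)
      ncat[i] <- length(unique(loc_cats))
      inloc[i] <- TRUE
    }
  }
  data.frame(gene = annotation$gene, categories = cats, n_categories = ncat,
             in_any_locus = inloc, pleiotropic = ncat >= 2L,
             stringsAsFactors = FALSE)
}

#' Fisher-exact enrichment of a gene list in one category's loci
#'
#' Builds the 2x2 table with rows \{disease-associated genes, other
#' predictable genes\} and columns \{overlaps a locus of the category, does
#' not\}, and applies the two-sided Fisher exact test for count data (the
#' two-sided p sums all hypergeometric tables with point probability at or
#' below the observed one, the convention of [stats::fisher.test()]). The
#' odds ratio reported is the sample (cross-product) odds ratio of the
#' table.
#'
#' @param disease_genes character vector, subset of `all_genes`
#' @param all_genes comparison universe (all predictable genes)
#' @param overlap_table output of [overlap_genes()]
#' @param category category label to test
#' @return list: `table` (named counts a, b, c, d), `odds_ratio`, `p`
#' @export
category_enrichment <- function(disease_genes, all_genes, overlap_table,
                                category) {
  if (!all(disease_genes %in% all_genes))
    stop2("disease_genes must be a subset of all_genes")
  has_cat <- vapply(split_labels(overlap_table$categories),
                    function(v) category %in% v, logical(1))
  in_cat <- overlap_table$gene[has_cat]
  other <- setdiff(all_genes, disease_genes)
  a <- sum(disease_genes %in% in_cat)
  b <- length(disease_genes) - a
  c_ <- sum(other %in% in_cat)
  d <- length(other) - c_
  tab <- matrix(c(a, c_, b, d), nrow = 2)
  p <- if (sum(tab) == 0L || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    1 else stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (a * d) / (b * c_)
  list(table = c(a = a, b = b, c = c_, d = d),
       odds_ratio = or, p = p)
}

#' Enrichment across every category in an overlap table
#'
#' @inheritParams category_enrichment
#' @return data.frame (`category`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`)
#'   sorted by category
#' @export
category_enrichment_all <- function(disease_genes, all_genes, overlap_table) {
  cats <- sort(unique(unlist(split_labels(overlap_table$categories))))
  rows <- lapply(cats, function(cat) {
    e <- category_enrichment(disease_genes, all_genes, overlap_table, cat)
    data.frame(category = cat, a = e$table[["a"]], b = e$table[["b"]],
               c = e$table[["c"]], d = e$table[["d"]],
               odds_ratio = e$odds_ratio, p = e$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(category = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), odds_ratio = numeric(),
               p = numeric())
  rownames(out) <- NULL
  out
}

#' Compare significant-tissue counts between in-locus and out-of-locus genes
#'
#' Two-sided Mann–Whitney U test of `n_significant_tissues` between genes
#' that overlap at least one locus and genes that do not. The null is exact
#' (full enumeration) when the combined n is at most 25 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param gene_summary output of [summarize_genes()] (needs
#'   `n_significant_tissues`)
#' @param overlap_table output of [overlap_genes()] (needs `in_any_locus`)
#' @return list: `U` (statistic for the in-locus group), `p`,
#'   `n_in`, `n_out`
#' @export
tissue_count_comparison <- function(gene_summary, overlap_table) {
  inloc <- overlap_table$in_any_locus[match(gene_summary$gene,
                                            overlap_table$gene)]
  if (anyNA(inloc))
    stop2("gene(s) missing from overlap table: ",
          paste(utils::head(gene_summary$gene[is.na(inloc)], 3),
                collapse = ", "))
  x <- gene_summary$n_significant_tissues[inloc]
  y <- gene_summary$n_significant_tissues[!inloc]
  if (length(x) == 0L || length(y) == 0L)
    stop2("both gene groups (in-locus / out-of-locus) must be non-empty")
  no_ties <- !any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 25L && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_in = length(x), n_out = length(y))
}
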