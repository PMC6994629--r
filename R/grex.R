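#' Fill missing dosages with the modal genotype
#'
#' Expression imputation needs a complete dosage matrix, so missing
#' genotypes of single individuals are filled by the most frequent genotype
#' of that variant: non-missing dosages are rounded (half away from zero) to
#' the nearest integer genotype in \{0, 1, 2\}, the modal genotype is taken
#' (ties broken toward the lower genotype), and each missing cell receives
#' that value. Non-missing cells are untouched.
#'
#' @param panel a [dosage_panel()]
#' @return a [dosage_panel()] without missing cells; the input is returned
#'   unchanged when it has none
#' @export
fill_missing_dosages <- function(panel) {
  stopifnot(inherits(panel, "dosage_panel"))
  D <- panel$dosages
  if (!anyNA(D)) return(panel)
  miss_by_col <- colSums(is.na(D))
  all_missing <- miss_by_col == nrow(D)
  if (any(all_missing))
    stop2("variant(s) with all dosages missing: ",
          paste(panel$variants$id[all_missing], collapse = ", "))
  for (j in which(miss_by_col > 0L)) {
    d <- D[, j]
    geno <- pmin(pmax(round_half_up(d[!is.na(d)], 0), 0), 2)
    counts <- tabulate(geno + 1L, nbins = 3L)  # counts for genotypes 0,1,2
    modal <- which.max(counts) - 1L            # which.max -> first max = lower genotype
    D[is.na(d), j] <- modal
  }
  out <- panel
  out$dosages <- D
  out
}

#' Resolve allele orientation between a weight entry and a panel variant
#'
#' A model entry's weight applies to its effect allele. If the effect allele
#' is the panel's alternate allele the dosage is used as-is (`"identity"`);
#' if effect/non-effect match the panel's ref/alt the effect-allele dosage is
#' `2 - d` (`"flip"`); any other allele pair is incompatible and the entry is
#' dropped (`"drop"`).
#'
#' @param effect_allele,non_effect_allele alleles from the weight entry
#' @param ref,alt alleles of the matching panel variant
#' @return character vector over \{"identity", "flip", "drop"\}, vectorized
#'   over its arguments
#' @export
harmonize_alleles <- function(effect_allele, non_effect_allele, ref, alt) {
  out <- rep("drop", length(effect_allele))
  out[effect_allele == alt & non_effect_allele == ref] <- "identity"
  out[effect_allele == ref & non_effect_allele == alt] <- "flip"
  out
}

#' Impute genetically regulated expression for one tissue
#'
#' PrediXcan-style scoring: for each gene, the genetically regulated
#' expression of sample i is the weighted sum of harmonized effect-allele
#' dosages over the gene's model entries present in the panel,
#' `sum_k w_k * d_ik`. Entries whose variant is absent from the panel are
#' dropped; entries with incompatible alleles are dropped with a warning;
#' genes with no usable entry are omitted. No intercept or normalization is
#' applied — association downstream is scale-equivariant.
#'
#' @param panel a complete [dosage_panel()] (apply [fill_missing_dosages()]
#'   first)
#' @param weights a `weight_table` data.frame (see [read_weight_table()])
#' @param tissue tissue label to impute
#' @return numeric matrix samples x genes with attribute `tissue`; attribute
#'   `dropped_entries` counts allele-incompatible entries
#' @export
impute_expression <- function(panel, weights, tissue) {
  stopifnot(inherits(panel, "dosage_panel"))
  if (anyNA(panel$dosages))
    stop2("panel contains missing dosages; apply fill_missing_dosages() first")
  w <- as.data.frame(weights)
  if (!tissue %in% w$tissue)
    stop2("tissue '", tissue, "' absent from weight table")
  w <- w[w$tissue == tissue, , drop = FALSE]

  vi <- match(w$variant_id, panel$variants$id)
  present <- !is.na(vi)
  w <- w[present, , drop = FALSE]
  vi <- vi[present]

  orient <- harmonize_alleles(w$effect_allele, w$non_effect_allele,
                              panel$variants$ref[vi], panel$variants$alt[vi])
  n_dropped <- sum(orient == "drop")
  if (n_dropped > 0)
    warning(n_dropped, " weight entr", if (n_dropped == 1) "y" else "ies",
            " with incompatible alleles dropped (tissue ", tissue, ")",
            call. = FALSE)
  keep <- orient != "drop"
  w <- w[keep, , drop = FALSE]; vi <- vi[keep]; orient <- orient[keep]

  genes <- sort(unique(w$gene))
  all_genes <- sort(unique(weights$gene[weights$tissue == tissue]))
  omitted <- setdiff(all_genes, genes)
  if (length(omitted))
    log_event("grex", "genes_without_panel_variants", tissue = tissue,
              n = length(omitted))
  n <- length(panel$samples)
  if (length(genes) == 0L) {
    out <- matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(panel$samples, character()))
    attr(out, "tissue") <- tissue
    attr(out, "dropped_entries") <- n_dropped
    return(out)
  }
  gi <- match(w$gene, genes)
  # flipped entries score w*(2-d) = -w*d + 2w: sign-flip the weight and add
  # a per-gene constant offset
  sgn <- ifelse(orient == "flip", -1, 1)
  offset <- vapply(seq_along(genes), function(g)
    2 * sum(w$weight[gi == g & orient == "flip"]), numeric(1))
  W <- Matrix::sparseMatrix(i = vi, j = gi, x = sgn * w$weight,
                            dims = c(nrow(panel$variants), length(genes)))
  E <- as.matrix(panel$dosages %*% W)
  E <- sweep(E, 2L, -offset)  # adds offset
  dimnames(E) <- list(panel$samples, genes)
  attr(E, "tissue") <- tissue
  attr(E, "dropped_entries") <- n_dropped
  E
}
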