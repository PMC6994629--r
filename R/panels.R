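#' Dosage panel: samples x variants effect-allele dosages
#'
#' The genetic substrate of every pipeline stage. Dosages are expected counts
#' of the alternate allele per sample, in \[0, 2\]; missing genotypes are `NA`
#' (never silently 0 — missing-fill is an explicit, separate step, see
#' [fill_missing_dosages()]).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`; one row per variant, ids unique.
#' @param samples character vector of unique sample ids.
#' @param dosages numeric matrix, `length(samples)` rows x `nrow(variants)`
#'   columns; values in \[0,2\] or `NA`.
#' @return an object of class `dosage_panel`: a list with elements
#'   `variants`, `samples`, `dosages` (dimnames set to sample and variant ids).
#' @export
dosage_panel <- function(variants, samples, dosages) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols))
    stop2("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  variants <- variants[needed]
  variants$pos <- as.integer(variants$pos)
  samples <- as.character(samples)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"

  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants))
    stop2("dosage matrix is ", nrow(dosages), " x ", ncol(dosages),
          " but panel has ", length(samples), " samples and ",
          nrow(variants), " variants")
  if (anyDuplicated(samples))
    stop2("duplicate sample ids: ",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (nrow(variants) > 0) {
    if (anyDuplicated(variants$id))
      stop2("duplicate variant ids: ",
            paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
    if (any(variants$pos < 1L))
      stop2("variant positions must be >= 1 (1-based coordinates)")
    same <- variants$ref == variants$alt
    if (any(same))
      stop2("ref and alt allele identical for variant(s): ",
            paste(variants$id[same], collapse = ", "))
  }
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop2("dosage out of [0,2]: value ", dosages[bad][1], " at sample '",
          samples[idx[1]], "', variant '", variants$id[idx[2]], "'")
  }
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(variants = variants, samples = samples, dosages = dosages),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$dosages))
  cat(sprintf("dosage_panel: %d samples x %d variants (%d missing cells)\n",
              length(x$samples), nrow(x$variants), n_miss))
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosages)

#' Subset a dosage panel by sample and/or variant indices
#' @param x a `dosage_panel`
#' @param i sample index (logical/integer/character)
#' @param j variant index (logical/integer/character)
#' @param ... ignored
#' @export
`[.dosage_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(j)) j <- match(j, x$variants$id)
  dosage_panel(x$variants[j, , drop = FALSE],
               x$samples[i],
               x$dosages[i, j, drop = FALSE])
}
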