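read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop2("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop2(what, " file ", path, " lacks column(s): ",
          paste(missing_cols, collapse = ", "))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a per-tissue expression prediction weight table
#'
#' Expects a TSV with columns `tissue`, `gene`, `variant_id`, `effect_allele`,
#' `non_effect_allele`, `weight` — the flattened content of PredictDB-style
#' prediction models (one row per model variant). Each (tissue, gene) group
#' is one prediction model.
#'
#' @param path TSV file
#' @return a data.frame of class `weight_table` with the columns above,
#'   `weight` numeric.
#' @export
read_weight_table <- function(path) {
  cols <- c("tissue", "gene", "variant_id", "effect_allele",
            "non_effect_allele", "weight")
  df <- read_tsv_checked(path, cols, "weight table")
  df <- df[cols]
  w <- suppressWarnings(as.numeric(df$weight))
  bad <- is.na(w) & !is.na(df$weight)
  if (any(bad))
    stop2("non-numeric weight(s) in ", path, ": ",
          paste(utils::head(df$weight[bad], 3), collapse = ", "))
  if (anyNA(w)) stop2("missing weight(s) in ", path)
  df$weight <- w
  key <- paste(df$tissue, df$gene, df$variant_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), c("tissue", "gene", "variant_id")][1, ]
    stop2("duplicate weight row for tissue=", d$tissue, " gene=", d$gene,
          " variant=", d$variant_id)
  }
  class(df) <- c("weight_table", "data.frame")
  df
}

#' @rdname read_weight_table
#' @param weights a `weight_table` data.frame
#' @export
write_weight_table <- function(weights, path) {
  write_tsv_plain(as.data.frame(weights), path)
}

#' Number of prediction models in a weight table
#'
#' One model per distinct (tissue, gene) pair.
#' @param weights a `weight_table`
#' @return integer count
#' @export
n_weight_models <- function(weights) {
  nrow(unique(as.data.frame(weights)[c("tissue", "gene")]))
}

#' Read the cohort phenotype/covariate table
#'
#' TSV with columns `sample_id`, `status` (0 = control, 1 = case), `sex`
#' (0/1 or F/M), `age` (years), `pc1`, `pc2` (genotype principal components).
#'
#' @param path TSV file
#' @return data.frame with those columns; `status` integer in \{0,1\}.
#' @export
read_cohort_table <- function(path) {
  cols <- c("sample_id", "status", "sex", "age", "pc1", "pc2")
  df <- read_tsv_checked(path, cols, "cohort")[cols]
  df$status <- as.integer(df$status)
  if (any(!df$status %in% c(0L, 1L)))
    stop2("status must be 0 (control) or 1 (case)")
  if (anyDuplicated(df$sample_id))
    stop2("duplicate sample ids in cohort table")
  for (col in c("age", "pc1", "pc2")) df[[col]] <- as.numeric(df[[col]])
  if (is.character(df$sex)) df$sex <- as.integer(factor(df$sex)) - 1L
  df$sex <- as.numeric(df$sex)
  df
}

#' @rdname read_cohort_table
#' @param cohort cohort data.frame
#' @export
write_cohort_table <- function(cohort, path) write_tsv_plain(cohort, path)

#' Read GWAS summary statistics for one trait
#'
#' TSV with columns `variant_id`, `chrom`, `pos`, `p`. P-values must lie in
#' (0, 1].
#'
#' @param path TSV file
#' @param trait trait label attached to the result (defaults to the file
#'   name stem)
#' @return data.frame with columns `variant_id`, `chrom`, `pos`, `p` and
#'   attribute `trait`.
#' @export
read_gwas_summary <- function(path, trait = NULL) {
  df <- read_tsv_checked(path, c("variant_id", "chrom", "pos", "p"),
                         "GWAS summary")
  df <- df[c("variant_id", "chrom", "pos", "p")]
  df$pos <- as.integer(df$pos)
  df$p <- as.numeric(df$p)
  if (any(is.na(df$p) | df$p <= 0 | df$p > 1))
    stop2("GWAS p-values must lie in (0, 1]: ", path)
  attr(df, "trait") <- trait %||% sub("\\.[^.]*$", "", basename(path))
  df
}

#' @rdname read_gwas_summary
#' @param gwas GWAS summary data.frame
#' @export
write_gwas_summary <- function(gwas, path) {
  write_tsv_plain(gwas[c("variant_id", "chrom", "pos", "p")], path)
}

#' Read gene annotation
#'
#' TSV with columns `gene`, `chrom`, `start`, `end`; 1-based inclusive
#' coordinates, `start <= end`.
#'
#' @param path TSV file
#' @return data.frame with those columns.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_checked(path, c("gene", "chrom", "start", "end"),
                         "gene annotation")
  df <- df[c("gene", "chrom", "start", "end")]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop2("gene annotation has start > end: ", path)
  if (any(df$start < 1L)) stop2("gene annotation has start < 1: ", path)
  if (anyDuplicated(df$gene)) stop2("duplicate gene ids in annotation: ", path)
  df
}

#' @rdname read_gene_annotation
#' @param annotation gene annotation data.frame
#' @export
write_gene_annotation <- function(annotation, path) {
  write_tsv_plain(annotation[c("gene", "chrom", "start", "end")], path)
}

#' Read a trait-to-category map
#'
#' TSV with columns `trait`, `category` — the manual grouping of traits into
#' disease/trait categories used by the pleiotropy analysis.
#' @param path TSV file
#' @return data.frame with columns `trait`, `category`.
#' @export
read_trait_categories <- function(path) {
  df <- read_tsv_checked(path, c("trait", "category"), "trait category map")
  df[c("trait", "category")]
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `term <tab> description <tab> gene...`.
#' @param path GMT file
#' @return named list of character vectors (gene ids), names are terms;
#'   descriptions kept in attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop2("GMT line(s) with fewer than 3 fields in ", path,
          " (line ", which(short)[1], ")")
  terms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(terms)) stop2("duplicate terms in GMT: ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- terms
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
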