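#' Locus table constructor
#'
#' A locus is a 1-based inclusive genomic interval annotated with the traits
#' whose GWAS signals define it and (after category assignment) their trait
#' categories. Traits/categories are stored as sorted `;`-joined labels.
#'
#' @param chrom,start,end vectors defining the intervals (1-based inclusive)
#' @param traits,categories character vectors of `;`-joined labels (or lists
#'   of character vectors)
#' @return data.frame of class `locus_table` with columns `chrom`, `start`,
#'   `end`, `traits`, `categories`.
#' @export
locus_table <- function(chrom, start, end,
                        traits = rep(".", length(chrom)),
                        categories = rep(".", length(chrom))) {
  if (is.list(traits)) traits <- vapply(traits, join_labels, character(1))
  if (is.list(categories)) categories <- vapply(categories, join_labels, character(1))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop2("locus with start > end")
  if (any(start < 1L)) stop2("locus start < 1 (coordinates are 1-based)")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   traits = as.character(traits),
                   categories = as.character(categories),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("locus_table", "data.frame")
  df
}

#' Write loci to BED
#'
#' Internal coordinates are 1-based inclusive; BED uses 0-based half-open, so
#' each interval `[start, end]` is written as `start-1, end`. The name column
#' carries the `;`-joined trait labels and the score column 0; categories go
#' in a 6th column when present.
#'
#' @param loci a [locus_table()]
#' @param path output BED file
#' @return `path`, invisibly
#' @export
write_locus_bed <- function(loci, path) {
  loci <- loci[order(loci$chrom, loci$start, loci$end), , drop = FALSE]
  if (nrow(loci) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(loci$chrom, loci$start - 1L, loci$end, loci$traits, 0L,
                 loci$categories, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read loci from BED
#'
#' Inverse of [write_locus_bed()]: shifts 0-based half-open BED intervals
#' back to the internal 1-based inclusive convention.
#'
#' @param path BED file
#' @return a [locus_table()]
#' @export
read_locus_bed <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(locus_table(character(), integer(), integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop2("BED line with fewer than 3 fields in ", path)
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[i] else default, character(1))
  locus_table(chrom = get(1, "."),
              start = as.integer(get(2, "0")) + 1L,
              end = as.integer(get(3, "0")),
              traits = get(4, "."),
              categories = get(6, "."))
}
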