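#' Read a dosage panel from VCF
#'
#' Reads a VCF whose genotype FORMAT carries a numeric per-sample dosage
#' field (PrediXcan-style input; typically `DS` from imputation). Values are
#' copied verbatim; missing entries (`.`) become `NA`. Multi-allelic records
#' are rejected — dosages are only meaningful against a single alternate
#' allele.
#'
#' @param path VCF file (plain text or gzipped).
#' @param dosage_field name of the per-sample FORMAT field, default `"DS"`.
#' @return a [dosage_panel()].
#' @export
read_dosage_vcf <- function(path, dosage_field = "DS") {
  if (!file.exists(path)) stop2("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(dosage_panel(
      data.frame(chrom = character(), pos = integer(), id = character(),
                 ref = character(), alt = character()),
      samples = colnames(vcf@gt)[-1] %||% character(),
      dosages = matrix(numeric(), nrow = length(colnames(vcf@gt)[-1]), ncol = 0)))

  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop2("multi-allelic record(s) not supported: ",
          paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))

  fmt <- vcf@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) dosage_field %in% f, logical(1))))
    stop2("FORMAT field '", dosage_field, "' absent from some records")
  ds <- vcfR::extract.gt(vcf, element = dosage_field, as.numeric = TRUE)
  # extract.gt returns variants x samples; panel convention is samples x variants
  ds <- t(ds)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"], ":",
                       fix[no_id, "REF"], ":", alt[no_id])
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = ids, ref = fix[, "REF"], alt = alt,
                         stringsAsFactors = FALSE)
  dosage_panel(variants, rownames(ds), ds)
}

#' Write a dosage panel as VCF
#'
#' Emits a minimal VCFv4.2 file with a single per-sample FORMAT field holding
#' the dosage. Missing dosages are written as `.`. Full precision is kept
#' (up to 15 significant digits) so that write-then-read round-trips exactly.
#'
#' @param panel a [dosage_panel()]
#' @param path output file
#' @param dosage_field FORMAT field name, default `"DS"`
#' @return `path`, invisibly
#' @export
write_dosage_vcf <- function(panel, path, dosage_field = "DS") {
  stopifnot(inherits(panel, "dosage_panel"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"Effect allele dosage\">",
            dosage_field),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t"))
  v <- panel$variants
  fmt_ds <- function(j) {
    d <- panel$dosages[, j]
    out <- vapply(d, function(x) if (is.na(x)) "." else format(x, digits = 15),
                  character(1))
    out
  }
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", ".", ".",
            dosage_field, fmt_ds(j)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, sep = "\n", useBytes = TRUE)
  invisible(path)
}
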