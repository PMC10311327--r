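# Plain-text VCF 4.2 emission and phased-panel ingestion.  Reading goes
# through vcfR; writing is simple fixed-column formatting.

write_vcf <- function(variants, gt, path, contigs = NULL, gq = NULL) {
  stopifnot(nrow(variants) == nrow(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  fmt <- "GT"
  if (!is.null(gq)) {
    writeLines('##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">', con)
    fmt <- "GT:GQ"
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(gt)), collapse = "\t"), con)
  cells <- gt
  if (!is.null(gq)) cells <- matrix(paste(gt, gq, sep = ":"), nrow = nrow(gt))
  if (nrow(variants)) {
    body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                  ".", "PASS", ".", fmt, sep = "\t")
    body <- paste(body, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a phased panel VCF
#'
#' Parses a multi-sample VCF with phased `GT` fields into the variant table
#' and a per-haplotype allele-index matrix (two haplotype columns per
#' sample).  Records with any missing or unphased genotype are dropped, as
#' are genotype-free records.
#'
#' @param path VCF file (plain or gzipped).
#' @return List with `variants` (chrom/pos/ref/alt data frame; `alt` may be
#'   a comma-separated multi-allelic list), `hap` (integer matrix, sites x
#'   haplotypes) and `haplotypes` (column names, `<sample>_1/2`).
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt[, -1L, drop = FALSE]
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = 1L)
  gt <- sub(":.*$", "", gt_raw)
  phased <- apply(gt, 1L, function(row)
    all(grepl("^[0-9]+\\|[0-9]+$", row)))
  variants <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)[phased, , drop = FALSE]
  gt <- gt[phased, , drop = FALSE]
  samples <- colnames(v@gt)[-1L]
  hap <- matrix(0L, nrow = nrow(gt), ncol = 2L * length(samples))
  if (nrow(gt)) {
    parts <- strsplit(as.vector(gt), "|", fixed = TRUE)
    a1 <- matrix(as.integer(vapply(parts, `[[`, "", 1L)), nrow = nrow(gt))
    a2 <- matrix(as.integer(vapply(parts, `[[`, "", 2L)), nrow = nrow(gt))
    hap[, seq(1L, ncol(hap), 2L)] <- a1
    hap[, seq(2L, ncol(hap), 2L)] <- a2
  }
  colnames(hap) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  rownames(variants) <- NULL
  list(variants = variants, hap = hap, haplotypes = colnames(hap))
}

#' Read a single-sample VCF as a callset data frame
#'
#' @param path VCF file.
#' @return Data frame `chrom`, `pos`, `ref`, `alt`, `gt` (`NA` for `./.`).
#' @export
read_callset_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- sub(":.*$", "", v@gt[, 2L])
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt %in% c("./.", ".")] <- NA_character_
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"], gt = gt,
             stringsAsFactors = FALSE, row.names = NULL)
}
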