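## VCF subset I/O for the haploid SNP matrices: CHROM POS REF ALT with
## per-sample GT (haploid 0/1) and DP. Reading goes through vcfR; writing is
## plain formatting of the v4.2 subset.

#' Write a haploid SNP matrix as a VCF (v4.2 subset)
#'
#' Emits CHROM, POS, ID (.), REF/ALT (A/T placeholders -- the analysis is
#' allele-agnostic), QUAL/FILTER (./PASS), empty INFO, and per-sample
#' `GT:DP` with haploid genotypes.
#'
#' @param m an `sg_genomat`.
#' @param path file path.
#' @export
write_vcf_subset <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", m$chrom, m$chrom_length),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", m$sample_ids), collapse = "\t")), con)
  if (ncol(m$geno)) {
    gt <- matrix(paste(m$geno, m$depth, sep = ":"), nrow = nrow(m$geno))
    lines <- vapply(seq_along(m$positions), function(j)
      paste(c(m$chrom, m$positions[j], ".", "A", "T", ".", "PASS", ".",
              "GT:DP", gt[, j]), collapse = "\t"), character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a haploid SNP matrix from a VCF
#'
#' Parses a VCF (via [vcfR::read.vcfR()]) carrying haploid GT and DP fields
#' back into an `sg_genomat`.
#'
#' @param path VCF file path.
#' @param group group label to attach.
#' @param chrom_length chromosome length; defaults to the contig header
#'   length if present, else the maximum position.
#' @return an `sg_genomat`.
#' @export
read_vcf_subset <- function(path, group = "unknown", chrom_length = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  geno <- t(apply(gt_chr, 2, as.integer))
  depth <- t(dp)
  chrom <- as.character(v@fix[1, "CHROM"])
  pos <- as.integer(v@fix[, "POS"])
  if (is.null(chrom_length)) {
    meta <- grep("^##contig", v@meta, value = TRUE)
    len <- regmatches(meta, regexpr("length=[0-9]+", meta))
    chrom_length <- if (length(len)) as.integer(sub("length=", "", len[1]))
                    else max(pos)
  }
  sample_ids <- colnames(gt_chr)
  rownames(geno) <- sample_ids
  rownames(depth) <- sample_ids
  structure(list(chrom = chrom, chrom_length = as.integer(chrom_length),
                 positions = pos, geno = geno,
                 depth = matrix(as.integer(depth), nrow = nrow(depth),
                                dimnames = list(sample_ids, NULL)),
                 sample_ids = sample_ids, group = group),
            class = "sg_genomat")
}
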