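#' Write a SNP call table as VCF 4.2
#'
#' Sites are written on scaffold coordinates (1-based) with per-sample
#' `GT:DP:GQ` fields. Genotypes `"AA"/"AB"/"BB"` map to `0/0`, `0/1`, `1/1`;
#' missing calls become `./.`.
#'
#' @param snps A [snp_table()].
#' @param path Output file path.
#' @param contig_lengths Optional named vector of scaffold lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, contig_lengths = NULL) {
  samples <- snp_samples(snps)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=radanchor",
    '##INFO=<ID=.,Number=0,Type=Flag,Description="None">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  gt_code <- matrix(c("0/0", "0/1", "1/1")[match(snps$gt, c("AA", "AB", "BB"))],
                    nrow(snps), length(samples))
  gt_code[is.na(gt_code)] <- "./."
  dp <- snps$dp
  dp_chr <- ifelse(is.na(dp), ".", as.character(dp))
  gq <- snps$gq
  gq_chr <- ifelse(is.na(gq), ".", as.character(gq))
  cells <- matrix(paste(gt_code, dp_chr, gq_chr, sep = ":"),
                  nrow(snps), length(samples))
  ids <- if ("marker_id" %in% names(snps)) snps$marker_id else "."
  body <- paste(snps$scaffold_id, snps$pos, ids, snps$ref, snps$alt,
                format(snps$qual, trim = TRUE), "PASS", ".", "GT:DP:GQ",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a SNP call table
#'
#' Parses a VCF 4.2 file with `vcfR` and converts it to the package's
#' [snp_table()] layout. Only `GT`, `DP` and `GQ` per-sample fields are
#' retained. Genotypes other than diploid biallelic combinations of allele
#' 0 and allele 1 become `NA`; multiallelic and indel sites are kept (their
#' allele strings flag them for the site filters).
#'
#' @param path VCF file path.
#' @return A [snp_table()] tibble; a `marker_id` column carries the VCF ID
#'   field when present.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  code <- gsub("|", "/", gt_raw, fixed = TRUE)
  gt <- matrix(NA_character_, nrow(code), ncol(code), dimnames = dimnames(code))
  gt[code %in% "0/0"] <- "AA"
  gt[code %in% c("0/1", "1/0")] <- "AB"
  gt[code %in% "1/1"] <- "BB"
  sites <- tibble(
    scaffold_id = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = as.numeric(fix$QUAL)
  )
  if (!all(is.na(fix$ID)) && !all(fix$ID == ".")) sites$marker_id <- fix$ID
  storage.mode(dp) <- "integer"
  storage.mode(gq) <- "integer"
  rownames(gt) <- NULL
  rownames(dp) <- NULL
  rownames(gq) <- NULL
  snp_table(sites, gt, dp, gq)
}

#' Write a depth, phenotype or other result table as TSV
#' @param x Data frame. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header
#' @param path File path.
#' @return A tibble.
#' @export
read_tsv_file <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE))
}
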