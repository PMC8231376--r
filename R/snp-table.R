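#' Build a SNP call table
#'
#' The package's central genotype container: a tibble with one row per site
#' and matrix columns holding per-sample calls, so the table pipes through
#' dplyr verbs while keeping the sites-by-samples layout needed for
#' filtering and mapping. Genotypes are coded relative to the VCF alleles:
#' `"AA"` homozygous reference, `"AB"` heterozygous, `"BB"` homozygous
#' alternate, `NA` missing.
#'
#' @param sites Data frame with columns `scaffold_id`, `pos` (1-based),
#'   `ref`, `alt`, `qual`.
#' @param gt Character matrix (sites x samples) of `"AA"/"AB"/"BB"/NA` calls
#'   with sample ids as column names.
#' @param dp,gq Optional integer matrices of per-call depth and genotype
#'   quality, same shape as `gt`.
#' @return A tibble with scalar site columns plus matrix columns `gt`, `dp`,
#'   `gq`, sorted by `(scaffold_id, pos)`.
#' @export
snp_table <- function(sites, gt, dp = NULL, gq = NULL) {
  sites <- as_tibble(sites)
  stopifnot(all(c("scaffold_id", "pos", "ref", "alt", "qual") %in% names(sites)),
            is.matrix(gt), nrow(gt) == nrow(sites), !is.null(colnames(gt)))
  if (any(sites$pos < 1)) abort("positions must be >= 1 (VCF convention)")
  ok <- is.na(gt) | gt %in% c("AA", "AB", "BB")
  if (!all(ok)) abort("genotype calls must be AA/AB/BB or NA")
  if (is.null(dp)) dp <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  stopifnot(identical(dim(dp), dim(gt)), identical(dim(gq), dim(gt)))
  out <- sites
  out$gt <- gt
  out$dp <- dp
  out$gq <- gq
  arrange(out, .data$scaffold_id, .data$pos)
}

#' Sample identifiers of a SNP call table
#' @param snps A table built by [snp_table()].
#' @return Character vector of sample ids.
#' @export
snp_samples <- function(snps) colnames(snps$gt)

# internal: is a site an indel / multiallelic, judged from allele strings
site_is_indel <- function(ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)
  nchar(ref) != 1L | vapply(alts, function(a) any(nchar(a) != 1L), logical(1))
}

site_is_biallelic <- function(alt) !grepl(",", alt, fixed = TRUE)
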