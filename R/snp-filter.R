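#' Site-filter profiles for ddRAD-seq SNPs
#'
#' Two tiers mirroring common VCFtools usage in reduced-representation
#' genotyping: a `stringent` profile (call rate >= 0.95, site quality >= 20,
#' per-call depth in \[20, 200\], minor-allele frequency >= 0.025, biallelic
#' SNPs only) and a `less_stringent` profile (call rate >= 0.80, depth
#' >= 10 with no upper bound, otherwise identical).
#'
#' @param name `"stringent"` or `"less_stringent"`.
#' @return A list of class `"filter_profile"` with elements `name`,
#'   `max_missing` (call-rate floor), `min_quality`, `min_depth`,
#'   `max_depth` (`Inf` when absent), `min_maf`, `biallelic_only`,
#'   `exclude_indels`.
#' @export
filter_profile <- function(name = c("stringent", "less_stringent")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(paste0("unknown profile: ", name[1]),
                                             class = "radanchor_input_error"))
  p <- switch(name,
    stringent = list(max_missing = 0.95, min_quality = 20, min_depth = 20,
                     max_depth = 200, min_maf = 0.025),
    less_stringent = list(max_missing = 0.80, min_quality = 20, min_depth = 10,
                          max_depth = Inf, min_maf = 0.025)
  )
  structure(c(list(name = name), p,
              list(biallelic_only = TRUE, exclude_indels = TRUE)),
            class = "filter_profile")
}

#' Apply a site-filter profile to a SNP call table
#'
#' Depth bounds act per genotype call: calls with depth outside
#' `[min_depth, max_depth]` are set missing *before* the call-rate test,
#' matching the semantics of per-genotype depth flags in standard VCF
#' filtering tools. A site then passes if its non-missing call fraction is
#' at least `max_missing`, its site quality is at least `min_quality`, its
#' minor-allele frequency (computed from the retained calls, optionally on a
#' sample subset) is at least `min_maf`, it is biallelic, and it is not an
#' indel.
#'
#' @param snps A [snp_table()].
#' @param profile A [filter_profile()] or a profile name.
#' @param maf_samples Optional character vector of sample ids over which the
#'   minor-allele frequency is computed (e.g. the F2 individuals); default
#'   all samples.
#' @return The passing subset of `snps`, with the depth-masked genotype
#'   matrix, carrying an `"audit"` attribute: a tibble of every input site
#'   and the first rule it failed (`NA` for passing sites).
#' @export
apply_site_filters <- function(snps, profile = filter_profile("stringent"),
                               maf_samples = NULL) {
  if (is.character(profile)) profile <- filter_profile(profile)
  stopifnot(inherits(profile, "filter_profile"))
  gt <- snps$gt
  dp <- snps$dp
  # depth bounds per call; unknown depth is left alone
  bad_dp <- !is.na(dp) & !is.na(gt) & (dp < profile$min_depth | dp > profile$max_depth)
  gt[bad_dp] <- NA_character_

  call_rate <- rowMeans(!is.na(gt))
  maf_cols <- if (is.null(maf_samples)) seq_len(ncol(gt)) else {
    stopifnot(all(maf_samples %in% colnames(gt)))
    match(maf_samples, colnames(gt))
  }
  sub <- gt[, maf_cols, drop = FALSE]
  n_alt <- rowSums(sub == "BB", na.rm = TRUE) * 2 + rowSums(sub == "AB", na.rm = TRUE)
  n_called <- rowSums(!is.na(sub))
  p_alt <- ifelse(n_called > 0, n_alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)

  indel <- site_is_indel(snps$ref, snps$alt)
  biallelic <- site_is_biallelic(snps$alt)

  fail <- rep(NA_character_, nrow(snps))
  fail[is.na(fail) & profile$exclude_indels & indel] <- "indel"
  fail[is.na(fail) & profile$biallelic_only & !biallelic] <- "not_biallelic"
  fail[is.na(fail) & !(snps$qual >= profile$min_quality)] <- "site_quality"
  fail[is.na(fail) & call_rate < profile$max_missing] <- "call_rate"
  fail[is.na(fail) & (is.na(maf) | maf < profile$min_maf)] <- "maf"

  out <- snps
  out$gt <- gt
  out <- out[is.na(fail), , drop = FALSE]
  attr(out, "audit") <- tibble(scaffold_id = snps$scaffold_id, pos = snps$pos,
                               failed_rule = fail)
  attr(out, "profile") <- profile$name
  out
}

#' Keep sites informative for an F2 cross
#'
#' Retains sites where both parents are homozygous for *different* alleles
#' and the F1 is heterozygous — the configuration under which F2 genotypes
#' can be polarised by parental origin. Sites with a missing parental or F1
#' call are dropped (not an error).
#'
#' @param snps A [snp_table()].
#' @param p1,p2,f1 Sample ids of the two parents and the F1.
#' @return The informative subset of `snps`.
#' @export
apply_genotype_filter <- function(snps, p1 = "P1", p2 = "P2", f1 = "F1") {
  samples <- snp_samples(snps)
  missing_samples <- setdiff(c(p1, p2, f1), samples)
  if (length(missing_samples) > 0) {
    abort(paste0("samples not in call table: ", paste(missing_samples, collapse = ", ")),
          class = "radanchor_input_error")
  }
  g1 <- snps$gt[, p1]
  g2 <- snps$gt[, p2]
  gf <- snps$gt[, f1]
  keep <- !is.na(g1) & !is.na(g2) & !is.na(gf) &
    g1 %in% c("AA", "BB") & g2 %in% c("AA", "BB") & g1 != g2 & gf == "AB"
  snps[keep, , drop = FALSE]
}

#' Thin sites to a minimum physical spacing
#'
#' Greedy left-to-right per scaffold: the first site is kept, then each
#' subsequent site whose position is at least `interval_bp` beyond the last
#' kept site. Thinning an already-thinned set is the identity.
#'
#' @param snps A [snp_table()] (or any tibble with `scaffold_id`, `pos`).
#' @param interval_bp Spacing floor in bp (default 800000, i.e. ~0.8 Mb).
#' @return The thinned subset.
#' @export
thin_by_interval <- function(snps, interval_bp = 800000) {
  if (nrow(snps) == 0) return(snps)
  ord <- order(snps$scaffold_id, snps$pos)
  keep_idx <- logical(nrow(snps))
  last_scaf <- ""
  last_pos <- -Inf
  for (i in ord) {
    if (snps$scaffold_id[i] != last_scaf ||
        snps$pos[i] >= last_pos + interval_bp) {
      keep_idx[i] <- TRUE
      last_scaf <- snps$scaffold_id[i]
      last_pos <- snps$pos[i]
    }
  }
  snps[keep_idx, , drop = FALSE]
}

#' Merge two SNP site sets, removing redundant sites
#'
#' Union keyed by `(scaffold_id, pos)`; a site present in both sets
#' contributes once, preferring the copy from `set_a` (by convention the
#' stringent set). Identical keys with conflicting alleles are an error.
#'
#' @param set_a,set_b [snp_table()] tibbles with identical sample columns.
#' @return The merged table, sorted by `(scaffold_id, pos)`.
#' @export
merge_and_dedupe <- function(set_a, set_b) {
  if (nrow(set_a) == 0) return(set_b)
  if (nrow(set_b) == 0) return(set_a)
  key_a <- paste(set_a$scaffold_id, set_a$pos)
  key_b <- paste(set_b$scaffold_id, set_b$pos)
  shared <- intersect(key_a, key_b)
  if (length(shared) > 0) {
    ia <- match(shared, key_a)
    ib <- match(shared, key_b)
    if (any(set_a$ref[ia] != set_b$ref[ib] | set_a$alt[ia] != set_b$alt[ib])) {
      abort("conflicting alleles at shared sites", class = "radanchor_input_error")
    }
  }
  if (!identical(colnames(set_a$gt), colnames(set_b$gt))) {
    abort("sample columns differ between the two sets",
          class = "radanchor_input_error")
  }
  out <- bind_rows(set_a, set_b[!(key_b %in% key_a), , drop = FALSE])
  for (cc in intersect(c("gt", "dp", "gq"), names(out))) {
    colnames(out[[cc]]) <- colnames(set_a[[cc]])  # bind_rows drops dimnames
  }
  arrange(out, .data$scaffold_id, .data$pos)
}

#' Chi-square segregation test against an expected ratio
#'
#' Pearson chi-square of observed genotype (or phenotype-class) counts
#' against expected proportions, without continuity or multiple-testing
#' correction; `df = classes - 1`. A marker passes when `p > alpha`.
#'
#' @param counts Non-negative integer vector of observed class counts.
#' @param expected_ratio Expected ratio, same length (default `c(1, 2, 1)`
#'   for F2 codominant segregation; use `c(3, 1)` for a dominant binary
#'   trait).
#' @param alpha Significance level (default 0.001).
#' @return One-row tibble: `chi_square`, `df`, `p_value`, `pass`.
#' @export
#' @examples
#' segregation_test(c(25, 50, 25))            # perfect 1:2:1
#' segregation_test(c(60, 22), c(3, 1))       # 3:1 dominant trait
segregation_test <- function(counts, expected_ratio = c(1, 2, 1), alpha = 0.001) {
  stopifnot(length(counts) == length(expected_ratio), all(counts >= 0))
  if (sum(counts) == 0) {
    abort("total count is zero", class = "radanchor_input_error")
  }
  ht <- suppressWarnings(
    chisq.test(counts, p = expected_ratio / sum(expected_ratio), correct = FALSE)
  )
  tibble(chi_square = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), pass = unname(ht$p.value) > alpha)
}

#' Per-marker 1:2:1 segregation test over F2 samples
#'
#' @param snps A [snp_table()].
#' @param f2_samples Character vector of F2 sample ids (default: all samples
#'   whose ids start with `"F2"`).
#' @param alpha Significance level (default 0.001, no multiple-testing
#'   correction).
#' @return Tibble with one row per site: `scaffold_id`, `pos`, observed
#'   counts `n_AA`, `n_AB`, `n_BB`, `chi_square`, `df`, `p_value`, `pass`.
#' @export
test_segregation <- function(snps, f2_samples = NULL, alpha = 0.001) {
  samples <- snp_samples(snps)
  if (is.null(f2_samples)) f2_samples <- grep("^F2", samples, value = TRUE)
  sub <- snps$gt[, f2_samples, drop = FALSE]
  n_aa <- rowSums(sub == "AA", na.rm = TRUE)
  n_ab <- rowSums(sub == "AB", na.rm = TRUE)
  n_bb <- rowSums(sub == "BB", na.rm = TRUE)
  res <- purrr::pmap(list(n_aa, n_ab, n_bb), function(a, h, b) {
    segregation_test(c(a, h, b), c(1, 2, 1), alpha)
  }) |> purrr::list_rbind()
  bind_cols(tibble(scaffold_id = snps$scaffold_id, pos = snps$pos,
                   n_AA = n_aa, n_AB = n_ab, n_BB = n_bb), res)
}
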