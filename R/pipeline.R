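#' Run the full synthetic-study pipeline
#'
#' Executes every stage in order on data generated from `config`:
#' simulation, male/female depth screening of Y-linked scaffolds, the
#' two-tier SNP filter cascade with parental/F1 genotype filtering, interval
#' thinning, redundancy merging and 1:2:1 segregation testing, linkage-map
#' construction, chimera-aware scaffold anchoring into pseudomolecules, QTL
#' scans for the quantitative and binary traits, and gene confidence
#' classification. Writes every intermediate as a plain-text file under
#' `outdir` and returns the in-memory results plus a manifest of file
#' digests, so reruns with an equal config are reproducible bit-for-bit.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param n_genes Genes in the synthetic evidence table (default 2000).
#' @param n_perm Permutations for the QTL significance threshold
#'   (default 1000).
#' @param qtl_method `"cim"` (default) or `"hk"`.
#' @param thin_interval_bp Spacing floor for the less-stringent tier
#'   (default 800000).
#' @param seg_alpha Segregation-test significance level (default 0.001).
#' @param map_function Map function for cM distances.
#' @return A list of class `"pipeline_run"` with elements `genome`,
#'   `depths`, `sex`, `snps`, `map`, `segments`, `pseudo`, `qtl`,
#'   `classes`, `report`, `manifest`, `config`.
#' @export
run_pipeline <- function(config, outdir = tempfile("radanchor_run_"),
                         n_genes = 2000, n_perm = 1000,
                         qtl_method = c("cim", "hk"),
                         thin_interval_bp = 800000, seg_alpha = 0.001,
                         map_function = c("kosambi", "haldane")) {
  qtl_method <- match.arg(qtl_method)
  map_function <- match.arg(map_function)
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  stage_of <- c()
  emit <- function(stage, name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files <<- c(files, path)
    stage_of <<- c(stage_of, stage)
    path
  }

  # -- simulate ----------------------------------------------------------
  genome <- simulate_genome(config)
  depths <- simulate_depths(genome, config)
  f2 <- simulate_f2(genome, config)
  phen <- simulate_phenotypes(f2, config)
  evidence <- simulate_gene_evidence(n_genes, seed = config$seed)
  emit("simulate", "depths.tsv", function(p) write_tsv_file(depths, p))
  contig_lengths <- setNames(genome$scaffolds$length, genome$scaffolds$scaffold_id)
  vcf_path <- emit("simulate", "calls.vcf",
                   function(p) write_vcf(f2$calls, p, contig_lengths))
  emit("simulate", "phenotypes.tsv", function(p) write_tsv_file(phen, p))
  emit("simulate", "gene_evidence.tsv", function(p) write_tsv_file(evidence, p))
  emit("simulate", "truth_agp.tsv",
       function(p) write_tsv_file(genome$truth$agp, p))

  # -- sexfilter ---------------------------------------------------------
  sex <- classify_sex_scaffolds(depths)
  retained <- filter_sex_scaffolds(genome$scaffolds, sex)
  emit("sexfilter", "sex_classification.tsv", function(p) write_tsv_file(sex, p))

  # -- snpfilter ---------------------------------------------------------
  calls <- read_snp_vcf(vcf_path)
  calls <- filter(calls, .data$scaffold_id %in% retained$scaffold_id)
  f2_ids <- grep("^F2", snp_samples(calls), value = TRUE)
  strict <- apply_site_filters(calls, "stringent", maf_samples = f2_ids) |>
    apply_genotype_filter()
  loose <- apply_site_filters(calls, "less_stringent", maf_samples = f2_ids) |>
    apply_genotype_filter()
  thinned <- thin_by_interval(loose, thin_interval_bp)
  merged <- merge_and_dedupe(strict, thinned)
  seg <- test_segregation(merged, f2_ids, alpha = seg_alpha)
  informative <- merged[seg$pass, , drop = FALSE]
  emit("snpfilter", "sites_merged.vcf",
       function(p) write_vcf(informative, p, contig_lengths))
  emit("snpfilter", "segregation.tsv", function(p) write_tsv_file(seg, p))

  # -- map ---------------------------------------------------------------
  coded <- code_genotypes(informative)
  map <- build_linkage_map(coded$geno, coded$markers,
                           map_function = map_function)
  emit("map", "genetic_map.tsv", function(p) write_tsv_file(as_tibble(map), p))

  # -- anchor ------------------------------------------------------------
  assignments <- assign_scaffolds(map, retained)
  chim <- detect_chimeras(assignments)
  segments <- split_and_segment(retained, assignments, chim, map = map)
  pseudo <- build_pseudomolecules(segments, genome$sequences,
                                  total_input_bp = sum(retained$length))
  emit("anchor", "pseudomolecules.agp", function(p) write_agp(pseudo$agp, p))
  emit("anchor", "chromosome_summary.tsv",
       function(p) write_tsv_file(pseudo$summary, p))
  if (!is.null(pseudo$sequences)) {
    emit("anchor", "pseudomolecules.fasta",
         function(p) Biostrings::writeXStringSet(pseudo$sequences, p))
  }

  # -- qtl ---------------------------------------------------------------
  probs <- genotype_probs(map, coded$geno, step_cm = 1)
  qtl_rows <- list()
  scans <- list()
  for (tr in c("bolting", "prickly")) {
    scan <- scan_qtl(probs, phen, trait = tr, method = qtl_method,
                     geno = coded$geno, map = map)
    thr <- permutation_threshold(probs, phen, trait = tr, n_perm = n_perm,
                                 seed = config$seed)
    df <- as_tibble(scan)
    for (k in unique(df$lg_index)) {
      sub <- df[df$lg_index == k, ]
      if (max(sub$lod) >= thr) {
        ci <- lod_support_interval(scan, lg = sub$lg[1], map = map,
                                   agp = pseudo$agp)
        ci$trait <- tr
        ci$threshold <- unname(thr)
        ci$pve <- pve_from_lod(ci$peak_lod, attr(scan, "n"))
        qtl_rows[[length(qtl_rows) + 1]] <- ci
      }
    }
    scans[[tr]] <- scan
    emit("qtl", paste0("lod_", tr, ".tsv"), function(p) write_tsv_file(df, p))
  }
  qtl <- if (length(qtl_rows)) purrr::list_rbind(qtl_rows) |>
    select("trait", dplyr::everything()) else tibble()
  emit("qtl", "qtl_summary.tsv", function(p) write_tsv_file(qtl, p))
  parental <- attr(phen, "parental")
  par_test <- exact_rank_sum(parental$bolting[parental$line == "P1"],
                             parental$bolting[parental$line == "P2"])
  shape_counts <- c(sum(phen$prickly == 1), sum(phen$prickly == 0))
  shape_seg <- segregation_test(shape_counts, c(3, 1), alpha = 0.05)

  # -- classify ----------------------------------------------------------
  classes <- classify_genes(evidence)
  class_report <- classification_report(classes)
  emit("classify", "gene_classes.tsv", function(p) write_tsv_file(classes, p))

  manifest <- tibble(stage = stage_of, file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  report <- list(
    sex = attr(sex, "report"),
    n_sites_stringent = nrow(strict),
    n_sites_less_stringent = nrow(loose),
    n_sites_thinned = nrow(thinned),
    n_sites_merged = nrow(merged),
    n_sites_segregating = nrow(informative),
    map_summary = map_summary(map),
    n_chimeric = dplyr::n_distinct(chim$scaffold_id),
    chromosome_summary = pseudo$summary,
    qtl = qtl,
    parental_rank_sum = par_test,
    shape_segregation = bind_cols(tibble(n_dominant = shape_counts[1],
                                         n_recessive = shape_counts[2]),
                                  shape_seg),
    gene_classes = class_report
  )
  structure(list(genome = genome, depths = depths, sex = sex,
                 snps = informative, map = map, segments = segments,
                 pseudo = pseudo, qtl = qtl, scans = scans,
                 classes = classes, phenotypes = phen,
                 report = report, manifest = manifest,
                 config = config, outdir = outdir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat("<pipeline_run>\n")
  cat(sprintf("  scaffolds: %d in, %d Y-linked removed\n",
              r$sex$n_input, r$sex$n_y_linked))
  cat(sprintf("  sites: %d stringent, %d less-stringent (%d thinned), %d merged, %d segregating\n",
              r$n_sites_stringent, r$n_sites_less_stringent,
              r$n_sites_thinned, r$n_sites_merged, r$n_sites_segregating))
  cat(sprintf("  map: %d markers in %d groups, %.1f cM\n",
              sum(r$map_summary$n_markers), nrow(r$map_summary),
              sum(r$map_summary$length_cm)))
  cat(sprintf("  anchoring: %d chimeric scaffolds, %d pseudomolecules\n",
              r$n_chimeric, nrow(r$chromosome_summary)))
  cat(sprintf("  qtl: %d significant peak(s)\n",
              if (nrow(r$qtl)) nrow(r$qtl) else 0L))
  cat(sprintf("  genes: %d HC / %d LC / %d TE\n",
              r$gene_classes$n_HC, r$gene_classes$n_LC, r$gene_classes$n_TE))
  invisible(x)
}
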