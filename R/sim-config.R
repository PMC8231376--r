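#' Simulation configuration for a synthetic ddRAD-seq F2 study
#'
#' Bundles every knob of the synthetic-data generator: a small
#' multi-chromosome genome fragmented into scaffolds (some chimeric, some
#' Y-linked), an F2 cross genotyped at SNP markers, male/female read-depth
#' summaries, and phenotypes controlled by planted QTLs. The defaults emulate
#' a dioecious leafy-crop study design: two inbred parents crossed to give a
#' single F1, selfed to 101 F2 individuals, six chromosomes, roughly 2,000
#' informative SNP markers, and a genetic map of about 410 cM.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Integer vector of chromosome lengths in bp.
#' @param n_scaffolds Number of scaffolds the genome is fragmented into.
#' @param chimera_fraction Proportion of scaffolds formed by joining pieces
#'   of two different chromosomes (scaffolding errors).
#' @param inversion_fraction Proportion of scaffold pieces stored in reverse
#'   orientation relative to the chromosome.
#' @param n_f2 Number of F2 individuals.
#' @param marker_density Markers per Mb of genome.
#' @param genotyping_error_rate Per-call probability that a genotype is
#'   flipped to one of the other two classes.
#' @param missing_rate Per-call probability that an F2 genotype is masked
#'   (parents and the F1 are sequenced at higher depth and are not masked).
#' @param mean_depth Mean per-call read depth for F2 individuals; parents and
#'   the F1 are drawn at `parental_depth_factor` times this value.
#' @param parental_depth_factor Depth multiplier for parents/F1 (pooled
#'   libraries).
#' @param depth_model `"poisson"` or `"nbinom"` for per-call depth draws.
#' @param nbinom_size Dispersion parameter when `depth_model = "nbinom"`.
#' @param y_scaffold_fraction Proportion of scaffolds flagged Y-linked.
#' @param cm_per_mb Uniform recombination rate (centimorgan per Mb).
#' @param qtl_spec Data frame with columns `chrom`, `pos`, `additive`,
#'   `dominance` describing planted QTLs for the quantitative trait.
#'   Effects are in trait units; genotypes are coded as copies of the P2
#'   allele, so the genetic value is `additive * (g - 1) + dominance * (g == 1)`.
#' @param heritability Proportion of quantitative-trait variance explained by
#'   the planted QTLs jointly.
#' @param trait_mean Baseline quantitative-trait mean (days to bolting).
#' @param binary_locus Length-2 numeric `(chrom, pos)`: the locus whose P1
#'   allele dominantly confers the binary phenotype (e.g. prickly seeds), so
#'   carriers : non-carriers segregate 3:1 in the F2.
#' @param with_sequence Generate actual A/C/G/T residues (feasible for small
#'   genomes); otherwise scaffolds carry lengths and coordinates only.
#' @param seed Integer seed; a fixed config is reproduced byte-identically.
#'
#' @return A validated list with class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chromosome_lengths = c(5e6, 4e6),
#'                   n_scaffolds = 10, n_f2 = 50, seed = 1)
sim_config <- function(n_chromosomes = 6,
                       chromosome_lengths = rep(40e6, n_chromosomes),
                       n_scaffolds = 112,
                       chimera_fraction = 0.25,
                       inversion_fraction = 0.5,
                       n_f2 = 101,
                       marker_density = 8.5,
                       genotyping_error_rate = 0.01,
                       missing_rate = 0.05,
                       mean_depth = 30,
                       parental_depth_factor = 4,
                       depth_model = c("poisson", "nbinom"),
                       nbinom_size = 10,
                       y_scaffold_fraction = 0.05,
                       cm_per_mb = 1.7,
                       qtl_spec = default_qtl_spec(),
                       heritability = 0.592,
                       trait_mean = 15.3,
                       binary_locus = c(1, 0.93 * chromosome_lengths[1]),
                       with_sequence = FALSE,
                       seed = 1L) {
  depth_model <- match.arg(depth_model)
  chromosome_lengths <- as.numeric(chromosome_lengths)
  stopifnot(length(chromosome_lengths) == n_chromosomes)
  props <- c(chimera_fraction = chimera_fraction,
             inversion_fraction = inversion_fraction,
             genotyping_error_rate = genotyping_error_rate,
             missing_rate = missing_rate,
             y_scaffold_fraction = y_scaffold_fraction)
  bad <- props < 0 | props > 1
  if (any(bad)) {
    abort(paste0("proportions must lie in [0, 1]: ",
                 paste(names(props)[bad], collapse = ", ")),
          class = "radanchor_config_error")
  }
  if (any(chromosome_lengths <= 0)) {
    abort("chromosome lengths must be positive", class = "radanchor_config_error")
  }
  if (n_scaffolds < n_chromosomes) {
    abort("need at least one scaffold per chromosome",
          class = "radanchor_config_error")
  }
  if (mean_depth <= 0) {
    abort("mean_depth must be positive", class = "radanchor_config_error")
  }
  qtl_spec <- as_tibble(qtl_spec)
  if (nrow(qtl_spec) > 0) {
    stopifnot(all(c("chrom", "pos", "additive", "dominance") %in% names(qtl_spec)))
    if (any(qtl_spec$chrom > n_chromosomes) ||
        any(qtl_spec$pos > chromosome_lengths[qtl_spec$chrom])) {
      abort("qtl_spec positions must lie on simulated chromosomes",
            class = "radanchor_config_error")
    }
    if (heritability <= 0 || heritability > 1) {
      abort("heritability must lie in (0, 1] when QTL effects are planted",
            class = "radanchor_config_error")
    }
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_lengths = chromosome_lengths,
    n_scaffolds = as.integer(n_scaffolds),
    chimera_fraction = chimera_fraction,
    inversion_fraction = inversion_fraction,
    n_f2 = as.integer(n_f2),
    marker_density = marker_density,
    genotyping_error_rate = genotyping_error_rate,
    missing_rate = missing_rate,
    mean_depth = mean_depth,
    parental_depth_factor = parental_depth_factor,
    depth_model = depth_model,
    nbinom_size = nbinom_size,
    y_scaffold_fraction = y_scaffold_fraction,
    cm_per_mb = cm_per_mb,
    qtl_spec = qtl_spec,
    heritability = heritability,
    trait_mean = trait_mean,
    binary_locus = binary_locus,
    with_sequence = isTRUE(with_sequence),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Default planted QTLs for the quantitative trait
#'
#' Three loci emulating a bolting-time architecture: one dominant
#' early-bolting locus on chromosome 2 and two additive loci on
#' chromosome 3, with effect sizes whose variance contributions are roughly
#' 32:20:8 percent of the phenotypic variance at the default heritability.
#'
#' @return A tibble with columns `chrom`, `pos`, `additive`, `dominance`.
#' @export
default_qtl_spec <- function() {
  tibble(
    chrom = c(2L, 3L, 3L),
    pos = c(20e6, 31e6, 9e6),
    additive = c(3.6, 3.5, 2.15),
    dominance = c(-3.6, 0, 0)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosomes, %.1f Mb total, %d scaffolds (%.0f%% chimeric, %.0f%% Y-linked)\n",
              x$n_chromosomes, sum(x$chromosome_lengths) / 1e6, x$n_scaffolds,
              100 * x$chimera_fraction, 100 * x$y_scaffold_fraction))
  cat(sprintf("  cross: %d F2, %.1f markers/Mb, error %.1f%%, missing %.1f%%, depth %.0fx\n",
              x$n_f2, x$marker_density, 100 * x$genotyping_error_rate,
              100 * x$missing_rate, x$mean_depth))
  cat(sprintf("  traits: %d QTL(s), h2 = %.2f; binary locus chr%d:%.0f\n",
              nrow(x$qtl_spec), x$heritability,
              x$binary_locus[1], x$binary_locus[2]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
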