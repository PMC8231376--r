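#' Simulate F2 phenotypes controlled by planted QTLs
#'
#' The quantitative trait (days to bolting) is the sum of the planted QTL
#' additive/dominance effects plus Gaussian noise scaled so the QTLs jointly
#' explain the configured heritability of the realised phenotypic variance.
#' The binary trait (prickly seed) is conferred dominantly by the P1 allele
#' at the configured locus, so F2 carriers : non-carriers segregate 3:1.
#' Each planted locus sits at its requested chromosome coordinate: its
#' genotype is sampled conditionally on the nearest simulated marker through
#' the no-interference transition at the intervening distance, so downstream
#' QTL scans can rediscover it without the locus coinciding with a marker.
#'
#' @param f2 A `"sim_f2"` from [simulate_f2()].
#' @param config A [sim_config()]; defaults to the cross's own config.
#' @return Tibble with columns `individual`, `bolting`, `prickly`, carrying
#'   an attribute `"qtl_truth"`: a tibble of the planted loci with their
#'   anchor markers (`marker_id`, `chrom`, `chrom_pos`, `cm`) and effects.
#' @export
simulate_phenotypes <- function(f2, config = f2$config) {
  stopifnot(inherits(f2, "sim_f2"))
  if (nrow(config$qtl_spec) > 0 &&
      (config$heritability <= 0 || config$heritability > 1)) {
    abort("heritability must lie in (0, 1] when QTL effects are planted",
          class = "radanchor_config_error")
  }
  set.seed(derive_seed(config$seed, 4L))
  g <- f2$truth_geno
  mk <- f2$markers
  n <- ncol(g)

  nearest_marker <- function(chrom, pos) {
    cand <- which(mk$chrom == chrom)
    if (length(cand) == 0) abort(sprintf("no marker on chromosome %d", chrom))
    cand[which.min(abs(mk$chrom_pos[cand] - pos))]
  }

  # the causal locus sits at its requested coordinate, not on a marker:
  # sample its genotype conditional on the nearest marker through the
  # no-interference genotype transition at the intervening distance
  locus_genotype <- function(j, chrom, pos) {
    d_cm <- abs(mk$chrom_pos[j] - pos) / 1e6 * config$cm_per_mb
    r <- 0.5 * (1 - exp(-2 * d_cm / 100))
    q <- 1 - r
    Tr <- matrix(c(q^2, 2 * r * q, r^2,
                   r * q, q^2 + r^2, r * q,
                   r^2, 2 * r * q, q^2), 3, 3, byrow = TRUE)
    vapply(g[j, ] + 1L, function(gg) {
      sample(0:2, 1, prob = Tr[gg, ])
    }, integer(1))
  }

  gv <- rep(0, n)
  truth_rows <- list()
  if (nrow(config$qtl_spec) > 0) {
    for (i in seq_len(nrow(config$qtl_spec))) {
      q <- config$qtl_spec[i, ]
      j <- nearest_marker(q$chrom, q$pos)
      gj <- locus_genotype(j, q$chrom, q$pos)
      gv <- gv + q$additive * (gj - 1) + q$dominance * (gj == 1)
      truth_rows[[i]] <- tibble(
        trait = "bolting", chrom = q$chrom, requested_pos = q$pos,
        marker_id = mk$marker_id[j], chrom_pos = mk$chrom_pos[j],
        cm = mk$cm[j], additive = q$additive, dominance = q$dominance,
        genotype = list(gj)
      )
    }
  }
  v_g <- var(gv)
  sigma_e <- if (v_g > 0) sqrt(v_g * (1 - config$heritability) / config$heritability) else 1
  bolting <- config$trait_mean + gv + rnorm(n, 0, sigma_e)

  j_bin <- nearest_marker(config$binary_locus[1], config$binary_locus[2])
  g_bin <- locus_genotype(j_bin, config$binary_locus[1], config$binary_locus[2])
  prickly <- as.integer(g_bin <= 1)  # >= 1 copy of the dominant P1 allele
  truth_rows[[length(truth_rows) + 1]] <- tibble(
    trait = "prickly", chrom = as.integer(config$binary_locus[1]),
    requested_pos = config$binary_locus[2],
    marker_id = mk$marker_id[j_bin], chrom_pos = mk$chrom_pos[j_bin],
    cm = mk$cm[j_bin], additive = NA_real_, dominance = NA_real_,
    genotype = list(g_bin)
  )

  out <- tibble(individual = colnames(g), bolting = bolting, prickly = prickly)
  attr(out, "qtl_truth") <- purrr::list_rbind(truth_rows)

  # parental-line and F1 replicates for the line comparison (the P1 line is
  # fixed for the early alleles, P2 for the late ones, the F1 heterozygous)
  if (nrow(config$qtl_spec) > 0) {
    gv_line <- c(P1 = -sum(config$qtl_spec$additive),
                 P2 = sum(config$qtl_spec$additive),
                 F1 = sum(config$qtl_spec$dominance))
  } else {
    gv_line <- c(P1 = 0, P2 = 0, F1 = 0)
  }
  n_rep <- c(P1 = 7L, P2 = 8L, F1 = 7L)
  attr(out, "parental") <- tibble(
    line = rep(names(n_rep), n_rep),
    individual = paste0(rep(names(n_rep), n_rep), "_",
                        unlist(lapply(n_rep, seq_len))),
    bolting = config$trait_mean + rep(gv_line, n_rep) +
      rnorm(sum(n_rep), 0, sigma_e)
  )
  out
}

#' Simulate a per-gene evidence table with known confidence classes
#'
#' Emits one row per transcript carrying homology-search statistics
#' (UniProtKB, NR, a reference proteome, Pfam), a transposable-element
#' keyword flag and a TPM expression value, constructed so each gene
#' realises a specific branch of the high-confidence / low-confidence /
#' transposable-element classification rule. Class proportions default to
#' roughly 56% HC, 39% LC and 5% TE, as seen in large plant annotation sets.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param class_probs Named numeric vector of sampling proportions for
#'   `HC`, `LC`, `TE`.
#' @return Tibble with one row per transcript: identifiers, prediction
#'   score, per-channel hit statistics (`NA` = no hit), `uniprot_te_keyword`,
#'   `tpm`, and the planted `true_class` (on every transcript of the gene).
#' @export
simulate_gene_evidence <- function(n_genes, seed = 1L,
                                   class_probs = c(HC = 0.556, LC = 0.392, TE = 0.052)) {
  stopifnot(n_genes > 0)
  set.seed(derive_seed(seed, 5L))
  classes <- sample(names(class_probs), n_genes, replace = TRUE,
                    prob = class_probs)
  genes <- sprintf("g%05d", seq_len(n_genes))

  rows <- purrr::map(seq_len(n_genes), function(i) {
    cls <- classes[i]
    n_tr <- sample(1:3, 1)
    score <- round(runif(n_tr, 10, 100), 2)
    best <- which.max(score)
    base <- tibble(
      gene_id = genes[i],
      transcript_id = sprintf("%s.t%d", genes[i], seq_len(n_tr)),
      prediction_score = score,
      uniprot_evalue = NA_real_, uniprot_identity = NA_real_,
      uniprot_te_keyword = FALSE,
      nr_evalue = NA_real_, nr_identity = NA_real_,
      sp_evalue = NA_real_, sp_identity = NA_real_,
      sp_coverage = NA_real_, sp_hsp_identity = NA_real_,
      pfam_evalue = NA_real_,
      tpm = 0,
      true_class = cls
    )
    b <- best
    if (cls == "TE") {
      base$uniprot_evalue[b] <- 10^runif(1, -120, -11)
      base$uniprot_identity[b] <- runif(1, 98, 100)
      base$uniprot_te_keyword[b] <- TRUE
      base$tpm[b] <- round(runif(1, 0, 80), 2)
    } else if (cls == "HC") {
      expressed_only <- runif(1) < 0.15
      if (expressed_only) {
        base$tpm[b] <- round(runif(1, 0.1, 200), 2)
      } else {
        ch <- sample(c("uniprot", "nr", "sp", "pfam"), sample(1:3, 1))
        if ("uniprot" %in% ch) {
          base$uniprot_evalue[b] <- 10^runif(1, -120, -11)
          base$uniprot_identity[b] <- runif(1, 98, 100)
        }
        if ("nr" %in% ch) {
          base$nr_evalue[b] <- 10^runif(1, -120, -11)
          base$nr_identity[b] <- runif(1, 95, 100)
        }
        if ("sp" %in% ch) {
          base$sp_evalue[b] <- 10^runif(1, -200, -51)
          base$sp_identity[b] <- runif(1, 98, 100)
          base$sp_coverage[b] <- runif(1, 90, 110)
          base$sp_hsp_identity[b] <- runif(1, 98, 100)
        }
        if ("pfam" %in% ch) base$pfam_evalue[b] <- 10^runif(1, -200, -81)
        base$tpm[b] <- round(max(0, runif(1, -20, 150)), 2)
      }
    } else {
      # LC: hits exist but fail at least one threshold, or no hits; TPM 0
      if (runif(1) < 0.5) {
        base$uniprot_evalue[b] <- 10^runif(1, -9, -1)
        base$uniprot_identity[b] <- runif(1, 40, 97)
        if (runif(1) < 0.5) {
          base$sp_evalue[b] <- 10^runif(1, -200, -51)
          base$sp_identity[b] <- runif(1, 98, 100)
          base$sp_coverage[b] <- runif(1, 30, 89)  # outside the coverage window
          base$sp_hsp_identity[b] <- runif(1, 98, 100)
        }
      }
      base$tpm[b] <- 0
    }
    base
  })
  purrr::list_rbind(rows)
}
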