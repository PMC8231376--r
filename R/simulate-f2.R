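#' Simulate an F2 cross genotyped at SNP markers
#'
#' Places markers along the chromosomes at the configured density, lifts
#' them onto scaffold coordinates through the genome truth, and simulates
#' two inbred parents, their F1, and F2 progeny. Each F2 individual is the
#' product of two independent meioses; crossovers follow a Poisson
#' (no-interference, Haldane) process along the genetic map, implemented as
#' a Markov chain over adjacent-marker recombination fractions
#' `r = (1 - exp(-2 d / 100)) / 2` for an interval of `d` cM. Genotyping
#' error flips calls; missingness masks F2 calls (parents and the F1 are
#' simulated at pooled-library depth and stay complete).
#'
#' @param genome A `"sim_genome"` from [simulate_genome()].
#' @param config A [sim_config()]; defaults to the genome's own config.
#' @return A list of class `"sim_f2"`:
#'   * `markers`: tibble with `marker_id`, `scaffold_id`, `pos` (scaffold bp),
#'     `chrom`, `chrom_pos`, `cm`, `ref`, `alt`, `p1_is_ref`;
#'   * `calls`: a [snp_table()] with samples `P1`, `P2`, `F1`, `F2_001`, ...;
#'   * `truth_geno`: error-free F2 genotype matrix (markers x individuals)
#'     coded as copies of the P2 allele (0 = P1 homozygote, 1 = het, 2 = P2
#'     homozygote), rownames = marker ids;
#'   * `config`.
#' @export
simulate_f2 <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(derive_seed(config$seed, 3L))
  agp <- genome$truth$agp
  y_ids <- genome$truth$y_scaffolds
  n_f2 <- config$n_f2

  marker_list <- purrr::map(seq_len(config$n_chromosomes), function(ch) {
    L <- config$chromosome_lengths[ch]
    n_m <- round(config$marker_density * L / 1e6)
    if (n_m == 0) {
      warn(sprintf("no markers on chromosome %d; it will be unmapped", ch))
      return(NULL)
    }
    tibble(chrom = ch, chrom_pos = sort(sample.int(L, n_m)))
  }) |> purrr::list_rbind()

  # lift chromosome positions onto scaffold coordinates through the truth AGP
  seg <- agp
  idx <- purrr::map_int(seq_len(nrow(marker_list)), function(i) {
    hit <- which(seg$chrom == marker_list$chrom[i] &
                   seg$chrom_start <= marker_list$chrom_pos[i] &
                   seg$chrom_end >= marker_list$chrom_pos[i])
    hit[1]
  })
  marker_list$scaffold_id <- seg$scaffold_id[idx]
  off <- marker_list$chrom_pos - seg$chrom_start[idx]
  marker_list$pos <- ifelse(seg$strand[idx] == "+",
                            seg$scaf_start[idx] + off,
                            seg$scaf_start[idx] + (seg$chrom_end[idx] - marker_list$chrom_pos))

  # markers falling on Y-flagged scaffolds are sex-linked and uninformative
  # in the female-referenced F2 map; drop them
  marker_list <- filter(marker_list, !(.data$scaffold_id %in% y_ids))
  marker_list$cm <- marker_list$chrom_pos / 1e6 * config$cm_per_mb
  m <- nrow(marker_list)
  marker_list$marker_id <- sprintf("mk%05d", seq_len(m))

  # meiosis: genotype = sum of two independent gametes per individual
  truth_geno <- matrix(0L, m, n_f2,
                       dimnames = list(marker_list$marker_id,
                                       sprintf("F2_%03d", seq_len(n_f2))))
  for (ch in unique(marker_list$chrom)) {
    rows <- which(marker_list$chrom == ch)
    d <- marker_list$cm[rows]
    g1 <- sim_gametes(d, n_f2)
    g2 <- sim_gametes(d, n_f2)
    truth_geno[rows, ] <- g1 + g2
  }

  # allele bookkeeping: random ref/alt bases, random parental polarity
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  p1_is_ref <- rbinom(m, 1, 0.5) == 1
  marker_list$ref <- ref
  marker_list$alt <- alt
  marker_list$p1_is_ref <- p1_is_ref

  # copies of the ALT allele per call, for parents, F1 and F2
  alt_copies_f2 <- truth_geno
  alt_copies_f2[!p1_is_ref, ] <- 2L - truth_geno[!p1_is_ref, , drop = FALSE]
  par_alt <- cbind(P1 = ifelse(p1_is_ref, 0L, 2L),
                   P2 = ifelse(p1_is_ref, 2L, 0L),
                   F1 = 1L)
  alt_copies <- cbind(par_alt, alt_copies_f2)
  samples <- c("P1", "P2", "F1", sprintf("F2_%03d", seq_len(n_f2)))
  colnames(alt_copies) <- samples

  gt <- matrix(c("AA", "AB", "BB")[alt_copies + 1L], m, length(samples),
               dimnames = list(NULL, samples))

  # genotyping error: flip to one of the other two classes
  if (config$genotyping_error_rate > 0) {
    err <- matrix(runif(length(gt)) < config$genotyping_error_rate, m, length(samples))
    if (any(err)) {
      cur <- gt[err]
      pick <- runif(sum(err)) < 0.5
      other <- t(vapply(cur, function(g) setdiff(c("AA", "AB", "BB"), g), character(2)))
      gt[err] <- ifelse(pick, other[, 1], other[, 2])
    }
  }
  # missingness: F2 calls only (parents/F1 come from pooled libraries)
  if (config$missing_rate > 0) {
    f2_cols <- which(samples %in% colnames(truth_geno))
    miss <- matrix(runif(m * length(f2_cols)) < config$missing_rate, m, length(f2_cols))
    gt[, f2_cols][miss] <- NA_character_
  }

  # per-call depth and genotype quality
  n_all <- m * length(samples)
  lam <- matrix(config$mean_depth, m, length(samples))
  lam[, 1:3] <- config$mean_depth * config$parental_depth_factor
  dp <- if (config$depth_model == "poisson") {
    matrix(rpois(n_all, lam), m, length(samples))
  } else {
    matrix(rnbinom(n_all, mu = lam, size = config$nbinom_size), m, length(samples))
  }
  colnames(dp) <- samples
  gq <- matrix(pmin(99L, rpois(n_all, 80)), m, length(samples), dimnames = list(NULL, samples))

  qual <- round(rlnorm(m, log(200), 1.2), 1)
  sites <- tibble(scaffold_id = marker_list$scaffold_id,
                  pos = marker_list$pos,
                  ref = ref, alt = alt, qual = qual,
                  marker_id = marker_list$marker_id)
  ord <- order(sites$scaffold_id, sites$pos)
  calls <- snp_table(sites[ord, ], gt[ord, , drop = FALSE],
                     dp[ord, , drop = FALSE], gq[ord, , drop = FALSE])

  structure(list(markers = marker_list, calls = calls,
                 truth_geno = truth_geno, config = config),
            class = "sim_f2")
}

# internal: simulate gamete haplotypes along one chromosome.
# d_cm: sorted marker positions in cM; returns 0/1 matrix (markers x gametes)
# where 1 = the P2-derived allele. Markov chain with Haldane-implied
# adjacent-interval recombination fractions.
sim_gametes <- function(d_cm, n_gametes) {
  m <- length(d_cm)
  first <- rbinom(n_gametes, 1, 0.5)
  if (m == 1) return(matrix(first, 1, n_gametes))
  r <- 0.5 * (1 - exp(-2 * diff(d_cm) / 100))
  sw <- matrix(rbinom((m - 1) * n_gametes, 1, r), m - 1, n_gametes)
  apply(rbind(first, sw), 2, cumsum) %% 2L
}
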