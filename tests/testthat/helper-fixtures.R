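# shared fixtures and independent oracles, built in code at test time

fixture_env <- new.env(parent = emptyenv())

# a small 3-chromosome cross reused across tests (memoised)
small_cross <- function() {
  if (is.null(fixture_env$cross)) {
    cfg <- sim_config(
      n_chromosomes = 3, chromosome_lengths = c(6e6, 5e6, 4e6),
      n_scaffolds = 20, chimera_fraction = 0.25, n_f2 = 80,
      marker_density = 30, cm_per_mb = 12,
      qtl_spec = tibble::tibble(chrom = 2L, pos = 3e6,
                                additive = 3, dominance = -3),
      binary_locus = c(1, 5.5e6), seed = 42
    )
    genome <- simulate_genome(cfg)
    f2 <- simulate_f2(genome, cfg)
    fixture_env$cross <- list(cfg = cfg, genome = genome, f2 = f2)
  }
  fixture_env$cross
}

# the full study-scale design (6 chromosomes, ~2,000 markers, 101 F2,
# 1% genotyping error, 5% missing), memoised: built once per test run
study_scale <- function() {
  if (is.null(fixture_env$study)) {
    cfg <- sim_config(seed = 101)
    genome <- simulate_genome(cfg)
    f2 <- simulate_f2(genome, cfg)
    coded <- code_genotypes(apply_genotype_filter(f2$calls))
    map <- build_linkage_map(coded$geno, coded$markers)
    # a thinned marker subset for scanning (every 4th marker in map order)
    df <- tibble::as_tibble(map)
    sub_map <- df |>
      dplyr::group_by(lg) |>
      dplyr::slice(seq(1, dplyr::n(), by = 4)) |>
      dplyr::ungroup()
    attr(sub_map, "map_function") <- attr(map, "map_function")
    class(sub_map) <- c("genetic_map", class(sub_map))
    probs <- genotype_probs(sub_map, coded$geno[sub_map$marker_id, ],
                            step_cm = 2)
    fixture_env$study <- list(cfg = cfg, genome = genome, f2 = f2,
                              coded = coded, map = map, probs = probs)
  }
  fixture_env$study
}

# build a snp_table from compact per-sample genotype vectors
make_snps <- function(gt_rows, dp = NULL, qual = 100,
                      scaffold = "scf1", pos = NULL,
                      ref = "A", alt = "T") {
  gt <- do.call(rbind, gt_rows)
  if (is.null(colnames(gt))) {
    colnames(gt) <- c("P1", "P2", "F1",
                      sprintf("F2_%03d", seq_len(ncol(gt) - 3)))
  }
  n <- nrow(gt)
  sites <- tibble::tibble(
    scaffold_id = rep_len(scaffold, n),
    pos = if (is.null(pos)) seq_len(n) * 100 else pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n)
  )
  dp_m <- if (is.null(dp)) matrix(50L, n, ncol(gt), dimnames = dimnames(gt))
  else matrix(as.integer(dp), n, ncol(gt), dimnames = dimnames(gt))
  snp_table(sites, gt, dp_m)
}

# exhaustive grid-search likelihood oracle for the F2 recombination fraction
rf_grid_oracle <- function(a, b, grid = seq(1e-6, 0.5, length.out = 5001)) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  counts <- table(factor(a, 0:2), factor(b, 0:2))
  ll <- vapply(grid, function(r) {
    q <- 1 - r
    p <- matrix(c(q^2 / 4, r * q / 2, r^2 / 4,
                  r * q / 2, (q^2 + r^2) / 2, r * q / 2,
                  r^2 / 4, r * q / 2, q^2 / 4), 3, 3, byrow = TRUE)
    sum(counts * log(pmax(p, 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}

# exhaustive best path through a distance matrix (sum of adjacent distances)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

path_cost <- function(path, D) sum(D[cbind(path[-length(path)], path[-1])])

best_path_cost <- function(D) {
  n <- nrow(D)
  min(vapply(all_permutations(n), path_cost, numeric(1), D = D))
}

# simulate a single F2 marker pair with true recombination fraction r
simulate_marker_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  g1a <- rbinom(n, 1, 0.5)
  g2a <- rbinom(n, 1, 0.5)
  g1b <- (g1a + rbinom(n, 1, r)) %% 2
  g2b <- (g2a + rbinom(n, 1, r)) %% 2
  list(a = g1a + g2a, b = g1b + g2b)
}
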