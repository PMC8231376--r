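test_that("config validation rejects bad proportions, lengths and QTL placement", {
  expect_error(sim_config(chimera_fraction = 1.2), class = "radanchor_config_error")
  expect_error(sim_config(n_chromosomes = 1, chromosome_lengths = -5,
                          qtl_spec = tibble::tibble()[0, ]),
               class = "radanchor_config_error")
  expect_error(sim_config(n_chromosomes = 2, chromosome_lengths = c(1e6, 1e6),
                          qtl_spec = tibble::tibble(chrom = 2L, pos = 5e6,
                                                    additive = 1, dominance = 0)),
               class = "radanchor_config_error")
  expect_error(sim_config(heritability = 0), class = "radanchor_config_error")
})

test_that("identity fragmentation returns the chromosomes themselves", {
  cfg <- sim_config(n_chromosomes = 3, chromosome_lengths = c(4e5, 3e5, 2e5),
                    n_scaffolds = 3, chimera_fraction = 0,
                    inversion_fraction = 0, y_scaffold_fraction = 0,
                    qtl_spec = tibble::tibble()[0, ], seed = 5)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$scaffolds), 3)
  expect_setequal(g$scaffolds$length, cfg$chromosome_lengths)
  agp <- g$truth$agp
  expect_equal(nrow(agp), 3)           # one fragment per scaffold
  expect_true(all(agp$chrom_start == 1))
  expect_true(all(agp$strand == "+"))
  expect_equal(sort(agp$chrom_end), sort(cfg$chromosome_lengths))
})

test_that("chimera fraction yields the exact number of two-chromosome scaffolds", {
  cfg <- sim_config(n_chromosomes = 4, chromosome_lengths = rep(5e6, 4),
                    n_scaffolds = 40, chimera_fraction = 0.25,
                    y_scaffold_fraction = 0,
                    qtl_spec = tibble::tibble()[0, ], seed = 9)
  g <- simulate_genome(cfg)
  n_chim <- g$truth$agp |>
    dplyr::group_by(scaffold_id) |>
    dplyr::summarise(k = dplyr::n_distinct(chrom)) |>
    dplyr::filter(k >= 2) |>
    nrow()
  expect_equal(n_chim, 10)
  # every scaffold base maps to exactly one chromosome interval
  expect_equal(sum(g$truth$agp$scaf_end - g$truth$agp$scaf_start + 1),
               sum(cfg$chromosome_lengths))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_lengths = c(5e5, 4e5),
                    n_scaffolds = 8, n_f2 = 30, marker_density = 40,
                    cm_per_mb = 60, with_sequence = TRUE,
                    qtl_spec = tibble::tibble()[0, ],
                    binary_locus = c(1, 2.5e5), seed = 3)
  run_once <- function() {
    g <- simulate_genome(cfg)
    f2 <- simulate_f2(g, cfg)
    d <- simulate_depths(g, cfg)
    fa <- tempfile(fileext = ".fa"); vcf <- tempfile(fileext = ".vcf")
    Biostrings::writeXStringSet(g$sequences, fa)
    write_vcf(f2$calls, vcf)
    list(fa = readLines(fa), vcf = readLines(vcf), d = d)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$fa, r2$fa)
  expect_identical(r1$vcf, r2$vcf)
  expect_identical(r1$d, r2$d)
})

test_that("depth model separates Y-linked from autosomal scaffolds", {
  cfg0 <- sim_config(n_chromosomes = 2, chromosome_lengths = c(2e6, 2e6),
                     n_scaffolds = 30, chimera_fraction = 0,
                     y_scaffold_fraction = 0,
                     qtl_spec = tibble::tibble()[0, ],
                     binary_locus = c(1, 1e6), seed = 4)
  d0 <- simulate_depths(simulate_genome(cfg0), cfg0)
  lr0 <- compute_log_ratio(d0$male_depth, d0$female_depth)
  expect_lt(max(abs(lr0)), 0.2)   # autosomes hug ratio 0

  cfg1 <- sim_config(n_chromosomes = 2, chromosome_lengths = c(2e6, 2e6),
                     n_scaffolds = 30, chimera_fraction = 0,
                     y_scaffold_fraction = 0.2, mean_depth = 30,
                     qtl_spec = tibble::tibble()[0, ],
                     binary_locus = c(1, 1e6), seed = 4)
  g1 <- simulate_genome(cfg1)
  d1 <- simulate_depths(g1, cfg1)
  y <- d1$scaffold_id %in% g1$truth$y_scaffolds
  lr1 <- compute_log_ratio(d1$male_depth, d1$female_depth)
  expect_true(all(lr1[y] > 0.2))           # far above the screen threshold
  expect_true(all(d1$female_depth[y] < 3)) # near the cross-mapping floor
})

test_that("adjacent-marker recombination matches the Haldane map function", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_lengths = 2e6,
                    n_scaffolds = 1, chimera_fraction = 0,
                    inversion_fraction = 0, y_scaffold_fraction = 0,
                    n_f2 = 500, marker_density = 10, cm_per_mb = 20,
                    genotyping_error_rate = 0, missing_rate = 0,
                    qtl_spec = tibble::tibble()[0, ],
                    binary_locus = c(1, 1e6), seed = 21)
  f2 <- simulate_f2(simulate_genome(cfg), cfg)
  mk <- f2$markers[order(f2$markers$chrom_pos), ]
  dcm <- diff(mk$cm)
  # the interval closest to 10 cM; its Haldane-implied recombination
  # fraction (~0.0906 at exactly 10 cM) is the calibration target
  j <- which.min(abs(dcm - 10))
  r_exp <- 0.5 * (1 - exp(-2 * dcm[j] / 100))
  est <- estimate_rf(f2$truth_geno[mk$marker_id[j], ],
                     f2$truth_geno[mk$marker_id[j + 1], ])
  se <- sqrt(r_exp * (1 - r_exp) / (2 * cfg$n_f2))
  expect_lt(abs(est$rf - r_exp), 3 * se)
})

test_that("error-free F2 genotypes are complete and segregate 1:2:1", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_lengths = c(3e6, 3e6),
                    n_scaffolds = 4, chimera_fraction = 0,
                    y_scaffold_fraction = 0, n_f2 = 101,
                    marker_density = 30, cm_per_mb = 15,
                    genotyping_error_rate = 0, missing_rate = 0,
                    qtl_spec = tibble::tibble()[0, ],
                    binary_locus = c(1, 1e6), seed = 8)
  f2 <- simulate_f2(simulate_genome(cfg), cfg)
  f2_cols <- grep("^F2", colnames(f2$calls$gt))
  expect_false(anyNA(f2$calls$gt[, f2_cols]))
  seg <- test_segregation(f2$calls, alpha = 0.001)
  expect_gte(mean(seg$pass), 0.99)
})

test_that("phenotypes respond to planted QTLs and are null without them", {
  cr <- small_cross()
  # near-perfect heritability rank-separates genotype classes at the QTL
  cfg_h1 <- cr$cfg
  cfg_h1$heritability <- 0.999
  ph <- simulate_phenotypes(cr$f2, cfg_h1)
  tr <- attr(ph, "qtl_truth")
  g <- tr$genotype[tr$trait == "bolting"][[1]]
  expect_true(max(ph$bolting[g == 0]) < min(ph$bolting[g == 2]))

  # dominant binary locus segregates ~3:1
  expect_gt(segregation_test(c(sum(ph$prickly == 1), sum(ph$prickly == 0)),
                             c(3, 1), alpha = 0.01)$p_value, 0.01)

  # no QTLs: phenotype independent of every marker
  cfg0 <- cr$cfg
  cfg0$qtl_spec <- cfg0$qtl_spec[0, ]
  ph0 <- simulate_phenotypes(cr$f2, cfg0)
  cors <- abs(cor(ph0$bolting, t(cr$f2$truth_geno)))
  expect_lt(max(cors), 4 / sqrt(cfg0$n_f2))
})

test_that("gene evidence realises each classification branch with truth labels", {
  ev <- simulate_gene_evidence(400, seed = 6)
  ev2 <- simulate_gene_evidence(400, seed = 6)
  expect_identical(ev, ev2)
  best <- select_best_transcript(ev)
  cls <- classify_genes(ev)
  merged <- dplyr::left_join(cls,
                             dplyr::distinct(ev[c("gene_id", "true_class")]),
                             by = "gene_id")
  expect_equal(merged$label, merged$true_class)
  te <- best[best$true_class == "TE", ]
  expect_true(all(te$uniprot_te_keyword))
})
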