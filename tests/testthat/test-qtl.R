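# small deterministic map + genotypes for probability checks
prob_fixture <- function() {
  map <- tibble::tibble(
    marker_id = c("mA", "mB"), scaffold_id = "s", pos = c(1e5, 9e5),
    lg = "LG1", lg_index = 1L, order = 1:2, cm = c(0, 20)
  )
  map <- structure(map, class = c("genetic_map", class(map)),
                   map_function = "haldane", n_individuals = 3)
  geno <- matrix(c(0L, 0L,   # ind1 AA/AA
                   1L, 1L,   # ind2 AB/AB
                   0L, NA),  # ind3 AA/missing
                 nrow = 2, ncol = 3,
                 dimnames = list(c("mA", "mB"), c("i1", "i2", "i3")))
  list(map = map, geno = geno)
}

test_that("genotype probabilities are degenerate at typed markers and exact between", {
  fx <- prob_fixture()
  pr <- genotype_probs(fx$map, fx$geno, step_cm = 10)
  grid <- pr$grid
  j_mid <- which(grid$cm == 10)
  jA <- which(grid$cm == 0)
  # typed marker, call AB -> (0, 1, 0)
  expect_equal(pr$prob[2, jA, ], c(0, 1, 0))
  # midpoint of a 20 cM interval with AA/AA flanks: product of two Haldane
  # transition rows, computed by hand
  r10 <- 0.5 * (1 - exp(-0.2))
  T10 <- matrix(c((1 - r10)^2, 2 * r10 * (1 - r10), r10^2,
                  r10 * (1 - r10), (1 - r10)^2 + r10^2, r10 * (1 - r10),
                  r10^2, 2 * r10 * (1 - r10), (1 - r10)^2), 3, 3, byrow = TRUE)
  w <- T10[1, ] * T10[, 1]
  expect_equal(pr$prob[1, j_mid, ], w / sum(w), tolerance = 1e-12)
  # one-sided conditioning when the right flank is missing
  expect_equal(pr$prob[3, j_mid, ], T10[1, ], tolerance = 1e-12)
  # step 0 puts probabilities only at the markers
  pr0 <- genotype_probs(fx$map, fx$geno, step_cm = 0)
  expect_equal(nrow(pr0$grid), 2)
  expect_false(anyNA(pr0$grid$marker_id))
})

test_that("a noiseless phenotype peaks exactly at its marker", {
  cr <- small_cross()
  coded <- code_genotypes(apply_genotype_filter(cr$f2$calls))
  map <- build_linkage_map(coded$geno, coded$markers)
  pr <- genotype_probs(map, coded$geno, step_cm = 2)
  m_target <- map$marker_id[[10]]
  g <- coded$geno[m_target, pr$individuals]
  y <- ifelse(is.na(g), NA, g - 1)  # exact additive function, no noise
  ph <- tibble::tibble(individual = pr$individuals, y = y)
  scan <- scan_qtl(pr, ph, trait = "y")
  peak <- as_tibble(scan)[which.max(scan$lod), ]
  target_cm <- as_tibble(map) |> dplyr::filter(marker_id == m_target)
  expect_equal(peak$lg, target_cm$lg)
  expect_equal(peak$cm, target_cm$cm)
  expect_error(scan_qtl(pr, tibble::tibble(individual = pr$individuals, y = 1),
                        trait = "y"),
               class = "radanchor_input_error")
})

test_that("interval-mapping LOD at a fully typed marker equals single-marker regression", {
  cr <- small_cross()
  cfg <- cr$cfg
  cfg$missing_rate <- 0
  cfg$genotyping_error_rate <- 0
  f2 <- simulate_f2(cr$genome, cfg)
  coded <- code_genotypes(apply_genotype_filter(f2$calls))
  map <- build_linkage_map(coded$geno, coded$markers)
  pr <- genotype_probs(map, coded$geno, step_cm = 0)
  ph <- simulate_phenotypes(f2, cfg)
  scan <- scan_qtl(pr, ph, trait = "bolting")
  j <- 7
  mid <- scan$marker_id[j]
  g <- coded$geno[mid, pr$individuals]
  y <- ph$bolting[match(pr$individuals, ph$individual)]
  fit1 <- lm(y ~ I(g - 1) + I(as.integer(g == 1)))
  fit0 <- lm(y ~ 1)
  lod_direct <- (length(y) / 2) *
    log10(sum(fit0$residuals^2) / sum(fit1$residuals^2))
  expect_equal(scan$lod[j], lod_direct, tolerance = 1e-8)
})

test_that("LOD is invariant under affine transforms of the phenotype", {
  cr <- small_cross()
  coded <- code_genotypes(apply_genotype_filter(cr$f2$calls))
  map <- build_linkage_map(coded$geno, coded$markers)
  pr <- genotype_probs(map, coded$geno, step_cm = 5)
  ph <- simulate_phenotypes(cr$f2, cr$cfg)
  s1 <- scan_qtl(pr, ph, trait = "bolting")
  ph2 <- ph
  ph2$bolting <- 3.7 * ph$bolting - 12
  s2 <- scan_qtl(pr, ph2, trait = "bolting")
  expect_equal(s1$lod, s2$lod, tolerance = 1e-8)
})

test_that("PVE conversion matches its closed form and limits", {
  expect_equal(pve_from_lod(0, 100), 0)
  expect_equal(pve_from_lod(1, 100), 100 * (1 - 10^(-0.02)))
  expect_equal(pve_from_lod(1, 100), 4.50, tolerance = 0.01)
  expect_equal(pve_from_lod(15, 101), 49.5, tolerance = 0.1)
  lods <- seq(0, 30, by = 0.5)
  expect_true(all(diff(pve_from_lod(lods, 101)) > 0))
  expect_equal(pve_from_lod(1e6, 101), 100)
})

test_that("permutation thresholds are reproducible and sit in the null envelope", {
  cr <- small_cross()
  coded <- code_genotypes(apply_genotype_filter(cr$f2$calls))
  map <- build_linkage_map(coded$geno, coded$markers)
  pr <- genotype_probs(map, coded$geno, step_cm = 2)
  set.seed(99)
  ph <- tibble::tibble(individual = pr$individuals,
                       y = rnorm(length(pr$individuals)))
  t1 <- permutation_threshold(pr, ph, trait = "y", n_perm = 300, seed = 5)
  t2 <- permutation_threshold(pr, ph, trait = "y", n_perm = 300, seed = 5)
  expect_identical(t1, t2)
  expect_gt(t1, 2)
  expect_lt(t1, 4.5)
  # alpha = 1 returns the smallest permuted maximum
  t_min <- permutation_threshold(pr, ph, trait = "y", n_perm = 100,
                                 alpha = 1, seed = 5)
  expect_equal(as.numeric(t_min), min(attr(t_min, "perm_max")))
})

test_that("LOD support intervals bracket peaks and degenerate curves sanely", {
  grid <- tibble::tibble(
    lg = "LG1", lg_index = 1L, cm = 0:20,
    marker_id = ifelse(0:20 %% 5 == 0, sprintf("m%02d", 0:20), NA)
  )
  sym <- structure(dplyr::mutate(grid, lod = 5 - 0.5 * abs(cm - 10)),
                   class = c("qtl_scan", "tbl_df", "tbl", "data.frame"),
                   n = 100, trait = "t", method = "hk")
  ci <- lod_support_interval(sym, drop = 1.5)
  expect_equal(ci$peak_cm, 10)
  expect_equal(c(ci$ci_lo, ci$ci_hi), c(7, 13))
  expect_equal(ci$peak_cm - ci$ci_lo, ci$ci_hi - ci$peak_cm)
  expect_equal(c(ci$flank_lo, ci$flank_hi), c("m05", "m15"))

  flat <- structure(dplyr::mutate(grid, lod = 3),
                    class = class(sym), n = 100, trait = "t", method = "hk")
  ci_flat <- lod_support_interval(flat, drop = 1.5)
  expect_equal(c(ci_flat$ci_lo, ci_flat$ci_hi), c(0, 20))
})

test_that("exact rank-sum enumeration matches brute force and known cases", {
  # two fully separated groups of 7 and 8
  res <- exact_rank_sum(1:7, 11:18)
  expect_equal(res$W, 0)
  expect_equal(res$p_value, 2 / choose(15, 7), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  # a single tied pair is uninformative
  expect_equal(exact_rank_sum(5, 5)$p_value, 1)

  # brute-force enumeration oracle at n_a = n_b = 3, with ties
  set.seed(41)
  for (rep in 1:5) {
    vals <- sample(1:4, 6, replace = TRUE)
    a <- vals[1:3]; b <- vals[4:6]
    res <- exact_rank_sum(a, b)
    r <- rank(vals)
    mu <- 9 / 2
    combos <- combn(6, 3)
    w_all <- apply(combos, 2, function(ix) sum(r[ix]) - 6)
    p_brute <- mean(abs(w_all - mu) >= abs(res$W - mu) - 1e-9)
    expect_equal(res$p_value, p_brute, tolerance = 1e-12)
  }

  # agrees with the standard exact test when there are no ties
  a <- c(3.1, 5.2, 7.4, 2.2); b <- c(6.3, 8.1, 9.5, 4.4, 10.2)
  ours <- exact_rank_sum(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(ours$W, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("composite scans run with cofactors and respect the exclusion window", {
  cr <- small_cross()
  coded <- code_genotypes(apply_genotype_filter(cr$f2$calls))
  map <- build_linkage_map(coded$geno, coded$markers)
  pr <- genotype_probs(map, coded$geno, step_cm = 2)
  ph <- simulate_phenotypes(cr$f2, cr$cfg)
  cim <- scan_qtl(pr, ph, trait = "bolting", method = "cim",
                  geno = coded$geno, map = map)
  hk <- scan_qtl(pr, ph, trait = "bolting")
  expect_s3_class(cim, "qtl_scan")
  expect_true(all(cim$lod >= 0))
  # both methods localise the planted QTL on the same linkage group
  expect_equal(as_tibble(cim)$lg[which.max(cim$lod)],
               as_tibble(hk)$lg[which.max(hk$lod)])
  expect_error(scan_qtl(pr, ph, trait = "bolting", method = "cim"),
               class = "radanchor_input_error")
})
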