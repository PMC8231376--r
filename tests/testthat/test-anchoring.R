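# a hand-built map for block/breakpoint rules: columns follow genetic_map
toy_map <- function(rows) {
  df <- tibble::as_tibble(rows)
  df$lg_index <- as.integer(sub("LG", "", df$lg))
  structure(df, class = c("genetic_map", class(df)), map_function = "kosambi")
}

test_that("markers cluster into blocks by linkage group and cM jumps", {
  m <- toy_map(tibble::tibble(
    marker_id = sprintf("m%d", 1:8),
    scaffold_id = "s1",
    pos = c(1e5, 2e5, 3e5, 4e5, 6e5, 7e5, 8e5, 9e5),
    lg = c(rep("LG1", 5), rep("LG4", 3)),
    cm = c(1, 2, 3, 4, 5, 40, 41, 42)
  ))
  blocks <- assign_scaffolds(m)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$lg, c("LG1", "LG4"))
  expect_equal(blocks$n_markers, c(5, 3))

  # contiguous same-group markers form one block
  one <- toy_map(tibble::tibble(marker_id = c("a", "b", "c"),
                                scaffold_id = "s2", pos = c(1, 2, 3) * 1e5,
                                lg = "LG2", cm = c(10, 11, 12)))
  expect_equal(nrow(assign_scaffolds(one)), 1)

  # a same-group cM jump > gap_cm opens a new block
  jump <- toy_map(tibble::tibble(marker_id = c("a", "b", "c"),
                                 scaffold_id = "s3", pos = c(1, 2, 3) * 1e5,
                                 lg = "LG2", cm = c(10, 11, 45)))
  expect_equal(nrow(assign_scaffolds(jump)), 2)

  # markers on unknown scaffolds are an error when the assembly is given
  expect_error(assign_scaffolds(m, tibble::tibble(scaffold_id = "other",
                                                  length = 1e6)),
               class = "radanchor_input_error")
})

test_that("chimeras are detected at different-group boundaries with midpoint breakpoints", {
  m <- toy_map(tibble::tibble(
    marker_id = sprintf("m%d", 1:6),
    scaffold_id = "s1",
    pos = c(1e5, 2e5, 4e5, 6e5, 7.5e5, 9e5),
    lg = c("LG1", "LG1", "LG1", "LG4", "LG4", "LG4"),
    cm = c(1, 2, 3, 50, 51, 52)
  ))
  bp <- detect_chimeras(assign_scaffolds(m))
  expect_equal(nrow(bp), 1)
  expect_equal(bp$breakpoint, 500000)
  expect_equal(c(bp$lg_left, bp$lg_right), c("LG1", "LG4"))

  # same-group blocks separated by a cM jump: flagged, not chimeric
  warn_map <- toy_map(tibble::tibble(
    marker_id = c("a", "b"), scaffold_id = "s2",
    pos = c(1e5, 9e5), lg = "LG2", cm = c(0, 60)
  ))
  bp2 <- detect_chimeras(assign_scaffolds(warn_map))
  expect_equal(nrow(bp2), 0)
  expect_equal(attr(bp2, "warnings")$scaffold_id, "s2")

  # single block: nothing to report
  single <- toy_map(tibble::tibble(marker_id = "a", scaffold_id = "s3",
                                   pos = 1e5, lg = "LG1", cm = 5))
  expect_equal(nrow(detect_chimeras(assign_scaffolds(single))), 0)
})

test_that("splitting respects 1-based inclusive arithmetic and the >1 kb rule", {
  m <- toy_map(tibble::tibble(
    marker_id = sprintf("m%d", 1:6),
    scaffold_id = "s1",
    pos = c(1e5, 2e5, 4e5, 6e5, 7.5e5, 8.9e5),
    lg = c("LG1", "LG1", "LG1", "LG4", "LG4", "LG4"),
    cm = c(1, 2, 3, 50, 51, 52)
  ))
  scaffolds <- tibble::tibble(scaffold_id = "s1", length = 9e5)
  blocks <- assign_scaffolds(m)
  bp <- detect_chimeras(blocks)
  seg <- split_and_segment(scaffolds, blocks, bp, map = m)
  expect_equal(seg$start, c(1, 500001))
  expect_equal(seg$end, c(500000, 900000))
  expect_equal(seg$lg, c("LG1", "LG4"))
  expect_equal(seg$length, c(500000, 400000))

  # no breakpoints: the scaffold is one segment
  seg2 <- split_and_segment(scaffolds, blocks[1, ], bp[0, ], map = m)
  expect_equal(nrow(seg2), 1)
  expect_equal(c(seg2$start, seg2$end), c(1, 9e5))

  # a piece of exactly 1,000 bp is discarded (strict >)
  tiny_blocks <- tibble::tibble(scaffold_id = "t", block = 1:2,
                                lg = c("LG1", "LG2"), lg_index = 1:2,
                                n_markers = 1L,
                                bp_lo = c(500, 1500), bp_hi = c(900, 1900),
                                cm_lo = 0, cm_hi = 0, cm_mean = c(5, 50))
  tiny <- split_and_segment(tibble::tibble(scaffold_id = "t", length = 5000),
                            tiny_blocks,
                            tibble::tibble(scaffold_id = "t", breakpoint = 1000,
                                           lg_left = "LG1", lg_right = "LG2"))
  expect_equal(nrow(tiny), 1)   # only the 4,000 bp piece survives
  un <- attr(tiny, "unanchored")
  expect_true(any(un$reason == "too_short" & un$end - un$start + 1 == 1000))

  # conservation: anchored + unanchored bp = total scaffold bp
  expect_equal(sum(tiny$length) + sum(un$end - un$start + 1), 5000)

  expect_error(
    split_and_segment(scaffolds, blocks,
                      tibble::tibble(scaffold_id = "s1", breakpoint = 2e6,
                                     lg_left = "LG1", lg_right = "LG4")),
    class = "radanchor_input_error"
  )
})

test_that("segment orientation follows the bp-cM rank correlation", {
  expect_equal(orient_segment(c(1e4, 5e4, 9e4), c(2, 4, 6)), "+")
  expect_equal(orient_segment(c(1e4, 5e4, 9e4), c(6, 4, 2)), "-")
  expect_equal(orient_segment(5e4, 3), "?")
  expect_equal(orient_segment(c(1e4, 2e4), c(3, 3)), "?")
})

test_that("pseudomolecule gap accounting and naming follow the plan", {
  segs <- tibble::tibble(
    scaffold_id = c("sA", "sB"), start = c(1, 1), end = c(5000, 7000),
    length = c(5000, 7000), lg = "LG1", lg_index = 1L,
    cm = c(0, 10), n_markers = 2L, orientation = "+"
  )
  ps <- build_pseudomolecules(segs)
  expect_equal(ps$summary$object, "chr01")
  expect_equal(ps$summary$length_bp, 5000 + 10000 + 7000)
  expect_equal(ps$summary$n_segments, 2)
  # gap accounting invariant
  expect_equal(ps$summary$length_bp - ps$summary$segment_bp,
               10000 * (ps$summary$n_segments - 1))
  # duplicate placement is an error
  expect_error(build_pseudomolecules(dplyr::bind_rows(segs, segs[1, ])),
               class = "radanchor_input_error")
  # an empty group between populated ones draws a warning
  segs2 <- segs
  segs2$lg_index <- 2L
  expect_warning(build_pseudomolecules(segs2), "LG1")
})

test_that("AGP and FASTA round-trip byte-identically on a sequenced genome", {
  cfg <- sim_config(n_chromosomes = 3, chromosome_lengths = c(8e5, 6e5, 5e5),
                    n_scaffolds = 12, chimera_fraction = 0.25,
                    y_scaffold_fraction = 0, n_f2 = 101,
                    marker_density = 120, cm_per_mb = 60,
                    genotyping_error_rate = 0, missing_rate = 0,
                    with_sequence = TRUE,
                    qtl_spec = tibble::tibble()[0, ],
                    binary_locus = c(1, 4e5), seed = 19)
  genome <- simulate_genome(cfg)
  f2 <- simulate_f2(genome, cfg)
  coded <- code_genotypes(apply_genotype_filter(f2$calls))
  map <- build_linkage_map(coded$geno, coded$markers)
  blocks <- assign_scaffolds(map, genome$scaffolds)
  bp <- detect_chimeras(blocks)
  segs <- split_and_segment(genome$scaffolds, blocks, bp, map = map)
  ps <- build_pseudomolecules(segs, genome$sequences)

  # regenerating the FASTA from AGP + scaffolds reproduces it exactly
  rebuilt <- agp_to_fasta(ps$agp, genome$sequences)
  expect_identical(as.character(ps$sequences), as.character(rebuilt))

  # through a file round trip too
  f <- tempfile(fileext = ".agp")
  write_agp(ps$agp, f)
  agp2 <- read_agp(f)
  rebuilt2 <- agp_to_fasta(agp2, genome$sequences)
  expect_identical(as.character(ps$sequences), as.character(rebuilt2))

  # conservation of bp through splitting and anchoring
  un <- attr(segs, "unanchored")
  expect_equal(sum(segs$length) + sum(un$end - un$start + 1),
               sum(genome$scaffolds$length))

  # chromosome count matches the simulated genome
  expect_equal(nrow(ps$summary), 3)
})

test_that("a chimera-free densely mapped genome round-trips to its chromosomes", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_lengths = c(6e5, 4e5),
                    n_scaffolds = 8, chimera_fraction = 0,
                    y_scaffold_fraction = 0, n_f2 = 150,
                    marker_density = 150, cm_per_mb = 60,
                    genotyping_error_rate = 0, missing_rate = 0,
                    with_sequence = TRUE,
                    qtl_spec = tibble::tibble()[0, ],
                    binary_locus = c(1, 3e5), seed = 23)
  genome <- simulate_genome(cfg)
  f2 <- simulate_f2(genome, cfg)
  coded <- code_genotypes(apply_genotype_filter(f2$calls))
  map <- build_linkage_map(coded$geno, coded$markers)
  blocks <- assign_scaffolds(map, genome$scaffolds)
  bp <- detect_chimeras(blocks)
  expect_equal(nrow(bp), 0)
  segs <- split_and_segment(genome$scaffolds, blocks, bp, map = map)
  ps <- build_pseudomolecules(segs, genome$sequences)

  # each emitted chromosome contains every anchored scaffold of one true
  # chromosome, i.e. segments of one object map to a single true chromosome
  truth <- genome$truth$agp
  seg_chrom <- truth$chrom[match(segs$scaffold_id, truth$scaffold_id)]
  obj_of_lg <- split(seg_chrom, segs$lg_index)
  expect_true(all(vapply(obj_of_lg, function(x) length(unique(x)) == 1,
                         logical(1))))
})
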