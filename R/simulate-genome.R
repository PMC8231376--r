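#' Simulate a fragmented genome with chimeric and Y-linked scaffolds
#'
#' Cuts each simulated chromosome into fragments and reassembles them into
#' scaffolds. A configurable fraction of scaffolds are chimeric — each joins
#' two fragments from *different* chromosomes, emulating scaffolding errors —
#' and a fraction are flagged Y-linked (male-specific sequence that the
#' male/female depth screen should remove). Ground truth records the exact
#' chromosome interval and orientation behind every scaffold base.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_genome"` with elements:
#'   * `scaffolds`: tibble of `scaffold_id`, `length`, `is_y`, `n_fragments`;
#'   * `truth`: list with `agp` (tibble mapping scaffold intervals to
#'     chromosome intervals with strand), `y_scaffolds`, `chromosome_lengths`;
#'   * `sequences`: named `DNAStringSet` of scaffold residues, or `NULL`
#'     when `config$with_sequence` is `FALSE`;
#'   * `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$chimera_fraction > 0 && config$n_chromosomes < 2) {
    abort("chimeric scaffolds need at least two chromosomes",
          class = "radanchor_config_error")
  }
  set.seed(derive_seed(config$seed, 1L))
  n_chr <- config$n_chromosomes
  lens <- config$chromosome_lengths
  n_scaf <- config$n_scaffolds
  n_chim <- round(config$chimera_fraction * n_scaf)
  n_frag <- n_scaf + n_chim
  if (n_frag > sum(lens)) {
    abort("total scaffold count exceeds genome length",
          class = "radanchor_config_error")
  }

  # fragments per chromosome: proportional to length, largest remainder, >= 1
  share <- n_frag * lens / sum(lens)
  k <- pmax(1L, floor(share))
  left <- n_frag - sum(k)
  if (left > 0) {
    extra <- order(share - floor(share), decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1L
  } else if (left < 0) {
    drop <- order(k, decreasing = TRUE)[seq_len(-left)]
    k[drop] <- k[drop] - 1L
  }

  frags <- purrr::map(seq_len(n_chr), function(i) {
    ki <- k[i]
    L <- lens[i]
    min_piece <- max(1, min(50e3, floor(L / (2 * ki))))
    w <- diff(c(0, sort(runif(max(ki - 1, 0))), 1))
    pl <- min_piece + floor((L - ki * min_piece) * w)
    pl[ki] <- pl[ki] + (L - sum(pl))
    ends <- cumsum(pl)
    tibble(chrom = i, chrom_start = c(1, head(ends, -1) + 1), chrom_end = ends)
  }) |> purrr::list_rbind()
  frags$strand <- ifelse(rbinom(nrow(frags), 1, config$inversion_fraction) == 1, "-", "+")
  frags$frag_id <- seq_len(nrow(frags))

  # pair fragments from different chromosomes into chimeras
  pool <- sample(frags$frag_id)
  chim_pairs <- list()
  while (length(chim_pairs) < n_chim) {
    a <- pool[1]
    other <- pool[frags$chrom[match(pool, frags$frag_id)] != frags$chrom[match(a, frags$frag_id)]]
    if (length(other) == 0) {
      abort("cannot form requested chimeras: fragments exhausted on one chromosome")
    }
    b <- other[1]
    chim_pairs[[length(chim_pairs) + 1]] <- c(a, b)
    pool <- setdiff(pool, c(a, b))
  }
  singles <- pool

  members <- c(chim_pairs, as.list(singles))
  members <- members[sample.int(length(members))]
  scaf_ids <- sprintf("scf%04d", seq_along(members))

  agp <- purrr::imap(members, function(fr, i) {
    rows <- frags[match(fr, frags$frag_id), ]
    plen <- rows$chrom_end - rows$chrom_start + 1
    ends <- cumsum(plen)
    tibble(
      scaffold_id = scaf_ids[i],
      scaf_start = c(1, head(ends, -1) + 1),
      scaf_end = ends,
      chrom = rows$chrom,
      chrom_start = rows$chrom_start,
      chrom_end = rows$chrom_end,
      strand = rows$strand
    )
  }) |> purrr::list_rbind()

  scaffolds <- agp |>
    group_by(.data$scaffold_id) |>
    summarise(length = max(.data$scaf_end),
              n_fragments = n(),
              n_chroms = dplyr::n_distinct(.data$chrom),
              .groups = "drop")

  # Y-linked subset: non-chimeric scaffolds above the size screen's floor
  n_y <- round(config$y_scaffold_fraction * n_scaf)
  eligible <- scaffolds$scaffold_id[scaffolds$n_chroms == 1 & scaffolds$length > 10000]
  if (n_y > length(eligible)) {
    abort("not enough non-chimeric scaffolds > 10 kb to flag as Y-linked")
  }
  y_ids <- sort(sample(eligible, n_y))
  scaffolds$is_y <- scaffolds$scaffold_id %in% y_ids

  sequences <- NULL
  if (config$with_sequence) {
    chrom_seq <- Biostrings::DNAStringSet(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(chrom_seq) <- paste0("chrom", seq_len(n_chr))
    pieces <- Biostrings::DNAStringSet(Biostrings::DNAString(""))[0]
    seqs <- vapply(split(agp, agp$scaffold_id), function(rows) {
      part <- purrr::pmap_chr(rows, function(chrom, chrom_start, chrom_end, strand, ...) {
        s <- Biostrings::subseq(chrom_seq[[chrom]], chrom_start, chrom_end)
        if (strand == "-") s <- Biostrings::reverseComplement(s)
        as.character(s)
      })
      paste(part, collapse = "")
    }, character(1))
    sequences <- Biostrings::DNAStringSet(seqs)
  }

  structure(list(
    scaffolds = select(scaffolds, "scaffold_id", "length", "is_y", "n_fragments"),
    truth = list(agp = agp, y_scaffolds = y_ids, chromosome_lengths = lens),
    sequences = sequences,
    config = config
  ), class = "sim_genome")
}

#' Simulate per-scaffold male and female mapped depths
#'
#' Mapped coverage is modelled as Poisson read counts per 1-kb window,
#' averaged over the scaffold, so long scaffolds have tight depth means as
#' per-scaffold coverage summaries do in practice. Autosomal scaffolds draw
#' male and female depth around the same mean; Y-linked scaffolds draw male
#' depth around half the autosomal mean (hemizygous) and female depth around
#' a small cross-mapping floor (2% of the mean), so the male/female ratio is
#' strongly elevated but finite.
#'
#' @param genome A `"sim_genome"` from [simulate_genome()].
#' @param config A [sim_config()]; defaults to the genome's own config.
#' @return Tibble with `scaffold_id`, `length`, `male_depth`, `female_depth`.
#' @export
simulate_depths <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "sim_genome"), config$mean_depth > 0)
  set.seed(derive_seed(config$seed, 2L))
  sc <- genome$scaffolds
  win <- pmax(1, round(sc$length / 1000))
  lam_m <- ifelse(sc$is_y, config$mean_depth / 2, config$mean_depth)
  lam_f <- ifelse(sc$is_y, 0.02 * config$mean_depth, config$mean_depth)
  tibble(
    scaffold_id = sc$scaffold_id,
    length = sc$length,
    male_depth = rpois(nrow(sc), lam_m * win) / win,
    female_depth = rpois(nrow(sc), lam_f * win) / win
  )
}
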