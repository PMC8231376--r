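#' Linkage-group recovery metrics against simulation truth
#'
#' Compares an estimated map's grouping with the chromosomes the markers
#' were simulated on. Purity is the fraction of mapped markers assigned to
#' their linkage group's majority chromosome.
#'
#' @param map A `"genetic_map"`.
#' @param f2 The `"sim_f2"` whose `markers` table carries the true
#'   chromosome of every marker.
#' @return List with `n_groups`, `purity`, and the group-by-chromosome
#'   contingency `table`.
#' @export
lg_purity <- function(map, f2) {
  df <- as_tibble(map) |>
    left_join(f2$markers |> select("marker_id", "chrom"), by = "marker_id")
  tab <- table(df$lg, df$chrom)
  list(n_groups = nrow(tab),
       purity = sum(apply(tab, 1, max)) / sum(tab),
       table = tab)
}

#' Chimera-detection metrics against simulation truth
#'
#' Sensitivity is computed over *informative* true chimeras — chimeric
#' scaffolds whose every constituent fragment carries at least `min_markers`
#' mapped markers, since a join with an unmarked side is undetectable from a
#' linkage map in principle. Precision is computed over all called
#' chimeras.
#'
#' @param breakpoints Output of [detect_chimeras()].
#' @param genome The `"sim_genome"`.
#' @param map The `"genetic_map"` used for detection.
#' @param min_markers Markers required per fragment for a truth chimera to
#'   count as informative (default 1).
#' @return List with `sensitivity`, `precision`, `n_true`,
#'   `n_true_informative`, `n_called`.
#' @export
chimera_metrics <- function(breakpoints, genome, map, min_markers = 1) {
  agp <- genome$truth$agp
  multi <- agp |>
    group_by(.data$scaffold_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom), .groups = "drop")
  true_ids <- multi$scaffold_id[multi$n_chrom > 1]

  mk <- as_tibble(map)
  frag_counts <- agp |>
    filter(.data$scaffold_id %in% true_ids) |>
    mutate(n_mk = purrr::pmap_int(
      list(.data$scaffold_id, .data$scaf_start, .data$scaf_end),
      function(sid, s, e) sum(mk$scaffold_id == sid & mk$pos >= s & mk$pos <= e)
    ))
  informative <- frag_counts |>
    group_by(.data$scaffold_id) |>
    summarise(ok = all(.data$n_mk >= min_markers), .groups = "drop")
  inf_ids <- informative$scaffold_id[informative$ok]

  called <- unique(breakpoints$scaffold_id)
  list(
    sensitivity = if (length(inf_ids)) mean(inf_ids %in% called) else NA_real_,
    precision = if (length(called)) mean(called %in% true_ids) else NA_real_,
    n_true = length(true_ids),
    n_true_informative = length(inf_ids),
    n_called = length(called)
  )
}

#' Y-scaffold screening metrics against simulation truth
#'
#' @param classification Output of [classify_sex_scaffolds()].
#' @param genome The `"sim_genome"`.
#' @return List with `recall`, `precision`, `n_true`, `n_called`.
#' @export
y_scaffold_metrics <- function(classification, genome) {
  truth <- genome$truth$y_scaffolds
  called <- classification$scaffold_id[classification$label == "Y_LINKED"]
  list(
    recall = if (length(truth)) mean(truth %in% called) else NA_real_,
    precision = if (length(called)) mean(called %in% truth) else NA_real_,
    n_true = length(truth),
    n_called = length(called)
  )
}
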