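#' Default transposable-element keyword list
#'
#' Keywords matched (case-insensitively) against protein-database hit
#' descriptions to flag transposable-element-related genes. The exact list
#' used by any given annotation project is rarely published; this default is
#' configurable everywhere it is consumed.
#'
#' @return Character vector of keywords.
#' @export
default_te_keywords <- function() {
  c("transposon", "retrotransposon", "transposase",
    "reverse transcriptase", "gag-pol", "integrase")
}

#' Flag transposable-element keywords in hit descriptions
#'
#' @param description Character vector of hit descriptions.
#' @param keywords Keyword list (default [default_te_keywords()]).
#' @return Logical vector.
#' @export
flag_te_keywords <- function(description, keywords = default_te_keywords()) {
  pat <- paste(keywords, collapse = "|")
  !is.na(description) & grepl(pat, description, ignore.case = TRUE)
}

#' Keep each gene's best-scoring transcript
#'
#' Splicing variants are reduced to the transcript with the highest
#' prediction score; ties break to the lexicographically first transcript
#' id.
#'
#' @param evidence Tibble with at least `gene_id`, `transcript_id`,
#'   `prediction_score` (one row per transcript).
#' @return The per-gene best rows.
#' @export
select_best_transcript <- function(evidence) {
  as_tibble(evidence) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$prediction_score), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Qualify per-channel homology evidence
#'
#' Applies the inclusive evidence thresholds per search channel:
#' * UniProtKB: E-value <= 1e-10 and identity >= 98%;
#' * NR: E-value <= 1e-10 and identity >= 95%;
#' * reference proteome: E-value <= 1e-50, 90% <= length coverage <= 110%,
#'   identity >= 98% and HSP identity >= 98%;
#' * Pfam: E-value <= 1e-80.
#' Absent hits (`NA`) never qualify.
#'
#' @param evidence Tibble with columns `uniprot_evalue`, `uniprot_identity`,
#'   `nr_evalue`, `nr_identity`, `sp_evalue`, `sp_identity`, `sp_coverage`,
#'   `sp_hsp_identity`, `pfam_evalue` (`NA` = no hit).
#' @return `evidence` with added logical columns `q_uniprot`, `q_nr`,
#'   `q_sp`, `q_pfam`.
#' @export
qualify_hits <- function(evidence) {
  ev <- as_tibble(evidence)
  pctcols <- c("uniprot_identity", "nr_identity", "sp_identity",
               "sp_coverage", "sp_hsp_identity")
  for (cc in intersect(pctcols, names(ev))) {
    if (any(ev[[cc]] < 0, na.rm = TRUE)) {
      abort(paste0("negative percentage in ", cc), class = "radanchor_input_error")
    }
  }
  qq <- function(x) !is.na(x) & x
  ev |>
    mutate(
      q_uniprot = qq(.data$uniprot_evalue <= 1e-10 & .data$uniprot_identity >= 98),
      q_nr = qq(.data$nr_evalue <= 1e-10 & .data$nr_identity >= 95),
      q_sp = qq(.data$sp_evalue <= 1e-50 & .data$sp_coverage >= 90 &
                  .data$sp_coverage <= 110 & .data$sp_identity >= 98 &
                  .data$sp_hsp_identity >= 98),
      q_pfam = qq(.data$pfam_evalue <= 1e-80)
    )
}

#' Classify genes as high-confidence, low-confidence or TE
#'
#' Precedence TE > HC > LC:
#' * TE — a qualifying UniProtKB hit whose description carries a
#'   transposable-element keyword;
#' * HC — any qualifying homology channel, or evidence of expression
#'   (TPM > 0);
#' * LC — everything else.
#'
#' @param evidence Per-transcript evidence tibble (see
#'   [simulate_gene_evidence()] for the column layout); reduced to best
#'   transcripts with [select_best_transcript()] first.
#' @param best Set `FALSE` if `evidence` is already one row per gene.
#' @return Tibble with `gene_id`, `transcript_id`, `label` (`"HC"`, `"LC"`,
#'   `"TE"`) and the qualifying-channel flags.
#' @export
classify_genes <- function(evidence, best = TRUE) {
  ev <- if (best) select_best_transcript(evidence) else as_tibble(evidence)
  ev <- qualify_hits(ev)
  ev |>
    mutate(
      is_te = .data$q_uniprot & .data$uniprot_te_keyword,
      is_hc = .data$q_uniprot | .data$q_nr | .data$q_sp | .data$q_pfam |
        .data$tpm > 0,
      label = case_when(.data$is_te ~ "TE", .data$is_hc ~ "HC", TRUE ~ "LC")
    ) |>
    select("gene_id", "transcript_id", "label",
           "q_uniprot", "q_nr", "q_sp", "q_pfam", "tpm")
}

#' Summarise a gene classification
#'
#' @param classes Output of [classify_genes()].
#' @return One-row tibble: `n_genes`, `n_HC`, `n_LC`, `n_TE`, and qualifying
#'   counts per channel.
#' @export
classification_report <- function(classes) {
  tibble(
    n_genes = nrow(classes),
    n_HC = sum(classes$label == "HC"),
    n_LC = sum(classes$label == "LC"),
    n_TE = sum(classes$label == "TE"),
    n_q_uniprot = sum(classes$q_uniprot),
    n_q_nr = sum(classes$q_nr),
    n_q_sp = sum(classes$q_sp),
    n_q_pfam = sum(classes$q_pfam),
    n_expressed = sum(classes$tpm > 0)
  )
}
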