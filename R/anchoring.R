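#' Assign mapped markers to per-scaffold linkage blocks
#'
#' Walks each scaffold's markers in bp order and clusters them into blocks:
#' consecutive markers sharing a linkage group join one block; a switch of
#' linkage group, or a same-group jump in map position larger than `gap_cm`,
#' starts a new block. Scaffolds whose blocks disagree on linkage group are
#' chimera candidates.
#'
#' @param map A `"genetic_map"` (tibble with `marker_id`, `scaffold_id`,
#'   `pos`, `lg`, `lg_index`, `cm`).
#' @param scaffolds Optional tibble with `scaffold_id`, `length` used to
#'   check that every mapped marker lies on a known scaffold.
#' @param gap_cm Same-group cM jump that opens a new block (default 20).
#' @return Tibble with one row per block: `scaffold_id`, `block`, `lg`,
#'   `lg_index`, `n_markers`, `bp_lo`, `bp_hi`, `cm_lo`, `cm_hi`, `cm_mean`.
#' @export
assign_scaffolds <- function(map, scaffolds = NULL, gap_cm = 20) {
  df <- as_tibble(map)
  if (!is.null(scaffolds)) {
    unknown <- setdiff(unique(df$scaffold_id), scaffolds$scaffold_id)
    if (length(unknown) > 0) {
      abort(paste0("mapped markers on scaffolds absent from the assembly: ",
                   paste(head(unknown, 5), collapse = ", ")),
            class = "radanchor_input_error")
    }
    bad <- left_join(df, scaffolds, by = "scaffold_id") |>
      filter(.data$pos > .data$length)
    if (nrow(bad) > 0) {
      abort("marker positions beyond scaffold length",
            class = "radanchor_input_error")
    }
  }
  df |>
    arrange(.data$scaffold_id, .data$pos) |>
    group_by(.data$scaffold_id) |>
    mutate(new_block = .data$lg != lag(.data$lg, default = first(.data$lg)) |
             abs(.data$cm - lag(.data$cm, default = first(.data$cm))) > gap_cm,
           block = cumsum(.data$new_block) + 1L) |>
    group_by(.data$scaffold_id, .data$block) |>
    summarise(lg = first(.data$lg), lg_index = first(.data$lg_index),
              n_markers = n(),
              bp_lo = min(.data$pos), bp_hi = max(.data$pos),
              cm_lo = min(.data$cm), cm_hi = max(.data$cm),
              cm_mean = mean(.data$cm), .groups = "drop")
}

#' Detect chimeric scaffolds and place breakpoints
#'
#' A scaffold is chimeric when it carries blocks from *different* linkage
#' groups. The breakpoint between two adjacent conflicting blocks is placed
#' at the midpoint between the last marker of one block and the first
#' marker of the next. Adjacent same-group blocks (opened by a cM jump) are
#' not chimeric; they are reported in the `"warnings"` attribute.
#'
#' @param assignments Output of [assign_scaffolds()].
#' @return Tibble with `scaffold_id`, `breakpoint` (bp), `lg_left`,
#'   `lg_right`; attribute `"warnings"` lists same-group multi-block
#'   scaffolds.
#' @export
detect_chimeras <- function(assignments) {
  a <- arrange(assignments, .data$scaffold_id, .data$block)
  res <- a |>
    group_by(.data$scaffold_id) |>
    mutate(next_lg = lead(.data$lg), next_lo = lead(.data$bp_lo)) |>
    filter(!is.na(.data$next_lg)) |>
    ungroup()
  warnings_tbl <- res |>
    filter(.data$lg == .data$next_lg) |>
    transmute(.data$scaffold_id,
              note = "same-group blocks separated by a cM jump")
  out <- res |>
    filter(.data$lg != .data$next_lg) |>
    transmute(.data$scaffold_id,
              breakpoint = floor((.data$bp_hi + .data$next_lo) / 2),
              lg_left = .data$lg, lg_right = .data$next_lg)
  attr(out, "warnings") <- distinct(warnings_tbl)
  out
}

#' Split scaffolds at chimera breakpoints and collect anchor segments
#'
#' Cuts each scaffold at its breakpoints (1-based inclusive pieces), assigns
#' every piece the linkage block it contains, and retains pieces strictly
#' longer than `min_len` as anchor segments. Pieces without mapped markers,
#' scaffolds without assignments, and sub-threshold pieces are reported as
#' unanchored.
#'
#' @param scaffolds Tibble with `scaffold_id`, `length`.
#' @param assignments Output of [assign_scaffolds()].
#' @param breakpoints Output of [detect_chimeras()].
#' @param min_len Minimum retained segment length in bp, strict (default
#'   1000).
#' @param map Optional `"genetic_map"`; when given, each segment's anchor cM
#'   and orientation are recomputed from the markers inside it (see
#'   [orient_segment()]).
#' @return Tibble of segments: `scaffold_id`, `start`, `end`, `length`,
#'   `lg`, `lg_index`, `cm` (mean of member markers), `n_markers`,
#'   `orientation` (`"+"`, `"-"`, `"?"`). Attribute `"unanchored"`: tibble
#'   of `scaffold_id`, `start`, `end`, `reason` (`no_markers`,
#'   `too_short`, `unassigned_scaffold`).
#' @export
split_and_segment <- function(scaffolds, assignments, breakpoints,
                              min_len = 1000, map = NULL) {
  bp_list <- split(breakpoints$breakpoint, breakpoints$scaffold_id)
  seg_rows <- list()
  un_rows <- list()
  mk <- if (!is.null(map)) as_tibble(map) else NULL

  for (i in seq_len(nrow(scaffolds))) {
    sid <- scaffolds$scaffold_id[i]
    L <- scaffolds$length[i]
    blocks <- filter(assignments, .data$scaffold_id == sid)
    if (nrow(blocks) == 0) {
      un_rows[[length(un_rows) + 1]] <-
        tibble(scaffold_id = sid, start = 1, end = L, reason = "unassigned_scaffold")
      next
    }
    cuts <- sort(unique(bp_list[[sid]]))
    if (length(cuts) > 0 && (any(cuts < 1) || any(cuts >= L))) {
      abort(sprintf("breakpoints outside scaffold bounds on %s", sid),
            class = "radanchor_input_error")
    }
    starts <- c(1, cuts + 1)
    ends <- c(cuts, L)
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- ends[k]
      hit <- filter(blocks, .data$bp_lo <= e & .data$bp_hi >= s)
      if (nrow(hit) == 0) {
        un_rows[[length(un_rows) + 1]] <-
          tibble(scaffold_id = sid, start = s, end = e, reason = "no_markers")
        next
      }
      if (dplyr::n_distinct(hit$lg) > 1) {
        abort(sprintf("piece %s:%d-%d spans blocks of different linkage groups; breakpoints overlap or are missing",
                      sid, s, e), class = "radanchor_input_error")
      }
      if (e - s + 1 <= min_len) {
        un_rows[[length(un_rows) + 1]] <-
          tibble(scaffold_id = sid, start = s, end = e, reason = "too_short")
        next
      }
      orientation <- "?"
      n_mk <- sum(hit$n_markers)
      cm_piece <- sum(hit$cm_mean * hit$n_markers) / n_mk
      if (!is.null(mk)) {
        sub <- filter(mk, .data$scaffold_id == sid, .data$pos >= s, .data$pos <= e)
        if (nrow(sub) > 0) {
          orientation <- orient_segment(sub$pos, sub$cm)
          cm_piece <- mean(sub$cm)
          n_mk <- nrow(sub)
        }
      }
      seg_rows[[length(seg_rows) + 1]] <- tibble(
        scaffold_id = sid, start = s, end = e, length = e - s + 1,
        lg = hit$lg[1], lg_index = hit$lg_index[1],
        cm = cm_piece, n_markers = n_mk, orientation = orientation
      )
    }
  }
  out <- if (length(seg_rows)) purrr::list_rbind(seg_rows) else
    tibble(scaffold_id = character(), start = numeric(), end = numeric(),
           length = numeric(), lg = character(), lg_index = integer(),
           cm = numeric(), n_markers = integer(), orientation = character())
  attr(out, "unanchored") <- if (length(un_rows)) purrr::list_rbind(un_rows) else
    tibble(scaffold_id = character(), start = numeric(), end = numeric(),
           reason = character())
  out
}

#' Orient a segment from its markers
#'
#' Sign of the rank correlation between marker bp position on the scaffold
#' and genetic position: `"+"` when map position increases with bp, `"-"`
#' when it decreases, `"?"` (treated as `"+"` downstream) when fewer than
#' two distinct map positions are available.
#'
#' @param bp Marker positions on the segment (bp).
#' @param cm Their map positions (cM).
#' @return `"+"`, `"-"` or `"?"`.
#' @export
orient_segment <- function(bp, cm) {
  if (length(bp) < 2 || length(unique(cm)) < 2 || length(unique(bp)) < 2) return("?")
  rho <- suppressWarnings(cor(bp, cm, method = "spearman"))
  if (is.na(rho) || rho == 0) "?" else if (rho > 0) "+" else "-"
}

#' Build pseudomolecules from anchor segments
#'
#' Per linkage group, segments are sorted by anchor cM (ties broken by
#' scaffold id then start), minus-oriented segments are reverse-complemented
#' and the pieces are catenated with fixed-length N gaps. Pseudomolecules
#' are named `chr01`, `chr02`, ... after linkage groups `LG1`, `LG2`, ...
#' An AGP 2.1 plan (1-based inclusive coordinates) and, when sequences are
#' supplied, the pseudomolecule FASTA are produced together and are mutually
#' consistent.
#'
#' @param segments Output of [split_and_segment()].
#' @param sequences Optional named `DNAStringSet` of scaffold residues.
#' @param gap Gap length in bp between adjacent segments (default 10000).
#' @param total_input_bp Optional total input scaffold bp, for the anchored
#'   fraction in the summary.
#' @return List of class `"pseudomolecule_set"`: `agp` (tibble of AGP rows),
#'   `sequences` (`DNAStringSet` or `NULL`), `summary` (per-chromosome
#'   tibble: `object`, `lg`, `n_segments`, `segment_bp`, `length_bp`, and
#'   `anchored_fraction` when `total_input_bp` is given).
#' @export
build_pseudomolecules <- function(segments, sequences = NULL, gap = 10000,
                                  total_input_bp = NULL) {
  if (anyDuplicated(segments[c("scaffold_id", "start", "end")])) {
    abort("duplicate segment placement", class = "radanchor_input_error")
  }
  lgs <- sort(unique(segments$lg_index))
  empty <- setdiff(seq_len(max(c(lgs, 0))), lgs)
  if (length(empty) > 0) {
    warn(paste0("no segments for linkage group(s): ",
                paste0("LG", empty, collapse = ", "), "; omitted"))
  }
  agp_rows <- list()
  seq_out <- list()
  sum_rows <- list()
  for (k in lgs) {
    seg <- segments |>
      filter(.data$lg_index == k) |>
      arrange(.data$cm, .data$scaffold_id, .data$start)
    object <- sprintf("chr%02d", k)
    obj_pos <- 0
    part <- 0
    pieces <- character(nrow(seg))
    for (j in seq_len(nrow(seg))) {
      if (j > 1) {
        part <- part + 1
        agp_rows[[length(agp_rows) + 1]] <- tibble(
          object = object, object_beg = obj_pos + 1, object_end = obj_pos + gap,
          part_number = part, component_type = "U",
          component_id = as.character(gap), component_beg = "contig",
          component_end = "yes", orientation = "map"
        )
        obj_pos <- obj_pos + gap
      }
      part <- part + 1
      len <- seg$end[j] - seg$start[j] + 1
      agp_rows[[length(agp_rows) + 1]] <- tibble(
        object = object, object_beg = obj_pos + 1, object_end = obj_pos + len,
        part_number = part, component_type = "W",
        component_id = seg$scaffold_id[j],
        component_beg = as.character(seg$start[j]),
        component_end = as.character(seg$end[j]),
        orientation = seg$orientation[j]
      )
      obj_pos <- obj_pos + len
      if (!is.null(sequences)) {
        s <- Biostrings::subseq(sequences[[seg$scaffold_id[j]]],
                                seg$start[j], seg$end[j])
        if (seg$orientation[j] == "-") s <- Biostrings::reverseComplement(s)
        pieces[j] <- as.character(s)
      }
    }
    if (!is.null(sequences)) {
      seq_out[[object]] <- paste(pieces,
                                 collapse = paste(rep("N", gap), collapse = ""))
    }
    sum_rows[[length(sum_rows) + 1]] <- tibble(
      object = object, lg = paste0("LG", k), n_segments = nrow(seg),
      segment_bp = sum(seg$end - seg$start + 1),
      length_bp = obj_pos
    )
  }
  agp <- purrr::list_rbind(agp_rows)
  summary <- purrr::list_rbind(sum_rows)
  if (!is.null(total_input_bp)) {
    summary$anchored_fraction <- summary$segment_bp / total_input_bp
  }
  seqs <- if (!is.null(sequences)) {
    Biostrings::DNAStringSet(unlist(seq_out))
  } else NULL
  structure(list(agp = agp, sequences = seqs, summary = summary),
            class = "pseudomolecule_set")
}

#' @export
print.pseudomolecule_set <- function(x, ...) {
  cat(sprintf("<pseudomolecule_set> %d chromosome(s), %.1f Mb total\n",
              nrow(x$summary), sum(x$summary$length_bp) / 1e6))
  print(x$summary)
  invisible(x)
}

#' Write an AGP 2.1 file
#'
#' @param agp AGP tibble from [build_pseudomolecules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##agp-version\t2.1", "# generated by radanchor"), con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AGP 2.1 file written by [write_agp()]
#' @param path AGP file path.
#' @return AGP tibble with the same columns [build_pseudomolecules()] emits.
#' @export
read_agp <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("object", "object_beg", "object_end",
                                        "part_number", "component_type",
                                        "component_id", "component_beg",
                                        "component_end", "orientation"))
  as_tibble(df)
}

#' Rebuild pseudomolecule sequences from an AGP plan
#'
#' The AGP-to-FASTA direction of the round trip: component rows are cut from
#' the scaffold sequences (reverse-complemented for `-` orientation; `?` is
#' treated as `+`), gap rows become runs of N.
#'
#' @param agp AGP tibble.
#' @param sequences Named `DNAStringSet` of scaffold residues.
#' @return `DNAStringSet` of pseudomolecules.
#' @export
agp_to_fasta <- function(agp, sequences) {
  objs <- unique(agp$object)
  out <- vapply(objs, function(ob) {
    rows <- filter(agp, .data$object == ob) |> arrange(.data$part_number)
    parts <- purrr::map_chr(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type == "U") {
        paste(rep("N", as.integer(r$component_id)), collapse = "")
      } else {
        s <- Biostrings::subseq(sequences[[r$component_id]],
                                as.integer(r$component_beg),
                                as.integer(r$component_end))
        if (r$orientation == "-") s <- Biostrings::reverseComplement(s)
        as.character(s)
      }
    })
    paste(parts, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(out, objs))
}
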