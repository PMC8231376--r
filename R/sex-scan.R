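#' Log10 male/female depth ratio
#'
#' A pseudocount keeps the ratio finite when the female depth is zero, as it
#' is on Y-linked scaffolds absent from an XX genome.
#'
#' @param male_depth,female_depth Mean mapped coverages (non-negative).
#' @param pseudocount Depth added to both numerator and denominator
#'   (default 0.01).
#' @return `log10((male + pseudocount) / (female + pseudocount))`.
#' @export
#' @examples
#' compute_log_ratio(20, 20)    # 0
#' compute_log_ratio(10, 0)     # ~3: strongly male-biased
compute_log_ratio <- function(male_depth, female_depth, pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  if (any(male_depth < 0, na.rm = TRUE) || any(female_depth < 0, na.rm = TRUE)) {
    abort("depths must be non-negative", class = "radanchor_input_error")
  }
  log10((male_depth + pseudocount) / (female_depth + pseudocount))
}

#' Classify scaffolds as Y-linked from male/female depth
#'
#' A scaffold is called Y-linked when its log10 male/female depth ratio
#' *strictly* exceeds `ratio_threshold` and its size *strictly* exceeds
#' `size_threshold`; everything else is retained. With the default
#' thresholds (0.2 and 10 kb) this removes male-specific sequence so the
#' retained set represents the female (XX) genome.
#'
#' @param depths Data frame with columns `scaffold_id`, `length`,
#'   `male_depth`, `female_depth` (one row per scaffold).
#' @param ratio_threshold Log10-ratio cutoff (default 0.2).
#' @param size_threshold Minimum scaffold length in bp (default 10000).
#' @param pseudocount Passed to [compute_log_ratio()].
#' @param normalize Divide each library's depths by its own median before
#'   forming the ratio, guarding against unequal sequencing effort.
#' @return Tibble with `scaffold_id`, `length`, `log10_ratio`, `label`
#'   (`"Y_LINKED"` or `"RETAINED"`), carrying a `"report"` attribute with
#'   counts and total bp removed.
#' @export
classify_sex_scaffolds <- function(depths, ratio_threshold = 0.2,
                                   size_threshold = 10000,
                                   pseudocount = 0.01,
                                   normalize = FALSE) {
  depths <- as_tibble(depths)
  stopifnot(all(c("scaffold_id", "length", "male_depth", "female_depth") %in% names(depths)))
  if (anyDuplicated(depths$scaffold_id)) {
    abort("expected one depth record per scaffold", class = "radanchor_input_error")
  }
  m <- depths$male_depth
  f <- depths$female_depth
  if (normalize) {
    m <- m / median(m)
    f <- f / median(f)
  }
  lr <- compute_log_ratio(m, f, pseudocount)
  label <- ifelse(lr > ratio_threshold & depths$length > size_threshold,
                  "Y_LINKED", "RETAINED")
  out <- tibble(scaffold_id = depths$scaffold_id, length = depths$length,
                log10_ratio = lr, label = label)
  attr(out, "report") <- tibble(
    n_input = nrow(out),
    n_y_linked = sum(label == "Y_LINKED"),
    n_retained = sum(label == "RETAINED"),
    bp_removed = sum(depths$length[label == "Y_LINKED"]),
    ratio_threshold = ratio_threshold,
    size_threshold = size_threshold
  )
  out
}

#' Drop Y-linked scaffolds from a scaffold set
#'
#' @param scaffolds Tibble with a `scaffold_id` column (e.g. from
#'   [simulate_genome()]), or a named `DNAStringSet`.
#' @param classification Output of [classify_sex_scaffolds()]. Every
#'   scaffold must have a depth record.
#' @return The retained subset, same type as `scaffolds`.
#' @export
filter_sex_scaffolds <- function(scaffolds, classification) {
  ids <- if (inherits(scaffolds, "DNAStringSet")) names(scaffolds) else scaffolds$scaffold_id
  missing_ids <- setdiff(ids, classification$scaffold_id)
  if (length(missing_ids) > 0) {
    abort(paste0("scaffolds without a depth record: ",
                 paste(head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) " ..."),
          class = "radanchor_input_error")
  }
  keep <- classification$scaffold_id[classification$label == "RETAINED"]
  if (inherits(scaffolds, "DNAStringSet")) {
    scaffolds[names(scaffolds) %in% keep]
  } else {
    filter(scaffolds, .data$scaffold_id %in% keep)
  }
}
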